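#!/usr/bin/env Rscript
# Compare the Otsu-based defect classification against the two alternative
# clustering rules (3-cluster k-means; fixed 20th-percentile threshold) on
# the same cohort: accuracy against ground truth and test-retest agreement.

library(qdpmri)

dir.create("results", showWarnings = FALSE)
seed <- 20221024L
cohort <- if (file.exists("scratch/cohort.rds")) {
  readRDS("scratch/cohort.rds")
} else {
  make_cohort(20, seed = seed)
}

rows <- list()
for (method in c("otsu", "kmeans", "percentile80")) {
  message("Method: ", method)
  run <- run_cohort(cohort, run_config(method = method, seed = seed))
  ag <- run$report$agreement
  pe <- run$per_exam[run$per_exam$qc_status == "pass", ]
  rows[[method]] <- data.frame(
    method = method,
    qdp_mae_vs_truth = mean(abs(pe$qdp - pe$qdp_truth)),
    qdp_loa_pct_of_median = ag$loa_pct_of_median[ag$metric == "qdp"],
    qdp_mid_pct_of_median = ag$mid_pct_of_median[ag$metric == "qdp"])
}
tbl <- do.call(rbind, rows)
write.csv(tbl, "results/clustering_comparators.csv", row.names = FALSE)
print(tbl, row.names = FALSE, digits = 3)
message("The fixed-percentile rule returns ~20% regardless of the true ",
        "defect extent (tiny LoA, but a ",
        round(tbl$qdp_mae_vs_truth[tbl$method == "percentile80"], 1),
        "-point mean error against truth: stable because insensitive). ",
        "Otsu and k-means both track the true defect extent closely; on ",
        "this cleanly separated phantom their agreement statistics are ",
        "nearly equivalent.")
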