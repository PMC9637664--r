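test_that("Bland-Altman matches the hand-evaluated closed form", {
  v1 <- c(10, 20, 30); v2 <- c(12, 18, 33)
  # oracle: direct formula evaluation
  d <- v2 - v1
  ba <- bland_altman(v1, v2)
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-10)
  expect_equal(ba$mean_diff, 1)
  expect_equal(ba$sd_diff, sqrt(7), tolerance = 1e-10)
  expect_equal(ba$loa_half_width, 1.96 * sqrt(7), tolerance = 1e-10)
  expect_equal(ba$pooled_median, 19)
  expect_equal(ba$loa_pct_of_median, 100 * 1.96 * sqrt(7) / 19,
               tolerance = 1e-10)
  expect_equal(ba$n, 3L)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "3")
})

test_that("Bland-Altman behaves under translation and scaling", {
  set.seed(4)
  v1 <- rnorm(12, 50, 10); v2 <- v1 + rnorm(12, 1, 3)
  ba <- bland_altman(v1, v2)
  sh <- bland_altman(v1 + 7, v2 + 7)
  expect_equal(sh$mean_diff, ba$mean_diff, tolerance = 1e-10)
  expect_equal(sh$sd_diff, ba$sd_diff, tolerance = 1e-10)
  expect_equal(sh$pooled_median, ba$pooled_median + 7, tolerance = 1e-10)
  sc <- bland_altman(3 * v1, 3 * v2)
  expect_equal(sc$mean_diff, 3 * ba$mean_diff, tolerance = 1e-10)
  expect_equal(sc$sd_diff, 3 * ba$sd_diff, tolerance = 1e-10)
  expect_equal(sc$loa_pct_of_median, ba$loa_pct_of_median, tolerance = 1e-10)
  ident <- bland_altman(v1, v1)
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$loa_half_width, 0)
})

test_that("rANOVA SEM satisfies the two-occasion identity", {
  v1 <- c(10, 20, 30); v2 <- c(12, 18, 33)
  m <- mid_from_ranova(v1, v2)
  expect_equal(m$sem, sd(v2 - v1) / sqrt(2), tolerance = 1e-10)
  expect_equal(m$sem, sqrt(7) / sqrt(2), tolerance = 1e-10)
  expect_equal(m$mid, m$sem)
  # identity holds on arbitrary complete tables
  set.seed(6)
  for (i in 1:5) {
    a <- rnorm(8, 40, 12); b <- a + rnorm(8, 2, 5)
    expect_equal(mid_from_ranova(a, b)$sem, sd(b - a) / sqrt(2),
                 tolerance = 1e-10)
  }
  # subject-level offsets are absorbed by the subject effect
  k <- rnorm(8, 0, 30)
  a <- rnorm(8); b <- a + rnorm(8)
  expect_equal(mid_from_ranova(a + k, b + k)$mid, mid_from_ranova(a, b)$mid,
               tolerance = 1e-10)
  # identical visits -> MID 0
  expect_equal(mid_from_ranova(a, a)$mid, 0, tolerance = 1e-12)
  # configurable multiplier for smallest detectable change
  expect_equal(mid_from_ranova(a, b, multiplier = 1.96 * sqrt(2))$mid,
               1.96 * sqrt(2) * mid_from_ranova(a, b)$sem, tolerance = 1e-10)
})

test_that("Wilcoxon signed-rank: exact enumeration and zero policy", {
  # n = 3, all negative differences: 2 * P(all three signs negative) = 0.25
  w <- wilcoxon_signed_rank(c(-1, -1, -1))
  expect_equal(w$p_value, 0.25, tolerance = 1e-12)
  expect_equal(w$statistic, 0)
  expect_equal(w$method, "exact")
  # all-zero differences: p = 1 with a warning, not an error
  expect_warning(wz <- wilcoxon_signed_rank(rep(5, 4), rep(5, 4)), "zero")
  expect_equal(wz$p_value, 1)
  expect_equal(wz$n_zero_dropped, 4L)
  # zeros dropped, count logged
  w2 <- wilcoxon_signed_rank(c(0, 0, -1, 2, 3, -4, 5))
  expect_equal(w2$n_zero_dropped, 2L)
  expect_equal(w2$n_used, 5L)
})

test_that("Wilcoxon agrees with the reference implementation when tie-free", {
  set.seed(9)
  for (i in 1:5) {
    d <- round(rnorm(12, 0.5, 2), 3)
    d <- d[d != 0]
    if (length(unique(abs(d))) < length(d)) next
    ref <- wilcox.test(d, exact = TRUE)
    w <- wilcoxon_signed_rank(d)
    expect_equal(w$statistic, unname(ref$statistic))
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }
  # large-sample branch tracks the tie-corrected normal approximation
  set.seed(10)
  d <- round(rnorm(40, 0.4, 1), 1)
  d <- d[d != 0]
  w <- wilcoxon_signed_rank(d)
  ref <- wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(w$method, "normal_tie_corrected")
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman correlation: monotone extremes and tie handling", {
  x <- 1:10
  expect_equal(spearman_cor(x, 2 * x + 3)$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  # ties: matches the average-rank formula evaluated directly
  set.seed(11)
  a <- sample(1:5, 30, replace = TRUE)
  b <- a + sample(0:3, 30, replace = TRUE)
  expect_equal(spearman_cor(a, b)$rho, cor(rank(a), rank(b)),
               tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 10), 1:10), "undefined_correlation")
  expect_error(spearman_cor(1:3, 3:1), "4")
})

test_that("Pearson-Filon z is zero under equality and rejects bad input", {
  pf <- pearson_filon_z(0.5, 0.5, 0.3, 27)
  expect_equal(pf$z, 0)
  expect_equal(pf$p_value, 1)
  expect_error(pearson_filon_z(1, 0.5, 0.3, 27), "absolute value")
  expect_error(pearson_filon_z(0.5, 0.4, 0.3, 5))
  # larger separation gives larger |z| at fixed n and r_kh
  z1 <- abs(pearson_filon_z(0.6, 0.5, 0.4, 27)$z)
  z2 <- abs(pearson_filon_z(0.8, 0.3, 0.4, 27)$z)
  expect_gt(z2, z1)
})

test_that("Kruskal-Wallis: identical groups, closed form, rank invariance", {
  expect_equal(kruskal_wallis(list(1:5, 1:5, 1:5))$H, 0, tolerance = 1e-12)
  # two fully separated groups: H equals the closed-form maximum
  g1 <- 1:4; g2 <- 5:10
  n1 <- 4; n2 <- 6; N <- 10
  r1 <- sum(1:4); r2 <- sum(5:10)
  h_max <- 12 / (N * (N + 1)) * (r1^2 / n1 + r2^2 / n2) - 3 * (N + 1)
  expect_equal(kruskal_wallis(list(g1, g2))$H, h_max, tolerance = 1e-10)
  # invariance under strictly monotone transforms
  set.seed(13)
  a <- rnorm(8); b <- rnorm(9, 1)
  expect_equal(kruskal_wallis(list(a, b))$H,
               kruskal_wallis(list(exp(a), exp(b)))$H, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:5, 3)), "at least 2")
})

test_that("cohort report assembles agreement and association tables", {
  set.seed(14)
  n <- 10
  truth <- runif(n, 10, 50)
  mk <- function(noise) truth + rnorm(n, 0, noise)
  tbl <- rbind(
    data.frame(subject_id = sprintf("S%02d", 1:n), group = "A", visit = 1,
               qdp = mk(1), pbf = 60 - truth + rnorm(n, 0, 8),
               pbv = 6 - truth / 10 + rnorm(n, 0, 0.8),
               score = round(truth / 5), fev1_pct = 90 - truth),
    data.frame(subject_id = sprintf("S%02d", 1:n), group = "A", visit = 2,
               qdp = mk(1), pbf = 60 - truth + rnorm(n, 0, 8),
               pbv = 6 - truth / 10 + rnorm(n, 0, 0.8),
               score = round(truth / 5), fev1_pct = 90 - truth))
  rep1 <- cohort_report(tbl)
  expect_equal(nrow(rep1$agreement), 3)
  expect_setequal(rep1$agreement$metric, c("qdp", "pbf", "pbv"))
  expect_equal(nrow(rep1$correlations), 6)
  expect_equal(nrow(rep1$comparisons), 4)
  expect_length(rep1$excluded_subjects, 0)
  # shuffling rows leaves the report unchanged
  rep2 <- cohort_report(tbl[sample(nrow(tbl)), ])
  expect_equal(rep2$agreement, rep1$agreement)
  # a subject with a missing visit is excluded and reported
  tbl3 <- tbl[!(tbl$subject_id == "S03" & tbl$visit == 2), ]
  rep3 <- cohort_report(tbl3)
  expect_equal(rep3$excluded_subjects, "S03")
  expect_true(all(rep3$agreement$n == n - 1))
  # identical visits: all LoA and MID zero
  tbl4 <- tbl; tbl4$qdp[tbl4$visit == 2] <- tbl4$qdp[tbl4$visit == 1]
  rep4 <- suppressWarnings(cohort_report(tbl4, metrics = "qdp"))
  expect_equal(rep4$agreement$loa_half_width, 0)
  expect_equal(rep4$agreement$mid, 0, tolerance = 1e-10)
})
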