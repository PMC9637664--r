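#' Bland-Altman agreement analysis of two visits
#'
#' Differences are taken as `visit2 - visit1`. The limits of agreement are
#' `mean difference +/- 1.96 * SD` of the differences (sample SD, n-1
#' denominator); their half width is additionally expressed as a percentage
#' of the pooled median of all `2n` observations.
#'
#' @param visit1,visit2 Paired numeric vectors, `n >= 3`.
#' @return A list of class `agreement_result`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_half_width`, `loa_lower`, `loa_upper`, `pooled_median`,
#'   `loa_pct_of_median`.
#' @export
bland_altman <- function(visit1, visit2) {
  stopifnot(length(visit1) == length(visit2))
  ok <- is.finite(visit1) & is.finite(visit2)
  visit1 <- visit1[ok]; visit2 <- visit2[ok]
  n <- length(visit1)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- visit2 - visit1
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  loa <- 1.96 * sd_diff
  med <- median(c(visit1, visit2))
  structure(list(n = n, mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_half_width = loa,
                 loa_lower = mean_diff - loa, loa_upper = mean_diff + loa,
                 pooled_median = med,
                 loa_pct_of_median = 100 * loa / med),
            class = "agreement_result")
}

#' Minimal important difference from repeated-measures ANOVA
#'
#' Fits the two-way repeated-measures ANOVA (subject + visit) to the `2n`
#' observations; the standard error of measurement is `sqrt(MS_error)` and
#' the minimal important difference is `multiplier * SEM` (default
#' multiplier 1). With two occasions and the visit effect in the model the
#' identity `SEM = sd(diff) / sqrt(2)` holds exactly.
#'
#' @param visit1,visit2 Paired numeric vectors, `n >= 3`.
#' @param multiplier MID multiplier (1 for SEM itself; `1.96 * sqrt(2)`
#'   yields the smallest detectable change).
#' @return A list: `n`, `sem`, `ms_error`, `mid`, `pooled_median`,
#'   `mid_pct_of_median`.
#' @export
mid_from_ranova <- function(visit1, visit2, multiplier = 1) {
  stopifnot(length(visit1) == length(visit2))
  ok <- is.finite(visit1) & is.finite(visit2)
  visit1 <- visit1[ok]; visit2 <- visit2[ok]
  n <- length(visit1)
  if (n < 3) stop("need at least 3 complete pairs")
  long <- data.frame(y = c(visit1, visit2),
                     subject = factor(rep(seq_len(n), 2)),
                     visit = factor(rep(1:2, each = n)))
  fit <- aov(y ~ subject + visit, data = long)
  ms_error <- sum(fit$residuals^2) / fit$df.residual
  sem <- sqrt(ms_error)
  med <- median(c(visit1, visit2))
  list(n = n, sem = sem, ms_error = ms_error, mid = multiplier * sem,
       pooled_median = med, mid_pct_of_median = 100 * multiplier * sem / med)
}

#' Wilcoxon signed-rank test for paired visits
#'
#' Zero differences are dropped (Wilcoxon's original policy) and their count
#' reported. For `n <= 25` retained pairs the exact null distribution of the
#' positive-rank sum is computed by generating-function convolution over the
#' (possibly tied, average) ranks, so exact p-values are available under
#' ties as well; larger samples use the normal approximation with tie
#' correction.
#'
#' @param visit1,visit2 Paired numeric vectors, or `visit2 = NULL` to treat
#'   `visit1` as precomputed differences.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A list: `statistic` (V, positive-rank sum), `p_value`, `n_used`,
#'   `n_zero_dropped`, `method`.
#' @export
wilcoxon_signed_rank <- function(visit1, visit2 = NULL, exact_max = 25) {
  d <- if (is.null(visit2)) visit1 else visit2 - visit1
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; returning p = 1")
    return(list(statistic = 0, p_value = 1, n_used = 0,
                n_zero_dropped = n_zero, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of V: product of (1 + x^r_i)/2 over doubled ranks
    r2 <- round(2 * r)
    pmf <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), pmf)
      pmf <- c(pmf, rep(0, ri)) + shifted
    }
    pmf <- pmf / sum(pmf)
    v2 <- round(2 * v)
    p_le <- sum(pmf[seq_len(v2 + 1)])
    p_ge <- sum(pmf[(v2 + 1):length(pmf)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(statistic = v, p_value = p, n_used = n, n_zero_dropped = n_zero,
       method = method)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-approximation. Errors on constant input where the correlation is
#' undefined.
#'
#' @param x,y Numeric vectors, `n >= 4`.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined_correlation: constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Pearson-Filon z test for two overlapping dependent correlations
#'
#' Tests `r_jk = r_jh` for two correlations sharing the variable `j`
#' (e.g. two perfusion metrics correlated with the same clinical score),
#' using the classical Pearson-Filon (1898) statistic with the correlation
#' `r_kh` between the non-shared variables accounting for the dependence.
#'
#' @param r_jk,r_jh The two correlations sharing variable j.
#' @param r_kh Correlation between the non-shared variables k and h.
#' @param n Sample size (>= 10).
#' @return A list: `z`, `p_value`.
#' @export
pearson_filon_z <- function(r_jk, r_jh, r_kh, n) {
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1))
    stop("correlations must have absolute value < 1")
  stopifnot(n >= 10)
  k <- r_kh * (1 - r_jk^2 - r_jh^2) -
    0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  denom <- (1 - r_jk^2)^2 + (1 - r_jh^2)^2 - 2 * k
  z <- sqrt(n) * (r_jk - r_jh) / sqrt(denom)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value on `k - 1` degrees of
#' freedom.
#'
#' @param groups List of numeric vectors, each with `n >= 2`.
#' @return A list: `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 observations")
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Cohort-level reproducibility and association report
#'
#' Builds, from a long per-exam table, the tables behind a test-retest
#' reproducibility analysis: per group and metric the per-visit mean and SD,
#' the Wilcoxon signed-rank p-value, the limits of agreement (absolute and
#' as percent of the pooled median) and the minimal important difference;
#' pooled-visit Spearman correlations of each metric with each covariate
#' (with OLS slope/intercept for plot overlays); and Pearson-Filon
#' comparisons of the defect percentage's correlation against the other
#' metrics' correlations with the same covariate. Subjects missing a visit
#' are excluded (complete-case) and listed.
#'
#' @param per_exam Data frame with columns `subject_id`, `group`, `visit`
#'   (1/2), one column per metric, and the covariate columns.
#' @param metrics Character vector of metric column names.
#' @param covariates Character vector of covariate column names (constant
#'   within subject).
#' @param mid_multiplier Passed to [mid_from_ranova()].
#' @return A list of class `cohort_report` with data frames `agreement`,
#'   `correlations`, `comparisons` and the character vector
#'   `excluded_subjects`.
#' @export
cohort_report <- function(per_exam, metrics = c("qdp", "pbf", "pbv"),
                          covariates = c("score", "fev1_pct"),
                          mid_multiplier = 1) {
  stopifnot(all(c("subject_id", "group", "visit", metrics) %in%
                  names(per_exam)))
  covariates <- intersect(covariates, names(per_exam))
  complete <- function(df) {
    tab <- table(df$subject_id[!is.na(df[[metrics[1]]])], df$visit[!is.na(df[[metrics[1]]])])
    rownames(tab)[rowSums(tab > 0) == 2]
  }
  keep_ids <- complete(per_exam)
  excluded <- setdiff(unique(per_exam$subject_id), keep_ids)
  tbl <- per_exam[per_exam$subject_id %in% keep_ids, ]
  tbl <- tbl[order(tbl$group, tbl$subject_id, tbl$visit), ]

  agreement <- do.call(rbind, lapply(split(tbl, tbl$group), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      v1 <- g[[m]][g$visit == 1]; v2 <- g[[m]][g$visit == 2]
      ba <- bland_altman(v1, v2)
      mid <- mid_from_ranova(v1, v2, multiplier = mid_multiplier)
      wx <- wilcoxon_signed_rank(v1, v2)
      data.frame(group = g$group[1], metric = m, n = ba$n,
                 mean_visit1 = mean(v1), sd_visit1 = sd(v1),
                 mean_visit2 = mean(v2), sd_visit2 = sd(v2),
                 wilcoxon_p = wx$p_value,
                 mean_diff = ba$mean_diff,
                 loa_half_width = ba$loa_half_width,
                 loa_pct_of_median = ba$loa_pct_of_median,
                 mid = mid$mid, mid_pct_of_median = mid$mid_pct_of_median,
                 pooled_median = ba$pooled_median)
    }))
  }))
  rownames(agreement) <- NULL

  correlations <- NULL; comparisons <- NULL
  for (cov in covariates) {
    for (grp in unique(tbl$group)) {
      g <- tbl[tbl$group == grp, ]          # pooled visits 1 and 2
      rs <- list()
      for (m in metrics) {
        sp <- spearman_cor(g[[m]], g[[cov]])
        ols <- lm(g[[m]] ~ g[[cov]])
        rs[[m]] <- sp
        correlations <- rbind(correlations, data.frame(
          group = grp, metric = m, covariate = cov, n = sp$n,
          spearman_rho = sp$rho, spearman_p = sp$p_value,
          ols_intercept = unname(coef(ols)[1]),
          ols_slope = unname(coef(ols)[2])))
      }
      # dependent-correlation comparisons share the covariate variable;
      # computed on rank-transformed data, consistent with Spearman rho
      rk <- function(v) rank(v)
      for (m in setdiff(metrics, metrics[1])) {
        r_jk <- cor(rk(g[[cov]]), rk(g[[metrics[1]]]))
        r_jh <- cor(rk(g[[cov]]), rk(g[[m]]))
        r_kh <- cor(rk(g[[metrics[1]]]), rk(g[[m]]))
        pf <- pearson_filon_z(r_jk, r_jh, r_kh, nrow(g))
        comparisons <- rbind(comparisons, data.frame(
          group = grp, covariate = cov,
          metric_a = metrics[1], metric_b = m,
          r_a = r_jk, r_b = r_jh, z = pf$z, p_value = pf$p_value))
      }
    }
  }
  structure(list(agreement = agreement, correlations = correlations,
                 comparisons = comparisons,
                 excluded_subjects = excluded),
            class = "cohort_report")
}
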