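# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - theta_IVW)^2` over the per-SNP ratios with
#' fixed-effects IVW weights; chi-square with `k - 1` degrees of freedom
#' under homogeneity.
#'
#' @param set a `harmonized_set` with `k >= 2` SNPs.
#' @return list with `q`, `df`, `p`.
#' @export
cochran_q <- function(set) {
  k <- check_harmonized(set, 2, "cochran_q")
  rw <- ratio_weights(set)
  beta <- sum(rw$w * rw$theta) / sum(rw$w)
  q <- sum(rw$w * (rw$theta - beta)^2)
  list(q = q, df = k - 1L, p = pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept of [mr_egger()]: a nonzero intercept indicates
#' average directional pleiotropy across instruments. Two-sided t test
#' with `k - 2` degrees of freedom.
#'
#' @param set a `harmonized_set` with `k >= 3` SNPs.
#' @return list with `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(set) {
  e <- mr_egger(set)
  list(intercept = e$intercept, se = e$intercept_se, p = e$intercept_p)
}

# Leave-one-out IVW slopes for every SNP at once, via weighted sums.
loo_slopes <- function(bx, by, se_y) {
  w <- 1 / se_y^2
  s_xy <- sum(w * bx * by)
  s_xx <- sum(w * bx^2)
  (s_xy - w * bx * by) / (s_xx - w * bx^2)
}

#' MR-PRESSO global test and outlier detection
#'
#' Residual-based simulation test for horizontal pleiotropy. For each SNP
#' the leave-one-out IVW slope gives an expected outcome beta; the observed
#' residual sum of squares (inverse-variance standardized) is compared with
#' its distribution over `n_sim` parametric simulations in which outcome
#' betas are drawn about their leave-one-out expectations and exposure
#' betas about their observed values. Per-SNP squared residuals yield
#' empirical outlier p-values, declared outlying below a Bonferroni bar of
#' `0.05/k` by default; when outliers are found the fixed-effects IVW is
#' re-estimated without them. Empirical p-values use the `(1 + x)/(n + 1)`
#' estimator, so they are bounded below by `1/(n_sim + 1)`.
#'
#' @param set a `harmonized_set` with `k >= 4` SNPs.
#' @param n_sim number of simulated datasets (default 1000).
#' @param seed RNG seed (default 20240507).
#' @param outlier_alpha per-SNP declaration threshold; default `0.05 / k`.
#' @return A `presso_result`: `rss_obs`, `global_p`, `n_sim`, `outlier_p`
#'   (named per-SNP vector), `outliers`, `corrected` (re-estimated
#'   `mr_estimate` or `NULL`), `seed`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed = 20240507,
                      outlier_alpha = NULL) {
  k <- check_harmonized(set, 4, "mr_presso")
  if (is.null(outlier_alpha)) outlier_alpha <- 0.05 / k
  bx <- set$beta_x; by <- set$beta_y
  se_x <- set$se_x; se_y <- set$se_y
  w <- 1 / se_y^2

  theta_loo <- loo_slopes(bx, by, se_y)
  d_obs <- by - theta_loo * bx
  rss_obs <- sum(w * d_obs^2)

  sims <- with_seed(seed, {
    mu_y <- theta_loo * bx
    bxs <- matrix(rnorm(n_sim * k, rep(bx, each = n_sim),
                        rep(se_x, each = n_sim)), nrow = n_sim)
    bys <- matrix(rnorm(n_sim * k, rep(mu_y, each = n_sim),
                        rep(se_y, each = n_sim)), nrow = n_sim)
    # leave-one-out slopes within each simulated dataset, vectorized
    s_xy <- (bxs * bys) %*% w
    s_xx <- (bxs^2) %*% w
    wm <- matrix(w, nrow = n_sim, ncol = k, byrow = TRUE)
    th <- (as.vector(s_xy) - wm * bxs * bys) /
      (as.vector(s_xx) - wm * bxs^2)
    d <- bys - th * bxs
    list(rss = as.vector((d^2) %*% w), d2 = d^2)
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + colSums(sims$d2 >= matrix(d_obs^2, nrow = n_sim,
                                              ncol = k, byrow = TRUE))) /
    (n_sim + 1)
  names(outlier_p) <- set$snp_id
  outliers <- set$snp_id[outlier_p < outlier_alpha]

  corrected <- NULL
  if (length(outliers)) {
    keep <- !(set$snp_id %in% outliers)
    sub <- set[keep, , drop = FALSE]
    attr(sub, "outcome_type") <- attr(set, "outcome_type")
    corrected <- if (nrow(sub) >= 2) mr_ivw(sub, "fixed")
                 else if (nrow(sub) == 1) mr_wald_ratio(sub)
  }
  structure(list(rss_obs = rss_obs, global_p = global_p, n_sim = n_sim,
                 outlier_p = outlier_p, outliers = outliers,
                 outlier_alpha = outlier_alpha, corrected = corrected,
                 seed = seed),
            class = "presso_result")
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the fixed-effects IVW slope excluding each SNP in turn and
#' flags exclusions that change the sign of the estimate or move its
#' p-value across 0.05.
#'
#' @param set a `harmonized_set` with `k >= 3` SNPs.
#' @return Data frame with one row per excluded SNP: `snp_id, beta, se,
#'   pvalue, delta_beta, sign_change, p_crossing`.
#' @export
leave_one_out <- function(set) {
  k <- check_harmonized(set, 3, "leave_one_out")
  full <- mr_ivw(set, "fixed")
  rows <- lapply(seq_len(k), function(j) {
    sub <- set[-j, , drop = FALSE]
    attr(sub, "outcome_type") <- attr(set, "outcome_type")
    est <- if (nrow(sub) >= 2) mr_ivw(sub, "fixed") else mr_wald_ratio(sub)
    data.frame(snp_id = set$snp_id[j], beta = est$beta, se = est$se,
               pvalue = est$pvalue, delta_beta = est$beta - full$beta,
               sign_change = sign(est$beta) != sign(full$beta),
               p_crossing = (est$pvalue < 0.05) != (full$pvalue < 0.05),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precision (1/SE of the ratio), with
#' the IVW and (when `k >= 3`) MR-Egger slopes as reference lines; emitted
#' as a plain table for external plotting. Asymmetry of the scatter about
#' the IVW line suggests directional pleiotropy.
#'
#' @param set a `harmonized_set` with `k >= 2` SNPs.
#' @return Data frame `snp_id, ratio, precision` with attributes
#'   `ivw_beta` and `egger_beta`.
#' @export
funnel_data <- function(set) {
  k <- check_harmonized(set, 2, "funnel_data")
  theta <- set$beta_y / set$beta_x
  se_theta <- set$se_y / abs(set$beta_x)
  out <- data.frame(snp_id = set$snp_id, ratio = theta,
                    precision = 1 / se_theta, stringsAsFactors = FALSE)
  attr(out, "ivw_beta") <- mr_ivw(set, "fixed")$beta
  attr(out, "egger_beta") <- if (k >= 3) mr_egger(set)$beta else NA_real_
  out
}

#' Full sensitivity report for a harmonized set
#'
#' Bundles Cochran's Q, the MR-Egger intercept test (`k >= 3`), MR-PRESSO
#' (`k >= 4`), the leave-one-out table (`k >= 3`) and funnel data.
#'
#' @param set a `harmonized_set` with `k >= 2` SNPs.
#' @param n_sim,seed passed to [mr_presso()].
#' @return A `sensitivity_report` list with components `q`, `egger`,
#'   `presso`, `loo`, `funnel` (absent components are `NULL` when k is too
#'   small).
#' @export
sensitivity_report <- function(set, n_sim = 1000, seed = 20240507) {
  k <- nrow(set)
  structure(list(
    q = cochran_q(set),
    egger = if (k >= 3) egger_intercept_test(set),
    presso = if (k >= 4) mr_presso(set, n_sim = n_sim, seed = seed),
    loo = if (k >= 3) leave_one_out(set),
    funnel = funnel_data(set)),
    class = "sensitivity_report")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<mr_presso> RSS=%.4g, global p=%.4g (%d sims)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outliers))
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  else cat("  no outliers detected\n")
  invisible(x)
}
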