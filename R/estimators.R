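# Two-sample MR estimators on a harmonized exposure/outcome set.
#
# Throughout, theta_j = beta_y_j / beta_x_j is the per-SNP Wald ratio and
# w_j = beta_x_j^2 / se_y_j^2 its first-order inverse-variance weight
# (the exposure SE is ignored at first order, consistent with restricting
# to strong instruments).

check_harmonized <- function(set, k_min = 1, caller = "estimator") {
  stopifnot(inherits(set, "harmonized_set"))
  k <- nrow(set)
  if (k < k_min)
    stop(sprintf("%s requires at least %d SNP(s), got %d", caller, k_min, k))
  if (any(set$beta_x == 0))
    stop("beta_x = 0 for ", paste(set$snp_id[set$beta_x == 0],
                                  collapse = ", "),
         ": per-SNP ratio undefined")
  invisible(k)
}

ratio_weights <- function(set) {
  list(theta = set$beta_y / set$beta_x,
       w = set$beta_x^2 / set$se_y^2)
}

new_mr_estimate <- function(method, beta, se, k, df = NULL,
                            intercept = NULL, intercept_se = NULL,
                            outcome_type = "quantitative") {
  level <- 0.975
  if (is.null(df)) {
    crit <- qnorm(level)
    pvalue <- if (se > 0) 2 * pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  } else {
    crit <- qt(level, df)
    pvalue <- if (se > 0) 2 * pt(-abs(beta / se), df) else as.numeric(beta == 0)
  }
  est <- list(method = method, beta = beta, se = se,
              ci_low = beta - crit * se, ci_high = beta + crit * se,
              pvalue = pvalue, k = k, outcome_type = outcome_type)
  if (!is.null(intercept)) {
    est$intercept <- intercept
    est$intercept_se <- intercept_se
    est$intercept_p <- 2 * pt(-abs(intercept / intercept_se), df)
  }
  structure(est, class = "mr_estimate")
}

#' Wald ratio estimator (single instrument)
#'
#' For a single SNP the causal effect is `beta_y / beta_x` with the
#' first-order standard error `se_y / |beta_x|` (exposure uncertainty
#' ignored, the standard two-sample approximation for strong instruments);
#' the 95% CI and p-value use the normal distribution.
#'
#' @param set a `harmonized_set` with exactly one SNP.
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(set) {
  k <- check_harmonized(set, 1, "wald_ratio")
  if (k != 1) stop("wald_ratio is defined for a single instrument; use mr_ivw")
  new_mr_estimate("wald_ratio", set$beta_y / set$beta_x,
                  set$se_y / abs(set$beta_x), 1,
                  outcome_type = attr(set, "outcome_type"))
}

#' Inverse-variance weighted estimator
#'
#' Precision-weighted average of per-SNP Wald ratios, equivalently a
#' weighted regression of outcome on exposure betas through the origin.
#' The fixed-effects SE is `(sum w_j)^(-1/2)`; the multiplicative
#' random-effects variant scales it by `sqrt(max(1, Q/(k-1)))` where Q is
#' Cochran's heterogeneity statistic, leaving the point estimate unchanged.
#'
#' @param set a `harmonized_set` with `k >= 2` SNPs.
#' @param effects_model `"fixed"` (primary) or `"random"`.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(set, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  k <- nrow(set)
  if (k < 2)
    stop("mr_ivw requires k >= 2 SNPs; use mr_wald_ratio for a single instrument")
  check_harmonized(set, 2, "ivw")
  rw <- ratio_weights(set)
  beta <- sum(rw$w * rw$theta) / sum(rw$w)
  se <- 1 / sqrt(sum(rw$w))
  if (effects_model == "random") {
    q <- sum(rw$w * (rw$theta - beta)^2)
    se <- se * sqrt(max(1, q / (k - 1)))
  }
  new_mr_estimate(paste0("ivw_", effects_model), beta, se, k,
                  outcome_type = attr(set, "outcome_type"))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure betas with an
#' intercept, after orienting every SNP to a non-negative exposure beta
#' (both betas negated where needed; the fit is otherwise not invariant to
#' allele coding). Weights are `1/se_y^2`. The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Standard errors carry the residual scale factor
#' `max(1, sqrt(RSS/(k-2)))` (no super-precision from underdispersion);
#' p-values use the t distribution with `k - 2` degrees of freedom.
#'
#' @param set a `harmonized_set` with `k >= 3` SNPs.
#' @return An `mr_estimate` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(set) {
  k <- check_harmonized(set, 3, "mr_egger")
  s <- sign(set$beta_x)
  bx <- abs(set$beta_x)
  by <- set$beta_y * s
  w <- 1 / set$se_y^2
  X <- cbind(1, bx)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * by))
  res <- by - X %*% coef
  rss <- sum(w * res^2)
  scale <- max(1, sqrt(rss / (k - 2)))
  se_unit <- unname(sqrt(diag(solve(xtwx))))
  new_mr_estimate("egger", coef[2], se_unit[2] * scale, k, df = k - 2,
                  intercept = coef[1], intercept_se = se_unit[1] * scale,
                  outcome_type = attr(set, "outcome_type"))
}

# Weighted-median point estimate: cumulative-midpoint interpolation of the
# sorted ratios at probability 0.5.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

boot_resample <- function(set, n_boot, point_fun) {
  k <- nrow(set)
  bx <- matrix(rnorm(n_boot * k, mean = rep(set$beta_x, each = n_boot),
                     sd = rep(set$se_x, each = n_boot)), nrow = n_boot)
  by <- matrix(rnorm(n_boot * k, mean = rep(set$beta_y, each = n_boot),
                     sd = rep(set$se_y, each = n_boot)), nrow = n_boot)
  vapply(seq_len(n_boot), function(b) {
    theta <- by[b, ] / bx[b, ]
    w <- bx[b, ]^2 / set$se_y^2
    point_fun(theta, w)
  }, numeric(1))
}

#' Weighted median estimator
#'
#' Consistent when at least half of the weight comes from valid
#' instruments. The point estimate interpolates the sorted per-SNP ratios
#' across cumulative weight midpoints at 0.5; the SE is the standard
#' deviation of the estimate over `n_boot` parametric resamples of the
#' exposure and outcome betas about their observed values (seeded).
#'
#' @param set a `harmonized_set` with `k >= 3` SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (default 20240507).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 20240507) {
  k <- check_harmonized(set, 3, "weighted_median")
  rw <- ratio_weights(set)
  beta <- weighted_median_point(rw$theta, rw$w)
  se <- with_seed(seed, sd(boot_resample(set, n_boot, weighted_median_point)))
  new_mr_estimate("weighted_median", beta, se, k,
                  outcome_type = attr(set, "outcome_type"))
}

# Mode point estimate: argmax of the weighted normal-kernel density of the
# ratios on a fixed 512-point grid; ties broken toward the smaller theta.
mode_point <- function(theta, w, phi = 1, grid_n = 512) {
  # degenerate spread measures (all-equal values, or a majority atom that
  # zeroes the mad) fall back to whichever measure is informative
  spread <- c(sd(theta), mad(theta))
  spread <- spread[is.finite(spread) & spread > 0]
  if (!length(spread)) return(theta[1])
  h <- phi * 0.9 * min(spread) * length(theta)^(-1 / 5)
  wn <- w / sum(w)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = grid_n)
  dens <- colSums(wn * outer(theta, grid, function(t, x)
    dnorm((x - t) / h))) / h
  grid[which.max(dens)]
}

#' Mode-based estimators (weighted and simple)
#'
#' Estimates the causal effect as the mode of the kernel-smoothed density
#' of per-SNP ratios: consistent when the largest homogeneous cluster of
#' SNPs is valid. Bandwidth is `phi * 0.9 * min(sd, mad) * k^(-1/5)`
#' (`mad` with the usual 1.4826 normal-consistency constant); the density
#' is evaluated on a fixed 512-point grid spanning the ratios plus three
#' bandwidths, with argmax ties broken toward the smaller ratio. The
#' simple mode uses uniform weights, the weighted mode the IVW weights.
#' The SE comes from the same parametric bootstrap as the weighted median.
#'
#' @param set a `harmonized_set` with `k >= 3` SNPs.
#' @param weighted use inverse-variance weights (`TRUE`, the weighted mode)
#'   or uniform weights (`FALSE`, the simple mode).
#' @param phi bandwidth inflation factor (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (default 20240507).
#' @return An `mr_estimate` with method `"weighted_mode"` or
#'   `"simple_mode"`. When all ratios are identical the estimate is that
#'   ratio and the SE is 0.
#' @export
mr_mode <- function(set, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = 20240507) {
  k <- check_harmonized(set, 3, "mode")
  rw <- ratio_weights(set)
  wts <- if (weighted) rw$w else rep(1, k)
  beta <- mode_point(rw$theta, wts, phi)
  if (diff(range(rw$theta)) == 0) {
    se <- 0
  } else {
    pf <- if (weighted) function(t, w) mode_point(t, w, phi)
          else function(t, w) mode_point(t, rep(1, length(t)), phi)
    se <- with_seed(seed, sd(boot_resample(set, n_boot, pf)))
  }
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, k, outcome_type = attr(set, "outcome_type"))
}

#' Express an estimate on the odds-ratio scale
#'
#' Exponentiates the causal beta and its confidence bounds. Only valid
#' when the outcome betas are log-odds (binary outcome); applying it to a
#' quantitative outcome is refused.
#'
#' @param est an `mr_estimate` from a binary-outcome analysis.
#' @return The estimate with an `or_scale` component
#'   `(or, or_low, or_high)`; beta-scale fields are untouched.
#' @export
mr_to_or <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  if (!identical(est$outcome_type, "binary"))
    stop("odds-ratio scale is only defined for binary outcomes")
  est$or_scale <- c(or = exp(est$beta), or_low = exp(est$ci_low),
                    or_high = exp(est$ci_high))
  est
}

#' Run the full estimator suite on a harmonized set
#'
#' Applies the estimator policy: a single SNP gets the Wald ratio; with
#' `k >= 2` the fixed- and random-effects IVW are fitted, and with
#' `k >= 3` MR-Egger, weighted median, weighted mode and simple mode are
#' added as complements.
#'
#' @param set a `harmonized_set`.
#' @param n_boot,seed passed to the bootstrap-based estimators.
#' @return Named list of `mr_estimate` objects.
#' @export
mr_all <- function(set, n_boot = 1000, seed = 20240507) {
  k <- nrow(set)
  if (k == 1) return(list(wald_ratio = mr_wald_ratio(set)))
  out <- list(ivw_fixed = mr_ivw(set, "fixed"),
              ivw_random = mr_ivw(set, "random"))
  if (k >= 3) {
    out$egger <- mr_egger(set)
    out$weighted_median <- mr_weighted_median(set, n_boot, seed)
    out$weighted_mode <- mr_mode(set, TRUE, 1, n_boot, seed)
    out$simple_mode <- mr_mode(set, FALSE, 1, n_boot, seed)
  }
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (k=%d): beta=%.4g (95%% CI %.4g, %.4g), p=%.3g\n",
              x$method, x$k, x$beta, x$ci_low, x$ci_high, x$pvalue))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept=%.4g (se %.4g), p=%.3g\n", x$intercept,
                x$intercept_se, x$intercept_p))
  if (!is.null(x$or_scale))
    cat(sprintf("  OR=%.3f (95%% CI %.3f, %.3f)\n", x$or_scale["or"],
                x$or_scale["or_low"], x$or_scale["or_high"]))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, k = x$k, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = if (!is.null(x$or_scale)) x$or_scale[["or"]] else NA_real_,
             or_low = if (!is.null(x$or_scale)) x$or_scale[["or_low"]] else NA_real_,
             or_high = if (!is.null(x$or_scale)) x$or_scale[["or_high"]] else NA_real_,
             intercept = x$intercept %||% NA_real_,
             intercept_se = x$intercept_se %||% NA_real_,
             intercept_p = x$intercept_p %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Bind a list of estimates into one table
#' @param estimates list of `mr_estimate` objects.
#' @return A data frame with one row per method.
#' @export
mr_table <- function(estimates) {
  do.call(rbind, lapply(estimates, as.data.frame))
}
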