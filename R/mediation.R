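# Two-step mediation MR: screen mediators, estimate the exposure->mediator
# (a) and mediator->outcome (b) paths, and decompose the total effect (c)
# into an indirect (a*b) and a direct (c' = c - a*b) component with
# delta-method confidence intervals for the mediated proportion.

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 1400)  # 3.57e-5
#' bonferroni_threshold(0.05, 168)   # 2.98e-4
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m
}

#' Screen candidate mediators at a family-wise Bonferroni level
#'
#' @param step1 data frame with columns `mediator`, `beta`, `pvalue`
#'   (one row per candidate, from the exposure-to-mediator MR).
#' @param alpha family-wise level (default 0.05).
#' @return A `screen_result`: `n_tested`, `alpha_family`, `threshold`
#'   (`alpha / n_tested`), and `passing` (rows with `pvalue < threshold`).
#' @export
screen_mediators <- function(step1, alpha = 0.05) {
  stopifnot(is.data.frame(step1),
            all(c("mediator", "beta", "pvalue") %in% names(step1)),
            nrow(step1) >= 1)
  threshold <- bonferroni_threshold(alpha, nrow(step1))
  passing <- step1[!is.na(step1$pvalue) & step1$pvalue < threshold, ,
                   drop = FALSE]
  rownames(passing) <- NULL
  structure(list(n_tested = nrow(step1), alpha_family = alpha,
                 threshold = threshold, passing = passing),
            class = "screen_result")
}

as_effect <- function(x, label) {
  if (inherits(x, "mr_estimate")) return(list(beta = x$beta, se = x$se))
  if (is.list(x) && all(c("beta", "se") %in% names(x)))
    return(list(beta = x$beta, se = x$se))
  stop(label, " must be an mr_estimate or a list(beta, se)")
}

#' Mediation decomposition with delta-method confidence intervals
#'
#' Given the exposure-to-mediator effect `a`, the mediator-to-outcome
#' effect `b` and the total exposure-to-outcome effect `c`, the indirect
#' effect is `a * b` (product-of-coefficients) with first-order delta SE
#' `sqrt(a^2 se_b^2 + b^2 se_a^2)` (the two steps come from non-overlapping
#' samples, so their covariance is taken as zero), the direct effect is
#' `c - a*b`, and the proportion mediated is `a*b / c`. With
#' `include_c_uncertainty = TRUE` (the default) the proportion's delta SE
#' propagates the uncertainty in `c` as well:
#' `sqrt(se_ab^2 / c^2 + (ab)^2 se_c^2 / c^4)`; otherwise `c` is treated
#' as fixed and the SE is `se_ab / |c|`. All intervals are normal 95%.
#'
#' @param a_est,b_est,c_est `mr_estimate` objects (or `list(beta, se)`)
#'   for the a, b and total paths, all on the additive scale (log-odds for
#'   binary outcomes).
#' @param include_c_uncertainty propagate `se_c` into the proportion CI.
#' @param exposure,mediator,outcome trait labels carried into the result.
#' @return A `mediation_result` list: `a, se_a, b, se_b, c, se_c`,
#'   `indirect, se_indirect, indirect_low, indirect_high, p_indirect`,
#'   `direct`, `proportion, se_proportion, proportion_low, proportion_high`,
#'   and `flags` (contains `"inconsistent_mediation"` when
#'   `|proportion| > 1`, i.e. the indirect effect overshoots the total).
#'   `indirect + direct == c` and `proportion == indirect / c` hold exactly.
#' @export
mediate <- function(a_est, b_est, c_est, include_c_uncertainty = TRUE,
                    exposure = "exposure", mediator = "mediator",
                    outcome = "outcome") {
  a <- as_effect(a_est, "a_est"); b <- as_effect(b_est, "b_est")
  cc <- as_effect(c_est, "c_est")
  if (cc$beta == 0)
    stop("total effect c = 0: proportion mediated is undefined")
  z975 <- qnorm(0.975)

  indirect <- a$beta * b$beta
  se_ind <- sqrt(a$beta^2 * b$se^2 + b$beta^2 * a$se^2)
  p_ind <- if (se_ind > 0) 2 * pnorm(-abs(indirect / se_ind))
           else as.numeric(indirect == 0)
  direct <- cc$beta - indirect
  proportion <- indirect / cc$beta
  se_prop <- if (include_c_uncertainty)
    sqrt(se_ind^2 / cc$beta^2 + indirect^2 * cc$se^2 / cc$beta^4)
  else se_ind / abs(cc$beta)

  flags <- character()
  if (abs(proportion) > 1) {
    flags <- "inconsistent_mediation"
    warning("|proportion mediated| > 1: indirect effect exceeds the total",
            call. = FALSE)
  }
  structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    a = a$beta, se_a = a$se, b = b$beta, se_b = b$se,
    c = cc$beta, se_c = cc$se,
    indirect = indirect, se_indirect = se_ind,
    indirect_low = indirect - z975 * se_ind,
    indirect_high = indirect + z975 * se_ind,
    p_indirect = p_ind,
    direct = direct,
    proportion = proportion, se_proportion = se_prop,
    proportion_low = proportion - z975 * se_prop,
    proportion_high = proportion + z975 * se_prop,
    flags = flags), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation> %s -> %s -> %s\n", x$exposure, x$mediator,
              x$outcome))
  cat(sprintf("  a=%.4g  b=%.4g  c=%.4g  indirect=%.4g  direct=%.4g\n",
              x$a, x$b, x$c, x$indirect, x$direct))
  cat(sprintf("  proportion mediated %.1f%% (95%% CI %.1f%%, %.1f%%), p=%.3g\n",
              100 * x$proportion, 100 * x$proportion_low,
              100 * x$proportion_high, x$p_indirect))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(exposure = x$exposure, mediator = x$mediator,
             outcome = x$outcome, a = x$a, se_a = x$se_a, b = x$b,
             se_b = x$se_b, c = x$c, se_c = x$se_c, indirect = x$indirect,
             se_indirect = x$se_indirect, indirect_low = x$indirect_low,
             indirect_high = x$indirect_high, p_indirect = x$p_indirect,
             direct = x$direct, proportion = x$proportion,
             se_proportion = x$se_proportion,
             proportion_low = x$proportion_low,
             proportion_high = x$proportion_high,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

estimate_policy <- function(set) {
  if (nrow(set) == 1) mr_wald_ratio(set) else mr_ivw(set, "fixed")
}

#' Run the two-step mediation workflow
#'
#' Step 1 harmonizes the exposure instruments against every mediator panel,
#' estimates the exposure-to-mediator effect `a` (fixed-effects IVW, or the
#' Wald ratio for a single SNP) and screens the mediators at a Bonferroni
#' level over all candidates. Step 2 selects each passing mediator's own
#' instruments from its instrument-source panel with the same selection
#' rules (optionally excluding SNPs inside the exposure gene region to
#' limit pathway overlap), harmonizes them against the outcome, estimates
#' `b`, and applies a second Bonferroni screen over the step-2 tests. The
#' total effect `c` comes from the exposure instruments against the
#' outcome. One [mediate()] decomposition is emitted per step-1-passing
#' mediator, flagged with whether it also passes the step-2 screen.
#'
#' @param exposure_instruments an `instrument_set`.
#' @param mediator_panels named list of `summary_panel`s, one per
#'   candidate mediator (exposure-instrument lookups).
#' @param mediator_instrument_sources named list of `summary_panel`s used
#'   to select each mediator's own instruments (same names).
#' @param outcome_panel a `summary_panel`.
#' @param config list of knobs: `p_thresh` (1e-5), `window_kb` (10000),
#'   `r2_max` (0.001), `f_min` (10), `alpha` (0.05), `seed` (20240507),
#'   `ld` (optional [ld_matrix()]), `exclude_region` (optional gene
#'   region; step-2 instruments inside it are dropped),
#'   `include_c_uncertainty` (TRUE).
#' @return list with `c_est`, `screen1` (a `screen_result`),
#'   `step2_threshold`, `results` (list of `mediation_result`, one per
#'   mediator passing step 1, each with `p_b` and `pass_step2` fields),
#'   and `skipped` (mediators without usable instruments).
#' @export
run_two_step <- function(exposure_instruments, mediator_panels,
                         mediator_instrument_sources, outcome_panel,
                         config = list()) {
  stopifnot(inherits(exposure_instruments, "instrument_set"))
  cfg <- modifyList(list(p_thresh = 1e-5, window_kb = 10000, r2_max = 0.001,
                         f_min = 10, alpha = 0.05, seed = 20240507,
                         ld = NULL, exclude_region = NULL,
                         include_c_uncertainty = TRUE), config)
  stopifnot(length(mediator_panels) >= 1,
            !is.null(names(mediator_panels)))

  c_set <- harmonize(exposure_instruments, outcome_panel)
  c_est <- estimate_policy(c_set)

  step1 <- lapply(names(mediator_panels), function(nm) {
    est <- tryCatch(
      estimate_policy(harmonize(exposure_instruments, mediator_panels[[nm]])),
      error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(mediator = nm, beta = est$beta, se = est$se,
               pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  step1 <- do.call(rbind, step1[!vapply(step1, is.null, logical(1))])
  if (is.null(step1) || nrow(step1) == 0)
    stop("no mediator could be harmonized against the exposure instruments")
  screen1 <- screen_mediators(step1, alpha = cfg$alpha)

  passing <- screen1$passing$mediator
  step2_threshold <- if (length(passing))
    bonferroni_threshold(cfg$alpha, length(passing)) else NA_real_

  results <- list()
  skipped <- character()
  for (nm in passing) {
    src <- mediator_instrument_sources[[nm]]
    if (is.null(src)) { skipped <- c(skipped, nm); next }
    inst <- tryCatch({
      s <- select_instruments(src, p_thresh = cfg$p_thresh, ld = cfg$ld,
                              window_kb = cfg$window_kb,
                              r2_max = cfg$r2_max)
      s <- filter_weak(s, f_min = cfg$f_min)
      if (!is.null(cfg$exclude_region)) {
        reg <- as.list(cfg$exclude_region)
        lo <- as.numeric(reg$start); hi <- as.numeric(reg$end)
        inside <- !is.na(s$data$chrom) &
          s$data$chrom == as.character(reg$chrom) &
          !is.na(s$data$pos) & s$data$pos >= lo & s$data$pos <= hi
        s$data <- s$data[!inside, , drop = FALSE]
        s$f_stats <- s$f_stats[!inside]
      }
      s
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(inst) || nrow(inst$data) == 0) {
      skipped <- c(skipped, nm); next
    }
    b_est <- tryCatch(estimate_policy(harmonize(inst, outcome_panel)),
                      error = function(e) NULL)
    if (is.null(b_est)) { skipped <- c(skipped, nm); next }
    a_row <- screen1$passing[screen1$passing$mediator == nm, ]
    res <- mediate(list(beta = a_row$beta, se = a_row$se), b_est, c_est,
                   include_c_uncertainty = cfg$include_c_uncertainty,
                   exposure = exposure_instruments$exposure_name,
                   mediator = nm, outcome = outcome_panel$trait_name)
    res$p_a <- a_row$pvalue
    res$p_b <- b_est$pvalue
    res$pass_step2 <- !is.na(b_est$pvalue) && b_est$pvalue < step2_threshold
    results[[nm]] <- res
  }
  list(c_est = c_est, screen1 = screen1, step2_threshold = step2_threshold,
       results = results, skipped = skipped)
}
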