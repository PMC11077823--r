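# One-call orchestration of the full workflow: instrument selection ->
# strength filter -> harmonization -> estimation -> sensitivity (outlier
# removal, random-effects fallback) -> optional mediation, with per-stage
# TSV outputs and a line-oriented log.

pipeline_defaults <- function() {
  list(p_thresh = 1e-5, r2_max = 0.001, window_kb = 10000, f_min = 10,
       alpha = 0.05, het_alpha = 0.05, presso_nsim = 1000,
       n_boot = 1000, seed = 20240507, include_c_uncertainty = TRUE)
}

as_panel <- function(x, trait_type = "quantitative", name = NULL) {
  if (inherits(x, "summary_panel")) return(x)
  if (is.character(x)) return(read_panel(x, trait_name = name,
                                         trait_type = trait_type))
  stop("expected a summary_panel or a file path")
}

write_stage <- function(df, out_dir, name) {
  if (is.null(df) || is.null(out_dir)) return(invisible(NULL))
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num])
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.17g", df[[col]]))
  write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Run the full MR pipeline under one configuration
#'
#' Executes, in order: instrument selection (p-value threshold plus greedy
#' LD clumping), weak-instrument filtering, harmonization against the
#' outcome, estimation (Wald ratio when a single instrument remains,
#' otherwise the full suite with fixed-effects IVW as the primary method),
#' sensitivity analysis (Cochran's Q, Egger intercept, MR-PRESSO with
#' outlier removal and re-estimation, leave-one-out, funnel table), and —
#' when mediator panels are supplied — the two-step mediation analysis.
#' When heterogeneity persists (Q p-value below `het_alpha`) after outlier
#' removal, the reported primary estimate switches to the random-effects
#' IVW. Per-stage tables are written under `out_dir` (file contents are
#' deterministic under a fixed seed; timestamps go to the console only).
#'
#' @param config list (or path to a YAML file) with entries:
#'   `exposure` (path or `summary_panel`, or an `instrument_set` to skip
#'   selection), `outcome` (path or panel), `outcome_type`, optional `ld`
#'   (path or [ld_matrix()]), optional `mediators` and `mediator_sources`
#'   (named lists of paths/panels), optional `exclude_region`, `out_dir`,
#'   and the thresholds `p_thresh` (1e-5), `r2_max` (0.001), `window_kb`
#'   (10000), `f_min` (10), `alpha` (0.05), `het_alpha` (0.05),
#'   `presso_nsim` (1000), `n_boot` (1000), `seed` (20240507).
#' @param quiet suppress console progress lines.
#' @return A run report list: `instruments`, `harmonized`, `estimates`,
#'   `primary` (method label actually reported), `sensitivity`,
#'   `outliers_removed`, `mediation` (or `NULL`), `summary` (forest-style
#'   table), `log` (character vector of stage lines).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- modifyList(pipeline_defaults(), config)
  log_lines <- character()
  say <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
    if (!quiet) message(sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"),
                                stage, msg))
  }
  out_dir <- cfg$out_dir %||% NULL
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  ld <- cfg$ld
  if (is.character(ld)) ld <- read_ld(ld)
  cfg$ld <- ld

  # --- instruments -------------------------------------------------------
  if (inherits(cfg$exposure, "instrument_set")) {
    inst <- cfg$exposure
    say("instruments", sprintf("using %d pre-selected instrument(s)",
                               nrow(inst$data)))
  } else {
    exposure <- as_panel(cfg$exposure, name = "exposure")
    inst <- select_instruments(exposure, p_thresh = cfg$p_thresh, ld = ld,
                               window_kb = cfg$window_kb,
                               r2_max = cfg$r2_max)
    say("instruments", sprintf("selected %d instrument(s) at p < %g",
                               nrow(inst$data), cfg$p_thresh))
  }
  inst <- filter_weak(inst, f_min = cfg$f_min)
  say("filter_weak", sprintf("%d instrument(s) with F >= %g",
                             nrow(inst$data), cfg$f_min))
  if (nrow(inst$data) == 0) stop("pipeline aborted at filter_weak: no instruments")
  write_stage(cbind(inst$data, f_stat = unname(inst$f_stats)),
              out_dir, "instruments.tsv")
  write_stage(inst$selection_log, out_dir, "selection_log.tsv")

  # --- harmonize ---------------------------------------------------------
  outcome <- as_panel(cfg$outcome, trait_type = cfg$outcome_type %||%
                        "quantitative", name = "outcome")
  hset <- harmonize(inst, outcome)
  say("harmonize", sprintf("%d SNP(s) harmonized, %d palindromic removed",
                           nrow(hset),
                           length(attr(hset, "removed_palindromic"))))
  write_stage(as.data.frame(hset), out_dir, "harmonized.tsv")

  # --- estimate ----------------------------------------------------------
  estimates <- mr_all(hset, n_boot = cfg$n_boot, seed = cfg$seed)
  primary <- if (nrow(hset) == 1) "wald_ratio" else "ivw_fixed"
  say("estimate", sprintf("primary method %s, k = %d", primary, nrow(hset)))

  # --- sensitivity -------------------------------------------------------
  sens <- NULL
  outliers <- character()
  final_set <- hset
  if (nrow(hset) >= 2) {
    sens <- sensitivity_report(hset, n_sim = cfg$presso_nsim,
                               seed = cfg$seed)
    if (!is.null(sens$presso) && length(sens$presso$outliers)) {
      outliers <- sens$presso$outliers
      say("mr_presso", sprintf("removed outlier(s): %s; re-estimated",
                               paste(outliers, collapse = ", ")))
      keep <- !(hset$snp_id %in% outliers)
      final_set <- hset[keep, , drop = FALSE]
      attr(final_set, "outcome_type") <- attr(hset, "outcome_type")
      estimates <- mr_all(final_set, n_boot = cfg$n_boot, seed = cfg$seed)
      primary <- if (nrow(final_set) == 1) "wald_ratio" else "ivw_fixed"
    } else {
      say("mr_presso", if (is.null(sens$presso))
        "skipped (k < 4)" else "no outliers detected")
    }
    if (nrow(final_set) >= 2) {
      q_final <- cochran_q(final_set)
      if (q_final$p < cfg$het_alpha && nrow(final_set) >= 2) {
        primary <- "ivw_random"
        say("heterogeneity", sprintf(
          "Q p = %.3g persists after outlier removal: primary -> ivw_random",
          q_final$p))
      } else {
        say("heterogeneity", sprintf("Q p = %.3g", q_final$p))
      }
    }
    write_stage(data.frame(q = sens$q$q, q_df = sens$q$df, q_p = sens$q$p,
                           egger_intercept = sens$egger$intercept %||% NA_real_,
                           egger_intercept_p = sens$egger$p %||% NA_real_,
                           presso_global_p = if (!is.null(sens$presso))
                             sens$presso$global_p else NA_real_,
                           n_outliers = length(outliers)),
                out_dir, "sensitivity.tsv")
    if (!is.null(sens$loo)) write_stage(sens$loo, out_dir, "leave_one_out.tsv")
    write_stage(sens$funnel, out_dir, "funnel.tsv")
  } else {
    say("sensitivity", "skipped (single instrument)")
  }
  binary <- identical(attr(hset, "outcome_type"), "binary")
  if (binary) estimates <- lapply(estimates, mr_to_or)
  est_table <- mr_table(estimates)
  write_stage(est_table, out_dir, "estimates.tsv")

  # --- mediation ---------------------------------------------------------
  mediation <- NULL
  if (!is.null(cfg$mediators)) {
    med_panels <- lapply(names(cfg$mediators), function(nm)
      as_panel(cfg$mediators[[nm]], name = nm))
    names(med_panels) <- names(cfg$mediators)
    src_panels <- lapply(names(cfg$mediator_sources), function(nm)
      as_panel(cfg$mediator_sources[[nm]], name = nm))
    names(src_panels) <- names(cfg$mediator_sources)
    mediation <- run_two_step(inst, med_panels, src_panels, outcome,
                              config = cfg)
    say("mediation", sprintf("%d of %d mediator(s) pass the step-1 screen",
                             nrow(mediation$screen1$passing),
                             mediation$screen1$n_tested))
    if (length(mediation$results))
      write_stage(do.call(rbind, lapply(mediation$results, as.data.frame)),
                  out_dir, "mediation.tsv")
  }

  # --- summary -----------------------------------------------------------
  summary_tab <- est_table
  summary_tab$exposure <- inst$exposure_name
  summary_tab$outcome <- outcome$trait_name
  summary_tab$primary <- summary_tab$method == primary
  summary_tab <- summary_tab[c("exposure", "outcome", "method", "k", "beta",
                               "se", "ci_low", "ci_high", "pvalue", "or",
                               "or_low", "or_high", "primary")]
  write_stage(summary_tab, out_dir, "summary.tsv")
  if (!is.null(out_dir)) writeLines(log_lines, file.path(out_dir, "log.txt"))
  say("done", "pipeline complete")

  list(instruments = inst, harmonized = hset, estimates = estimates,
       primary = primary, sensitivity = sens, outliers_removed = outliers,
       mediation = mediation, summary = summary_tab, log = log_lines)
}
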