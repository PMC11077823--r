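# Synthetic three-trait GWAS summary statistics with known causal
# structure: a drug-target style exposure (biomarker-lowering scale), one
# or more mediators, and an outcome, on a shared SNP panel.
#
# Generating model, per SNP j:
#   exposure effect      gamma_j              (instruments only, else 0)
#   mediator effect      a * gamma_j          (exposure instruments)
#                        delta_j              (the mediator's own instruments)
#   outcome effect       (c' + a*b) * gamma_j + alpha_j   (exposure SNPs;
#                        alpha_j is horizontal pleiotropy on invalid SNPs,
#                        added to the outcome only, so InSIDE holds)
#                        b * delta_j          (mediator instruments)
# Observed betas are drawn normal about the truth with
# se = 1 / sqrt(2 * maf * (1 - maf) * n), independently per trait
# (the two-sample assumption).

NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"),
                             c("T", "C"), c("G", "A"), c("C", "A"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"),
                          c("G", "C"))

#' Configuration for the synthetic GWAS generator
#'
#' Defaults emulate the study conditions of a drug-target mediation
#' analysis: a large biomarker GWAS for the exposure (n = 344,182), a
#' moderately sized metabolite GWAS for mediators (n = 8,299), and an
#' imaging-scale outcome GWAS (n = 40,095), with per-SNP instrument
#' effects drawn uniformly from `[0.05, 0.15]` so that F statistics land
#' comfortably above the conventional bar of 10.
#'
#' @param k_x exposure instrument count (default 10).
#' @param k_m per-mediator instrument count (default 20).
#' @param n_x,n_m,n_y GWAS sample sizes for exposure, mediator(s), outcome.
#' @param theta total exposure-to-outcome effect; shorthand for
#'   `a = 0, b = 0, c_prime = theta`. Ignored when `a`/`b`/`c_prime` given.
#' @param a,b,c_prime mediation triple: exposure-to-mediator,
#'   mediator-to-outcome and direct effects (total effect
#'   `c = a*b + c_prime`).
#' @param pleiotropy list `fraction` (share of exposure instruments made
#'   invalid), `mean`, `sd` of the pleiotropic outcome offsets.
#' @param maf_range allele-frequency interval (default `[0.05, 0.5]`).
#' @param gamma_range per-SNP instrument-effect interval (default
#'   `[0.05, 0.15]`); widen downwards to inject weak instruments.
#' @param palindromic_rate fraction of SNPs given A/T or C/G allele pairs.
#' @param n_null_mediators additional mediators with `a = 0, b = 0`.
#' @param outcome_type `"quantitative"` or `"binary"` (binary reuses the
#'   quantitative SE model on the log-odds scale with `n_y` as effective
#'   sample size; not a case-control likelihood).
#' @param se_floor lower bound on every SE (set e.g. `1e-8` with huge `n`
#'   to emulate the noiseless limit).
#' @param seed RNG seed; a fixed seed makes the study bit-reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(k_x = 10, k_m = 20, n_x = 344182, n_m = 8299,
                       n_y = 40095, theta = NULL, a = NULL, b = NULL,
                       c_prime = NULL, pleiotropy = list(fraction = 0,
                                                         mean = 0, sd = 0),
                       maf_range = c(0.05, 0.5),
                       gamma_range = c(0.05, 0.15),
                       palindromic_rate = 0, n_null_mediators = 0,
                       outcome_type = c("quantitative", "binary"),
                       se_floor = 0, seed = 20240507) {
  outcome_type <- match.arg(outcome_type)
  if (is.null(a) && is.null(b) && is.null(c_prime)) {
    theta <- theta %||% 0.5
    a <- 0; b <- 0; c_prime <- theta
  } else {
    a <- a %||% 0; b <- b %||% 0; c_prime <- c_prime %||% 0
  }
  pl <- modifyList(list(fraction = 0, mean = 0, sd = 0), pleiotropy)
  stopifnot(k_x >= 1, k_m >= 1, n_x > 0, n_m > 0, n_y > 0,
            pl$fraction >= 0, pl$fraction <= 1, pl$sd >= 0,
            palindromic_rate >= 0, palindromic_rate <= 1,
            n_null_mediators >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5, se_floor >= 0)
  structure(list(k_x = k_x, k_m = k_m, n_x = n_x, n_m = n_m, n_y = n_y,
                 a = a, b = b, c_prime = c_prime, theta = a * b + c_prime,
                 pleiotropy = pl, maf_range = maf_range,
                 gamma_range = gamma_range,
                 palindromic_rate = palindromic_rate,
                 n_null_mediators = n_null_mediators,
                 outcome_type = outcome_type, se_floor = se_floor,
                 seed = seed),
            class = "sim_config")
}

nominal_se <- function(maf, n, floor = 0) {
  pmax(1 / sqrt(2 * maf * (1 - maf) * n), floor)
}

# Positions 20,000 kb apart on chromosomes cycling 1..22, so the default
# 10,000 kb clumping window never prunes independently simulated SNPs.
snp_coords <- function(n) {
  chrom <- as.character(rep_len(1:22, n))
  slot <- (seq_len(n) - 1) %/% 22
  list(chrom = chrom, pos = 1e6 + slot * 2e7 + (seq_len(n) - 1) %% 22)
}

#' Simulate a three-trait two-sample GWAS study
#'
#' Draws a shared SNP universe (exposure instruments, one "true" mediator's
#' instruments when `a` or `b` is nonzero, and instruments for any null
#' mediators), assigns true effects under the configured mediation model,
#' and emits observed summary panels with independent sampling noise per
#' trait. Pleiotropic offsets are added to the outcome associations of a
#' random subset of exposure instruments only, so the InSIDE assumption
#' holds by construction. Null mediators have `a = 0` (and no effect on
#' the outcome) but carry real instruments of their own.
#'
#' @param config a [sim_config()].
#' @return A `simulated_study`: `panels` (named list: `exposure`,
#'   `mediators` named list, `outcome`), `truth` (true effects, per-SNP
#'   `gamma`/`delta`, invalid SNP ids, true mediated proportion
#'   `a*b / (a*b + c_prime)`), and the `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    has_mediation <- cfg$a != 0 || cfg$b != 0
    n_med <- as.integer(has_mediation) + cfg$n_null_mediators
    med_names <- character()
    if (has_mediation) med_names <- "mediator1"
    if (cfg$n_null_mediators > 0)
      med_names <- c(med_names,
                     paste0("null_mediator", seq_len(cfg$n_null_mediators)))

    n_snp <- cfg$k_x + n_med * cfg$k_m
    ids <- sprintf("rs%05d", seq_len(n_snp))
    coords <- snp_coords(n_snp)
    maf <- runif(n_snp, cfg$maf_range[1], cfg$maf_range[2])
    pal <- runif(n_snp) < cfg$palindromic_rate
    pair_idx <- sample.int(length(NONPALINDROMIC_PAIRS), n_snp,
                           replace = TRUE)
    pal_idx <- sample.int(length(PALINDROMIC_PAIRS), n_snp, replace = TRUE)
    ea <- ifelse(pal, vapply(pal_idx, function(i) PALINDROMIC_PAIRS[[i]][1],
                             ""),
                 vapply(pair_idx, function(i) NONPALINDROMIC_PAIRS[[i]][1],
                        ""))
    oa <- ifelse(pal, vapply(pal_idx, function(i) PALINDROMIC_PAIRS[[i]][2],
                             ""),
                 vapply(pair_idx, function(i) NONPALINDROMIC_PAIRS[[i]][2],
                        ""))

    x_idx <- seq_len(cfg$k_x)
    gamma <- runif(cfg$k_x, cfg$gamma_range[1], cfg$gamma_range[2])
    med_idx <- list()
    delta <- list()
    for (m in seq_along(med_names)) {
      med_idx[[m]] <- cfg$k_x + (m - 1) * cfg$k_m + seq_len(cfg$k_m)
      delta[[m]] <- runif(cfg$k_m, cfg$gamma_range[1], cfg$gamma_range[2])
    }
    names(med_idx) <- names(delta) <- med_names

    # true per-SNP effects on each trait
    mu_x <- numeric(n_snp); mu_x[x_idx] <- gamma
    mu_m <- matrix(0, n_snp, max(1, n_med))
    for (m in seq_along(med_names)) {
      if (med_names[m] == "mediator1") mu_m[x_idx, m] <- cfg$a * gamma
      mu_m[med_idx[[m]], m] <- delta[[m]]
    }
    mu_y <- numeric(n_snp)
    mu_y[x_idx] <- cfg$theta * gamma
    if (has_mediation) mu_y[med_idx[["mediator1"]]] <-
      cfg$b * delta[["mediator1"]]

    n_invalid <- round(cfg$pleiotropy$fraction * cfg$k_x)
    invalid <- if (n_invalid > 0) sort(sample(x_idx, n_invalid)) else integer()
    alpha_j <- numeric(n_snp)
    if (n_invalid > 0) {
      alpha_j[invalid] <- rnorm(n_invalid, cfg$pleiotropy$mean,
                                cfg$pleiotropy$sd)
      mu_y[invalid] <- mu_y[invalid] + alpha_j[invalid]
    }

    make_panel <- function(mu, n, trait, type = "quantitative") {
      se <- nominal_se(maf, n, cfg$se_floor)
      beta <- rnorm(n_snp, mu, se)
      summary_panel(data.frame(
        snp_id = ids, chrom = coords$chrom, pos = coords$pos,
        effect_allele = ea, other_allele = oa, eaf = maf,
        beta = beta, se = se, pvalue = two_sided_p(beta, se),
        n = n, stringsAsFactors = FALSE),
        trait_name = trait, trait_type = type, check_pvalues = FALSE)
    }

    panels <- list(exposure = make_panel(mu_x, cfg$n_x, "exposure"))
    panels$mediators <- setNames(lapply(seq_along(med_names), function(m)
      make_panel(mu_m[, m], cfg$n_m, med_names[m])), med_names)
    panels$outcome <- make_panel(mu_y, cfg$n_y, "outcome",
                                 cfg$outcome_type)

    truth <- list(a = cfg$a, b = cfg$b, c_prime = cfg$c_prime,
                  theta = cfg$theta,
                  proportion = if (cfg$theta != 0)
                    cfg$a * cfg$b / cfg$theta else NA_real_,
                  gamma = setNames(gamma, ids[x_idx]),
                  delta = lapply(delta, function(d) d),
                  exposure_snps = ids[x_idx],
                  mediator_snps = lapply(med_idx, function(i) ids[i]),
                  invalid_snps = ids[invalid],
                  palindromic_snps = ids[pal])
    structure(list(panels = panels, truth = truth, config = cfg),
              class = "simulated_study")
  })
}

#' Simulate a harmonized exposure/outcome set directly
#'
#' A lightweight generator for estimator calibration loops: draws k
#' instrument effects, adds pleiotropic offsets to a subset of outcome
#' associations, and returns an already-harmonized set (no allele
#' bookkeeping). Uses the current RNG state — seed the caller.
#'
#' @param k instrument count.
#' @param theta true causal effect.
#' @param n_x,n_y exposure/outcome GWAS sample sizes.
#' @param maf_range,gamma_range as in [sim_config()].
#' @param pleio_fraction,pleio_mean,pleio_sd pleiotropy on the outcome:
#'   fraction of invalid SNPs and the offset distribution (balanced when
#'   `pleio_mean = 0`, directional otherwise; InSIDE holds).
#' @return A `harmonized_set` with attribute `truth` (list with `theta`
#'   and `invalid` indices).
#' @export
sim_harmonized <- function(k = 50, theta = 0.5, n_x = 344182, n_y = 40095,
                           maf_range = c(0.05, 0.5),
                           gamma_range = c(0.05, 0.15),
                           pleio_fraction = 0, pleio_mean = 0,
                           pleio_sd = 0) {
  maf <- runif(k, maf_range[1], maf_range[2])
  gamma <- runif(k, gamma_range[1], gamma_range[2])
  se_x <- nominal_se(maf, n_x)
  se_y <- nominal_se(maf, n_y)
  alpha <- numeric(k)
  n_invalid <- round(pleio_fraction * k)
  invalid <- if (n_invalid > 0) sample.int(k, n_invalid) else integer()
  if (n_invalid > 0) alpha[invalid] <- rnorm(n_invalid, pleio_mean, pleio_sd)
  set <- harmonized_set(beta_x = rnorm(k, gamma, se_x), se_x = se_x,
                        beta_y = rnorm(k, theta * gamma + alpha, se_y),
                        se_y = se_y)
  attr(set, "truth") <- list(theta = theta, invalid = invalid,
                             alpha = alpha, gamma = gamma)
  set
}

#' Write the deterministic fixture files used across module tests
#'
#' Emits small plain-text fixtures under `out_dir`: a 6-SNP clumping panel
#' with its LD matrix, a 3-SNP panel whose IVW estimate is exactly 0.2, a
#' 20-SNP planted-outlier harmonized set, a noiseless mediation triple of
#' panels, and a README listing the expected values. All files are
#' generated by fixed arithmetic (no RNG) and regenerate bit-identically.
#'
#' @param out_dir writable directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # 6-SNP clumping panel: snpA..snpF on chr1, pairwise LD below
  clump <- data.frame(
    snp_id = paste0("snp", LETTERS[1:6]), chrom = "1",
    pos = c(1e6, 1.005e6, 2e6, 2.004e6, 2.008e6, 9e7),
    effect_allele = c("A", "A", "C", "G", "A", "C"),
    other_allele = c("G", "C", "T", "A", "G", "A"),
    eaf = c(0.3, 0.3, 0.4, 0.4, 0.25, 0.2),
    beta = c(0.10, 0.08, 0.12, 0.11, 0.09, 0.07),
    se = c(0.010, 0.012, 0.011, 0.012, 0.013, 0.012),
    pvalue = c(1e-8, 1e-6, 1e-9, 1e-7, 2e-6, 1e-6),
    n = 10000, stringsAsFactors = FALSE)
  tsv(clump, "clump_panel.tsv")
  ids <- clump$snp_id
  r2 <- diag(6); dimnames(r2) <- list(ids, ids)
  r2["snpA", "snpB"] <- r2["snpB", "snpA"] <- 0.50
  r2["snpC", "snpD"] <- r2["snpD", "snpC"] <- 0.30
  r2["snpC", "snpE"] <- r2["snpE", "snpC"] <- 0.40
  r2["snpD", "snpE"] <- r2["snpE", "snpD"] <- 0.20
  tsv(data.frame(snp_id = ids, r2, check.names = FALSE), "clump_ld.tsv")

  # 3-SNP harmonized panel with all per-SNP ratios exactly 0.2
  ivw3 <- data.frame(snp_id = c("snp1", "snp2", "snp3"),
                     beta_x = c(0.3, 0.4, 0.5), se_x = c(0.01, 0.01, 0.01),
                     beta_y = c(0.06, 0.08, 0.10),
                     se_y = c(0.01, 0.01, 0.01), flip = FALSE,
                     stringsAsFactors = FALSE)
  tsv(ivw3, "ivw_exact.tsv")

  # 20-SNP planted-outlier harmonized set: theta = 0.5 throughout, SNP 20
  # carries a pleiotropic offset of 10 x its outcome SE
  bx <- 0.05 + 0.005 * (0:19)
  se_y <- rep(0.01, 20)
  by <- 0.5 * bx
  by[20] <- by[20] + 10 * se_y[20]
  outlier <- data.frame(snp_id = sprintf("rs%02d", 1:20), beta_x = bx,
                        se_x = 0.002, beta_y = by, se_y = se_y,
                        flip = FALSE, stringsAsFactors = FALSE)
  tsv(outlier, "outlier_set.tsv")

  # noiseless mediation triple: a = 0.5, b = 0.6, c' = 0.7 => c = 1.0,
  # proportion mediated exactly 30%. SNPs 1-4 instrument the exposure
  # (gamma), SNPs 5-8 the mediator (delta); the exposure gene region
  # [1, 7e7] on chr1 separates the two blocks so step-2 instrument
  # selection can exclude the exposure locus.
  a <- 0.5; b <- 0.6; c_tot <- a * 0.6 + 0.7
  gamma <- c(0.08, 0.10, 0.12, 0.14)
  delta <- c(0.09, 0.11, 0.13, 0.15)
  base <- data.frame(snp_id = sprintf("rs%02d", 1:8), chrom = "1",
                     pos = c(1e6 + (0:3) * 2e7, 1e8 + (0:3) * 2e7),
                     effect_allele = "A", other_allele = "G",
                     eaf = 0.3, se = 1e-8, n = 1e6,
                     stringsAsFactors = FALSE)
  med_triple <- function(beta, name) {
    d <- base
    d$beta <- beta
    d$pvalue <- pmax(2 * pnorm(-abs(d$beta / d$se)), .Machine$double.xmin)
    tsv(d[c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n")], name)
  }
  med_triple(c(gamma, rep(0, 4)), "mediation_exposure.tsv")
  med_triple(c(a * gamma, delta), "mediation_mediator.tsv")
  med_triple(c(c_tot * gamma, b * delta), "mediation_outcome.tsv")

  writeLines(c(
    "Deterministic fixtures (regenerated by mrmediate::make_fixtures).",
    "",
    "clump_panel.tsv + clump_ld.tsv: 6 SNPs; greedy clumping at",
    "  p < 1e-5, window 10,000 kb, r2 < 0.001 retains snpC, snpA, snpF",
    "  (snpB prunes to snpA at r2 = 0.5; snpD/snpE prune to snpC).",
    "ivw_exact.tsv: per-SNP ratios all 0.2, so the IVW estimate is 0.2",
    "  exactly and Cochran's Q = 0.",
    "outlier_set.tsv: theta = 0.5 with one planted pleiotropic SNP (rs20,",
    "  offset 10 x its outcome SE) for MR-PRESSO detection.",
    "mediation_*.tsv: noiseless triple with a = 0.5, b = 0.6, c' = 0.7,",
    "  so the total effect is 1.0 and the mediated proportion exactly 30%."),
    file.path(out_dir, "README.txt"))
  invisible(out_dir)
}

#' Write a simulated study to disk
#'
#' Emits one TSV per panel plus a `truth.json` record of the generating
#' effects.
#'
#' @param study a `simulated_study`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(study$panels$exposure, file.path(out_dir, "exposure.tsv"))
  for (nm in names(study$panels$mediators))
    write_panel(study$panels$mediators[[nm]],
                file.path(out_dir, paste0(nm, ".tsv")))
  write_panel(study$panels$outcome, file.path(out_dir, "outcome.tsv"))
  jsonlite::write_json(study$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
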