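# Instrument selection, strength filtering, cis (drug-target) restriction
# and exposure/outcome allele harmonization.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Construct an LD matrix object
#'
#' @param snp_ids character vector of SNP identifiers, one per row/column.
#' @param r2 square symmetric matrix of squared correlations in `[0, 1]`
#'   with unit diagonal.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from tab-separated text
#'
#' Two layouts are accepted: a square matrix whose first column and header
#' row hold SNP identifiers, or a long table with columns
#' `snp_a`, `snp_b`, `r2` (pairs absent from the long form are taken as
#' r2 = 0).
#'
#' @param path file path.
#' @return An `ld_matrix`.
#' @export
read_ld <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% tolower(names(raw)))) {
    names(raw) <- tolower(names(raw))
    ids <- sort(unique(c(raw$snp_a, raw$snp_b)))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(raw))) {
      m[raw$snp_a[i], raw$snp_b[i]] <- raw$r2[i]
      m[raw$snp_b[i], raw$snp_a[i]] <- raw$r2[i]
    }
    return(ld_matrix(ids, m))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  mode(m) <- "numeric"
  ld_matrix(ids, m)
}

ld_lookup <- function(ld, a, b) {
  if (is.null(ld)) return(NA_real_)
  if (!(a %in% ld$snp_ids) || !(b %in% ld$snp_ids)) return(0)
  ld$r2[a, b]
}

new_instrument_set <- function(exposure_name, data, selection_log) {
  f <- (data$beta / data$se)^2
  names(f) <- data$snp_id
  rownames(data) <- NULL
  structure(list(exposure_name = exposure_name, data = data, f_stats = f,
                 selection_log = selection_log),
            class = "instrument_set")
}

log_entry <- function(snp_id, action, reason) {
  data.frame(snp_id = snp_id, action = action, reason = reason,
             stringsAsFactors = FALSE)
}

#' Select independent genetic instruments by p-value and greedy LD clumping
#'
#' Candidates passing the significance threshold are sorted by ascending
#' p-value (ties broken by larger `|beta/se|`, then by identifier) and
#' clumped greedily: the best SNP is kept and any remaining SNP on the same
#' chromosome within `window_kb` whose squared correlation with a kept SNP
#' is at least `r2_max` is discarded; when no LD matrix is supplied the
#' clump degrades to distance-only pruning (one SNP per window).
#'
#' @param panel a `summary_panel` for the exposure trait.
#' @param p_thresh significance threshold (default `1e-5`).
#' @param ld optional [ld_matrix()]; pairs absent from it count as r2 = 0.
#' @param window_kb clumping window in kilobases (default 10,000).
#' @param r2_max LD ceiling: SNP pairs at or above this r2 cannot both be
#'   retained (default 0.001).
#' @return An `instrument_set`: exposure-side records of the retained SNPs,
#'   per-SNP F statistics `(beta/se)^2`, and a `selection_log` recording
#'   every keep/discard decision.
#' @export
select_instruments <- function(panel, p_thresh = 1e-5, ld = NULL,
                               window_kb = 10000, r2_max = 0.001) {
  stopifnot(inherits(panel, "summary_panel"))
  d <- panel$data
  logs <- list()
  pass <- !is.na(d$pvalue) & d$pvalue < p_thresh
  if (any(!pass))
    logs[[length(logs) + 1L]] <-
      log_entry(d$snp_id[!pass], "excluded", "p_above_threshold")
  cand <- d[pass, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no SNP passes p < ", format(p_thresh), call. = FALSE)
    return(new_instrument_set(panel$trait_name, cand,
                              do.call(rbind, logs) %||%
                                log_entry(character(), character(),
                                          character())))
  }
  z <- abs(cand$beta / cand$se)
  cand <- cand[order(cand$pvalue, -z, cand$snp_id), , drop = FALSE]

  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    logs[[length(logs) + 1L]] <- log_entry(cand$snp_id[i], "kept", "index_snp")
    for (j in seq_len(nrow(cand))) {
      if (!alive[j] || keep[j]) next
      same_chr <- !is.na(cand$chrom[i]) && !is.na(cand$chrom[j]) &&
        cand$chrom[i] == cand$chrom[j]
      near <- same_chr && !is.na(cand$pos[i]) && !is.na(cand$pos[j]) &&
        abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
      if (!near) next
      if (is.null(ld)) {
        alive[j] <- FALSE
        logs[[length(logs) + 1L]] <-
          log_entry(cand$snp_id[j], "discarded", "within_window_no_ld")
      } else if (ld_lookup(ld, cand$snp_id[i], cand$snp_id[j]) >= r2_max) {
        alive[j] <- FALSE
        logs[[length(logs) + 1L]] <-
          log_entry(cand$snp_id[j], "discarded",
                    paste0("r2_with_", cand$snp_id[i]))
      }
    }
  }
  new_instrument_set(panel$trait_name, cand[keep, , drop = FALSE],
                     do.call(rbind, logs))
}

#' Per-SNP instrument strength (F statistic)
#'
#' The summary-data approximation `F = (beta/se)^2`, i.e. the squared Wald
#' z of the SNP-exposure association. The sample-size-and-variance-explained
#' form is not computable from a single summary row; the squared-z form is
#' the standard surrogate and coincides with it for a single-SNP regression.
#'
#' @param beta SNP-exposure effect (or a `summary_panel` row's beta vector).
#' @param se its standard error (> 0).
#' @return F statistic(s), `(beta/se)^2`.
#' @export
#' @examples
#' f_statistic(2, 1)      # 4: weak, below the conventional F >= 10 bar
#' f_statistic(0.1, 0.013)
f_statistic <- function(beta, se) {
  if (any(se <= 0, na.rm = TRUE)) stop("se must be > 0")
  (beta / se)^2
}

#' Remove weak instruments from an instrument set
#'
#' @param set an `instrument_set`.
#' @param f_min minimum F statistic to retain (default 10, the conventional
#'   weak-instrument bar).
#' @return The filtered `instrument_set`; removals are appended to the
#'   selection log.
#' @export
filter_weak <- function(set, f_min = 10) {
  stopifnot(inherits(set, "instrument_set"))
  weak <- set$f_stats < f_min
  if (all(weak) && length(weak))
    warning("all instruments are weak (F < ", f_min, ")", call. = FALSE)
  logs <- set$selection_log
  if (any(weak))
    logs <- rbind(logs, log_entry(set$data$snp_id[weak], "discarded",
                                  paste0("F_below_", f_min)))
  out <- new_instrument_set(set$exposure_name,
                            set$data[!weak, , drop = FALSE], logs)
  out
}

#' Select cis (drug-target) instruments oriented to biomarker lowering
#'
#' Restricts a biomarker panel to a flanking window around the target gene,
#' optionally intersects with an eQTL panel (requiring expression
#' association below `eqtl_p`), clumps with [select_instruments()], and
#' finally re-orients every SNP so that a positive exposure beta is the
#' biomarker-LOWERING effect of the effect allele (the scale on which
#' pharmacological inhibition of the target is quantified): where the
#' coded allele raises the biomarker, the allele labels are swapped, the
#' beta negated and the EAF complemented.
#'
#' @param biomarker `summary_panel` of the biomarker GWAS (e.g. HbA1c).
#' @param gene_region list or vector with `chrom`, `start`, `end`
#'   (1-based inclusive); see [read_gene_region()] for BED input.
#' @param flank_kb window added on each side of the gene (default 100).
#' @param eqtl optional `summary_panel` of expression associations for the
#'   target gene.
#' @param eqtl_p expression-association threshold (default 1e-4).
#' @inheritParams select_instruments
#' @return An `instrument_set` on the biomarker-lowering scale.
#' @export
select_cis_instruments <- function(biomarker, gene_region, flank_kb = 100,
                                   eqtl = NULL, eqtl_p = 1e-4,
                                   p_thresh = 1e-5, ld = NULL,
                                   window_kb = 10000, r2_max = 0.001) {
  stopifnot(inherits(biomarker, "summary_panel"))
  region <- as.list(gene_region)
  lo <- as.numeric(region$start) - flank_kb * 1000
  hi <- as.numeric(region$end) + flank_kb * 1000
  d <- biomarker$data
  inside <- !is.na(d$chrom) & d$chrom == as.character(region$chrom) &
    !is.na(d$pos) & d$pos >= lo & d$pos <= hi
  logs <- list()
  if (any(!inside))
    logs[[1L]] <- log_entry(d$snp_id[!inside], "excluded", "outside_cis_window")
  sub <- biomarker
  sub$data <- d[inside, , drop = FALSE]
  if (!is.null(eqtl)) {
    e <- eqtl$data
    ok_ids <- e$snp_id[!is.na(e$pvalue) & e$pvalue < eqtl_p]
    drop <- !(sub$data$snp_id %in% ok_ids)
    if (any(drop))
      logs[[length(logs) + 1L]] <-
        log_entry(sub$data$snp_id[drop], "excluded", "no_eqtl_support")
    sub$data <- sub$data[!drop, , drop = FALSE]
  }
  if (nrow(sub$data) == 0)
    warning("no SNPs in the cis window", call. = FALSE)
  set <- select_instruments(sub, p_thresh = p_thresh, ld = ld,
                            window_kb = window_kb, r2_max = r2_max)

  # re-express on the lowering scale: lowering effect of the coded allele
  # is -beta; where negative, code the opposite allele instead
  dd <- set$data
  if (nrow(dd)) {
    lower <- -dd$beta
    swap <- lower < 0
    if (any(swap)) {
      tmp <- dd$effect_allele[swap]
      dd$effect_allele[swap] <- dd$other_allele[swap]
      dd$other_allele[swap] <- tmp
      dd$eaf[swap] <- 1 - dd$eaf[swap]
      lower[swap] <- -lower[swap]
      logs[[length(logs) + 1L]] <-
        log_entry(dd$snp_id[swap], "reoriented", "lowering_allele_coded")
    }
    dd$beta <- lower
  }
  logs <- do.call(rbind, c(list(set$selection_log), logs))
  new_instrument_set(paste0(set$exposure_name, "_lowering"), dd, logs)
}

#' Read a gene region from a BED-like file
#'
#' Expects three tab-separated columns (`chrom`, `start`, `end`) in the
#' BED convention (0-based, half-open); the returned region is converted
#' to 1-based inclusive coordinates (`start + 1`, `end`), the convention
#' used by summary-statistics positions throughout the package.
#'
#' @param path BED file path (no header, first record used).
#' @return list with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gene_region <- function(path) {
  raw <- read.delim(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  list(chrom = as.character(raw[1, 1]),
       start = as.numeric(raw[1, 2]) + 1,
       end = as.numeric(raw[1, 3]))
}

#' Construct a harmonized exposure/outcome set directly
#'
#' Builds the per-SNP table the estimators consume without going through
#' allele matching; used by the synthetic-data generator and tests.
#'
#' @param beta_x,se_x exposure effects and standard errors.
#' @param beta_y,se_y outcome effects and standard errors (same effect
#'   allele as the exposure).
#' @param snp_id identifiers (defaults to `snp1..snpk`).
#' @param flip logical flags marking SNPs whose outcome beta was negated
#'   during harmonization.
#' @param exposure,outcome trait labels.
#' @param outcome_type `"quantitative"` or `"binary"`.
#' @return A `harmonized_set` data frame with columns
#'   `snp_id, beta_x, se_x, beta_y, se_y, flip`.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y,
                           snp_id = paste0("snp", seq_along(beta_x)),
                           flip = rep(FALSE, length(beta_x)),
                           exposure = "exposure", outcome = "outcome",
                           outcome_type = "quantitative") {
  k <- length(beta_x)
  stopifnot(length(se_x) == k, length(beta_y) == k, length(se_y) == k,
            all(se_x > 0), all(se_y > 0))
  out <- data.frame(snp_id = snp_id, beta_x = beta_x, se_x = se_x,
                    beta_y = beta_y, se_y = se_y, flip = flip,
                    stringsAsFactors = FALSE)
  structure(out, class = c("harmonized_set", "data.frame"),
            exposure = exposure, outcome = outcome,
            outcome_type = outcome_type,
            removed_palindromic = character(),
            harmonization_log = log_entry(character(), character(),
                                          character()))
}

#' @export
`[.harmonized_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (at in c("exposure", "outcome", "outcome_type",
                 "removed_palindromic", "harmonization_log", "truth"))
      attr(out, at) <- attr(x, at)
    class(out) <- class(x)
  }
  out
}

#' Harmonize exposure instruments against an outcome panel
#'
#' Aligns outcome effects to the exposure's effect alleles. For each shared
#' SNP: identical allele pairs are kept as-is; swapped pairs have the
#' outcome beta negated; pairs matching only after strand complementation
#' (A<->T, C<->G) are complemented first and then treated the same way.
#' Palindromic SNPs (A/T or C/G pairs, whose strand cannot be resolved
#' from alleles alone) and irreconcilable ("ambiguous") pairs are removed
#' outright; SNPs absent from the outcome panel are dropped with a log
#' entry.
#'
#' @param exposure an `instrument_set`.
#' @param outcome a `summary_panel` for the outcome trait.
#' @return A `harmonized_set` (see [harmonized_set()]); attributes
#'   `removed_palindromic` and `harmonization_log` record exclusions.
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "instrument_set"),
            inherits(outcome, "summary_panel"))
  ex <- exposure$data
  oy <- outcome$data
  oy_idx <- match(ex$snp_id, oy$snp_id)

  rows <- vector("list", nrow(ex))
  logs <- list()
  removed_pal <- character()
  for (i in seq_len(nrow(ex))) {
    id <- ex$snp_id[i]
    j <- oy_idx[i]
    if (is.na(j)) {
      logs[[length(logs) + 1L]] <- log_entry(id, "dropped",
                                             "absent_from_outcome")
      next
    }
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    if (is_palindromic(e1, e2)) {
      removed_pal <- c(removed_pal, id)
      logs[[length(logs) + 1L]] <- log_entry(id, "removed", "palindromic")
      next
    }
    o1 <- oy$effect_allele[j]; o2 <- oy$other_allele[j]
    beta_y <- oy$beta[j]
    flip <- NA
    if (o1 == e1 && o2 == e2) {
      flip <- FALSE
    } else if (o1 == e2 && o2 == e1) {
      flip <- TRUE
    } else {
      o1c <- unname(COMPLEMENT[o1]); o2c <- unname(COMPLEMENT[o2])
      if (identical(o1c, e1) && identical(o2c, e2)) flip <- FALSE
      else if (identical(o1c, e2) && identical(o2c, e1)) flip <- TRUE
    }
    if (is.na(flip)) {
      logs[[length(logs) + 1L]] <- log_entry(id, "removed", "ambiguous")
      next
    }
    if (flip) beta_y <- -beta_y
    rows[[i]] <- data.frame(snp_id = id, beta_x = ex$beta[i],
                            se_x = ex$se[i], beta_y = beta_y,
                            se_y = oy$se[j], flip = flip,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("harmonization produced an empty set: no usable shared SNPs")
  rownames(out) <- NULL
  structure(out, class = c("harmonized_set", "data.frame"),
            exposure = exposure$exposure_name, outcome = outcome$trait_name,
            outcome_type = outcome$trait_type,
            removed_palindromic = removed_pal,
            harmonization_log = do.call(rbind, logs) %||%
              log_entry(character(), character(), character()))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d SNP(s)", x$exposure_name,
              nrow(x$data)))
  if (nrow(x$data))
    cat(sprintf(", F in [%.1f, %.1f]", min(x$f_stats), max(x$f_stats)))
  cat("\n")
  invisible(x)
}
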