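# Reading, validation and writing of GWAS summary-statistics panels.
#
# A panel holds one trait's per-SNP associations: identifier, location,
# allele pair, effect-allele frequency, additive effect (log-odds for binary
# traits), standard error, p-value and sample size. Panels are the input to
# every downstream step, so parsing is strict about the invariants the
# estimators rely on (distinct single-base alleles, positive SE) and lenient
# about fields some sources omit (EAF, N, p-value).

PANEL_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

# two-sided normal p for a Wald z, floored at the smallest normal double so
# that noiseless panels keep p in (0, 1]
two_sided_p <- function(beta, se) {
  pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
}

#' Column-name dialect for summary-statistics files
#'
#' Maps the canonical field names used throughout the package to the column
#' headers that may appear in a file. Defaults follow GWAS-SSF-style naming
#' with common aliases; any field can be overridden with the exact header
#' used by a particular source, e.g. `ssf_dialect(beta = "Effect", se = "StdErr")`.
#'
#' @param ... named character vectors overriding the accepted headers for
#'   individual canonical fields (`snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`).
#' @return A named list mapping canonical field names to accepted headers.
#' @export
#' @examples
#' d <- ssf_dialect(beta = "Effect")
#' d$beta
ssf_dialect <- function(...) {
  dialect <- list(
    snp_id        = c("snp_id", "rsid", "variant_id", "snp", "markername"),
    chrom         = c("chrom", "chromosome", "chr"),
    pos           = c("pos", "base_pair_location", "position", "bp"),
    effect_allele = c("effect_allele", "ea", "a1", "allele1"),
    other_allele  = c("other_allele", "oa", "a2", "allele2",
                      "non_effect_allele"),
    eaf           = c("eaf", "effect_allele_frequency", "freq", "maf"),
    beta          = c("beta", "effect", "b"),
    se            = c("se", "standard_error", "stderr"),
    pvalue        = c("pvalue", "p_value", "p", "pval"),
    n             = c("n", "sample_size", "n_total"))
  override <- list(...)
  bad <- setdiff(names(override), names(dialect))
  if (length(bad))
    stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
  for (nm in names(override)) dialect[[nm]] <- as.character(override[[nm]])
  dialect
}

#' Construct a summary panel from a data frame
#'
#' Wraps an in-memory table of per-SNP associations as a `summary_panel`,
#' applying the same row-level validation as [read_panel()]: rows with a
#' missing or unparseable identifier, allele or beta/SE, non-positive SE,
#' indel or identical alleles, out-of-range EAF or p-value, non-positive N,
#' or a duplicated identifier are dropped and counted in the parse report.
#' Missing p-values are filled from the two-sided normal test on beta/SE.
#'
#' @param data data frame with (a subset of) the canonical columns
#'   `snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pvalue, n`.
#'   `snp_id`, `effect_allele`, `other_allele`, `beta` and `se` are mandatory.
#' @param trait_name label for the trait.
#' @param trait_type `"quantitative"` or `"binary"` (betas on the log-odds
#'   scale).
#' @param check_pvalues warn when a reported p-value disagrees with the
#'   two-sided normal p implied by beta/SE by more than a factor of 10.
#' @return A `summary_panel`: list with `trait_name`, `trait_type`, `data`
#'   (validated data frame in canonical column order) and `report` (row
#'   counts and drop reasons).
#' @export
summary_panel <- function(data, trait_name = "trait",
                          trait_type = c("quantitative", "binary"),
                          check_pvalues = TRUE) {
  trait_type <- match.arg(trait_type)
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  n_read <- nrow(data)
  for (col in setdiff(PANEL_COLUMNS, names(data))) data[[col]] <- NA
  data <- data[PANEL_COLUMNS]

  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))

  reason <- rep(NA_character_, n_read)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(data$snp_id) | data$snp_id == "", "missing_snp_id")
  flag(is.na(data$beta), "unparseable_beta")
  flag(is.na(data$se), "unparseable_se")
  flag(data$se <= 0, "nonpositive_se")
  single <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  flag(!single(data$effect_allele) | !single(data$other_allele),
       "invalid_allele")
  flag(data$effect_allele == data$other_allele, "identical_alleles")
  flag(!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1), "eaf_out_of_range")
  flag(!is.na(data$pvalue) & (data$pvalue <= 0 | data$pvalue > 1),
       "pvalue_out_of_range")
  flag(!is.na(data$n) & data$n <= 0, "nonpositive_n")
  flag(duplicated(data$snp_id), "duplicate_snp_id")

  kept <- data[is.na(reason), , drop = FALSE]
  dropped <- data.frame(snp_id = data$snp_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)

  # fill missing p from the two-sided normal test, then cross-check reported p
  p_implied <- two_sided_p(kept$beta, kept$se)
  kept$pvalue[is.na(kept$pvalue)] <- p_implied[is.na(kept$pvalue)]
  n_warn_p <- 0L
  if (check_pvalues && nrow(kept)) {
    ratio <- kept$pvalue / p_implied
    discordant <- is.finite(ratio) & p_implied > 0 &
      (ratio > 10 | ratio < 0.1)
    n_warn_p <- sum(discordant)
    if (n_warn_p > 0)
      warning(sprintf(
        "%d SNP(s) have a reported p-value >10-fold discrepant with |beta/se| (e.g. %s)",
        n_warn_p, kept$snp_id[which(discordant)[1]]), call. = FALSE)
  }

  rownames(kept) <- NULL
  structure(list(
    trait_name = trait_name,
    trait_type = trait_type,
    data = kept,
    report = list(n_read = n_read, n_kept = nrow(kept),
                  n_dropped = nrow(dropped), dropped = dropped,
                  n_pvalue_warnings = n_warn_p)),
    class = "summary_panel")
}

#' Read a GWAS summary-statistics panel from a delimited file
#'
#' Accepts tab- or comma-separated files with a header row. Column headers
#' are matched case-insensitively against the `dialect` mapping. Rows that
#' violate hard invariants are dropped and counted in the parse report;
#' a missing `snp_id`, `effect_allele`, `other_allele`, `beta` or `se`
#' column is fatal.
#'
#' @param path file path.
#' @param trait_name label for the trait; defaults to the file base name.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param dialect column-name mapping from [ssf_dialect()].
#' @param check_pvalues see [summary_panel()].
#' @return A `summary_panel`; the parse report is in `$report`.
#' @seealso [write_panel()] for the inverse operation.
#' @export
read_panel <- function(path, trait_name = NULL,
                       trait_type = c("quantitative", "binary"),
                       dialect = ssf_dialect(), check_pvalues = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  lowered <- tolower(names(raw))
  out <- list()
  for (field in names(dialect)) {
    hit <- which(lowered %in% tolower(dialect[[field]]))
    if (length(hit)) out[[field]] <- raw[[hit[1]]]
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(out))
  if (length(missing_cols))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  summary_panel(df, trait_name = trait_name %||%
                  sub("\\.[^.]*$", "", basename(path)),
                trait_type = trait_type, check_pvalues = check_pvalues)
}

#' Write a summary panel to tab-separated text
#'
#' Numeric fields are serialized at full double precision (17 significant
#' digits) so that `read_panel(write_panel(p))` reproduces every field
#' bit-equal; missing values are written as `NA`.
#'
#' @param panel a `summary_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "summary_panel"))
  d <- panel$data
  out <- d
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    v <- d[[col]]
    out[[col]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write panel to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' @export
print.summary_panel <- function(x, ...) {
  cat(sprintf("<summary_panel> %s (%s): %d SNPs", x$trait_name,
              x$trait_type, nrow(x$data)))
  if (x$report$n_dropped > 0)
    cat(sprintf(" [%d row(s) dropped at parse]", x$report$n_dropped))
  cat("\n")
  invisible(x)
}

#' Number of SNP records in a panel
#' @param panel a `summary_panel`.
#' @return Integer count.
#' @export
n_snps <- function(panel) nrow(panel$data)
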