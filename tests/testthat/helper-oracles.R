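# Independent oracle implementations used to cross-check the package's
# estimators and clumper. Deliberately written as naive loops / stats-fit
# calls, not shared with the implementation.

oracle_wls_origin <- function(bx, by, se_y) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / se_y^2)
  unname(stats::coef(fit)[1])
}

oracle_egger <- function(bx, by, se_y) {
  s <- sign(bx)
  fit <- stats::lm(I(by * s) ~ I(abs(bx)), weights = 1 / se_y^2)
  sm <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       sigma = sm$sigma,
       se_unit = unname(sm$coefficients[, "Std. Error"] / sm$sigma))
}

oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- numeric(length(w))
  total <- 0
  for (j in seq_along(w)) {
    s[j] <- total + w[j] / 2
    total <- total + w[j]
  }
  below <- max(which(s < 0.5))
  theta[below] + (theta[below + 1] - theta[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

# same definition as the implementation's mode (512-point grid), computed
# with explicit loops
oracle_mode <- function(theta, w, phi = 1) {
  k <- length(theta)
  spread <- c(stats::sd(theta), stats::mad(theta))
  spread <- spread[is.finite(spread) & spread > 0]
  if (!length(spread)) return(theta[1])
  h <- phi * 0.9 * min(spread) * k^(-1 / 5)
  wn <- w / sum(w)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512)
  best <- grid[1]; best_d <- -Inf
  for (x in grid) {
    d <- 0
    for (j in seq_len(k)) d <- d + wn[j] * stats::dnorm((x - theta[j]) / h) / h
    if (d > best_d + 1e-15) { best_d <- d; best <- x }
  }
  best
}

# naive clumper over a plain data frame (snp_id, chrom, pos, beta, se, pvalue)
oracle_clump <- function(d, r2 = NULL, p_thresh = 1e-5, window_kb = 10000,
                         r2_max = 0.001) {
  cand <- d[d$pvalue < p_thresh, , drop = FALSE]
  if (nrow(cand) == 0) return(character())
  z <- abs(cand$beta / cand$se)
  cand <- cand[order(cand$pvalue, -z, cand$snp_id), , drop = FALSE]
  kept <- character()
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    kept <- c(kept, top$snp_id)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) == 0) break
    conflict <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      same <- cand$chrom[i] == top$chrom &&
        abs(cand$pos[i] - top$pos) <= window_kb * 1000
      if (!same) next
      if (is.null(r2)) conflict[i] <- TRUE
      else {
        rr <- if (top$snp_id %in% rownames(r2) &&
                  cand$snp_id[i] %in% rownames(r2))
          r2[top$snp_id, cand$snp_id[i]] else 0
        conflict[i] <- rr >= r2_max
      }
    }
    cand <- cand[!conflict, , drop = FALSE]
  }
  sort(kept)
}

# panel construction shorthand for tests
test_panel <- function(df, name = "trait", type = "quantitative") {
  summary_panel(df, trait_name = name, trait_type = type,
                check_pvalues = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small well-formed association table
basic_assoc <- function(n = 3) {
  if (n == 0) return(basic_assoc(1)[0, , drop = FALSE])
  data.frame(
    snp_id = paste0("rs", seq_len(n)),
    chrom = "1", pos = 1e6 * seq_len(n) * 30,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = seq(0.1, 0.3, length.out = n),
    se = rep(0.02, n),
    pvalue = 2 * stats::pnorm(-abs(seq(0.1, 0.3, length.out = n) / 0.02)),
    n = 10000, stringsAsFactors = FALSE)
}

# wrap a data frame as an instrument_set without selection
new_instrument_set_for_test <- function(df, name = "exposure") {
  mrmediate:::new_instrument_set(
    name, test_panel(df, name)$data,
    data.frame(snp_id = character(), action = character(),
               reason = character(), stringsAsFactors = FALSE))
}

fixtures_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "mrmediate-fixtures")
      make_fixtures(dir)
    }
    dir
  }
})

read_harmonized_fixture <- function(name, outcome_type = "quantitative") {
  d <- utils::read.delim(file.path(fixtures_dir(), name))
  harmonized_set(d$beta_x, d$se_x, d$beta_y, d$se_y, snp_id = d$snp_id,
                 outcome_type = outcome_type)
}
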