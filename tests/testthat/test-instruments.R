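test_that("per-SNP instrument strength is the squared Wald z", {
  expect_equal(f_statistic(2, 1), 4)
  expect_equal(f_statistic(0, 0.1), 0)
  # beta/se = 7.681 gives the F ~ 59 magnitude typical of a strong single
  # cis instrument
  expect_equal(f_statistic(7.681 * 0.1, 0.1), 59.0, tolerance = 1e-3)
  expect_error(f_statistic(1, 0), "se")
})

test_that("weak instruments are removed at the F threshold", {
  df <- basic_assoc(3)
  df$beta <- c(2, 4, 7.681) * df$se  # F = 4, 16, 59
  set <- select_instruments(test_panel(df), p_thresh = 1)
  strong <- filter_weak(set, f_min = 10)
  expect_equal(nrow(strong$data), 2)
  expect_true(all(strong$f_stats >= 10))
  expect_true(any(strong$selection_log$reason == "F_below_10"))
  # a set with min F = 16 passes unchanged
  expect_equal(nrow(filter_weak(strong, f_min = 10)$data), 2)
  # everything weak warns and empties the set
  expect_warning(empty <- filter_weak(set, f_min = 100), "weak")
  expect_equal(nrow(empty$data), 0)
})

test_that("greedy clumping keeps the most significant SNP of each cluster", {
  # single candidate below threshold
  df <- basic_assoc(2)
  df$pvalue <- c(1e-8, 1e-3)
  set <- select_instruments(test_panel(df), p_thresh = 1e-5)
  expect_equal(set$data$snp_id, "rs1")
  expect_true("p_above_threshold" %in% set$selection_log$reason)

  # two SNPs 5 kb apart at r2 = 0.5: only the smaller p survives
  df2 <- data.frame(snp_id = c("s1", "s2"), chrom = "1",
                    pos = c(1e6, 1.005e6), effect_allele = "A",
                    other_allele = "G", eaf = 0.3, beta = c(0.1, 0.08),
                    se = 0.01, pvalue = c(1e-8, 1e-6), n = 1e4)
  ld <- ld_matrix(c("s1", "s2"), matrix(c(1, .5, .5, 1), 2))
  set2 <- select_instruments(test_panel(df2), ld = ld)
  expect_equal(set2$data$snp_id, "s1")

  # the 6-SNP fixture resolves to snpA, snpC, snpF
  panel <- read_panel(file.path(fixtures_dir(), "clump_panel.tsv"),
                      check_pvalues = FALSE)
  ld6 <- read_ld(file.path(fixtures_dir(), "clump_ld.tsv"))
  set6 <- select_instruments(panel, ld = ld6)
  expect_setequal(set6$data$snp_id, c("snpA", "snpC", "snpF"))

  # no SNP passing the threshold warns and returns an empty set
  expect_warning(e <- select_instruments(test_panel(df2), p_thresh = 1e-20),
                 "no SNP")
  expect_equal(nrow(e$data), 0)
})

test_that("clumping matches the brute-force oracle on random small panels", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(3:8, 1)
    df <- data.frame(
      snp_id = paste0("v", sample(k)), chrom = as.character(sample(1:2, k,
                                                                   TRUE)),
      pos = sample(seq(1e6, 3e7, by = 1e5), k),
      effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = runif(k, 0.01, 0.2), se = runif(k, 0.005, 0.02),
      pvalue = 10^runif(k, -12, -3), n = 1e4, stringsAsFactors = FALSE)
    r2 <- matrix(runif(k * k), k)
    r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
    dimnames(r2) <- list(df$snp_id, df$snp_id)
    ld <- ld_matrix(df$snp_id, r2)
    got <- select_instruments(test_panel(df), p_thresh = 1e-5, ld = ld,
                              r2_max = 0.3)
    want <- oracle_clump(df, r2, p_thresh = 1e-5, r2_max = 0.3)
    expect_equal(sort(got$data$snp_id), want, info = paste("seed", seed))
    # invariant to input row order
    shuf <- df[sample(k), , drop = FALSE]
    got2 <- select_instruments(test_panel(shuf), p_thresh = 1e-5, ld = ld,
                               r2_max = 0.3)
    expect_setequal(got2$data$snp_id, got$data$snp_id)
  }
})

test_that("clumping degrades to one SNP per window without an LD matrix", {
  df <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "1",
                   pos = c(1e6, 2e6, 5e7), effect_allele = "A",
                   other_allele = "G", eaf = 0.3, beta = 0.1,
                   se = c(0.01, 0.012, 0.011),
                   pvalue = c(1e-9, 1e-7, 1e-8), n = 1e4)
  set <- select_instruments(test_panel(df))
  expect_setequal(set$data$snp_id, c("s1", "s3"))
  expect_true(any(set$selection_log$reason == "within_window_no_ld"))
})

test_that("cis selection restricts to the flank, honors the eQTL filter,
           and orients effects to the biomarker-lowering direction", {
  df <- data.frame(
    snp_id = c("in1", "in2", "out1"), chrom = "16",
    pos = c(31.48e6, 31.52e6, 35e6),
    effect_allele = c("A", "C", "A"), other_allele = c("G", "T", "G"),
    eaf = c(0.3, 0.4, 0.2),
    beta = c(0.02, -0.03, 0.05),      # in1 raises the biomarker, in2 lowers
    se = c(0.002, 0.003, 0.002),
    pvalue = c(1e-20, 1e-18, 1e-30), n = 344182, stringsAsFactors = FALSE)
  region <- list(chrom = "16", start = 31.49e6, end = 31.51e6)
  # in1/in2 sit 40 kb apart: supply their (negligible) LD so both survive
  # the clump
  ld <- ld_matrix(c("in1", "in2"), matrix(c(1, 1e-4, 1e-4, 1), 2))
  set <- select_cis_instruments(test_panel(df, "hba1c"), region,
                                flank_kb = 100, ld = ld)
  expect_setequal(set$data$snp_id, c("in1", "in2"))

  # the raising allele is re-coded: alleles swapped, beta now the positive
  # lowering effect, EAF complemented
  in1 <- set$data[set$data$snp_id == "in1", ]
  expect_equal(in1$effect_allele, "G")
  expect_equal(in1$other_allele, "A")
  expect_equal(in1$beta, 0.02)
  expect_equal(in1$eaf, 0.7)
  # the already-lowering allele keeps its coding with a positive beta
  in2 <- set$data[set$data$snp_id == "in2", ]
  expect_equal(in2$effect_allele, "C")
  expect_equal(in2$beta, 0.03)
  expect_true(all(set$data$beta > 0))

  # eQTL support required when an expression panel is supplied
  eqtl <- data.frame(snp_id = c("in1"), chrom = "16", pos = 31.48e6,
                     effect_allele = "A", other_allele = "G", eaf = 0.3,
                     beta = 0.1, se = 0.02, pvalue = 1e-6, n = 1000)
  set2 <- select_cis_instruments(test_panel(df, "hba1c"), region,
                                 flank_kb = 100,
                                 eqtl = test_panel(eqtl, "expression"))
  expect_equal(set2$data$snp_id, "in1")
})

test_that("BED regions convert from 0-based half-open to 1-based inclusive", {
  path <- tempfile(fileext = ".bed")
  writeLines("16\t31494323\t31500694", path)
  reg <- read_gene_region(path)
  expect_equal(reg$start, 31494324)
  expect_equal(reg$end, 31500694)
})

test_that("harmonization aligns, flips, complements, and removes
           palindromic or ambiguous SNPs", {
  ex <- basic_assoc(6)
  ex$effect_allele <- c("A", "A", "A", "A", "A", "A")
  ex$other_allele  <- c("G", "G", "G", "T", "G", "G")  # rs4 palindromic
  inst <- new_instrument_set_for_test(ex)
  oy <- ex
  oy$beta <- c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05)
  # rs1 same coding; rs2 swapped; rs3 strand-complemented; rs5 ambiguous;
  # rs6 absent from the outcome
  oy$effect_allele <- c("A", "G", "T", "A", "A", "A")
  oy$other_allele  <- c("G", "A", "C", "T", "C", "G")
  oy <- oy[oy$snp_id != "rs6", ]
  h <- harmonize(inst, test_panel(oy, "outcome"))
  expect_equal(h$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(h$beta_y, c(0.05, -0.05, 0.05))
  expect_equal(h$flip, c(FALSE, TRUE, FALSE))
  expect_equal(attr(h, "removed_palindromic"), "rs4")
  log <- attr(h, "harmonization_log")
  expect_equal(log$reason[log$snp_id == "rs5"], "ambiguous")
  expect_equal(log$reason[log$snp_id == "rs6"], "absent_from_outcome")
})

test_that("harmonization is involution-safe and estimates are invariant to
           outcome allele re-coding", {
  set.seed(42)
  ex <- basic_assoc(6)
  ex$beta <- runif(6, 0.05, 0.15)
  inst <- new_instrument_set_for_test(ex)
  oy <- ex
  oy$beta <- 0.5 * ex$beta + rnorm(6, 0, 0.01)
  oy$se <- rep(0.01, 6)
  h1 <- harmonize(inst, test_panel(oy, "outcome"))
  # already aligned: nothing flips, betas pass through
  expect_false(any(h1$flip))
  expect_equal(h1$beta_y, oy$beta)

  # randomly re-code outcome alleles (swap labels, negate beta): the
  # harmonized set and every per-SNP ratio are unchanged
  flip_rows <- c(2, 4, 5)
  oy2 <- oy
  oy2$effect_allele[flip_rows] <- oy$other_allele[flip_rows]
  oy2$other_allele[flip_rows] <- oy$effect_allele[flip_rows]
  oy2$beta[flip_rows] <- -oy$beta[flip_rows]
  oy2$eaf[flip_rows] <- 1 - oy$eaf[flip_rows]
  h2 <- harmonize(inst, test_panel(oy2, "outcome"))
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$beta_y / h2$beta_x, h1$beta_y / h1$beta_x)
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h1)$beta)
})

test_that("long-format LD input matches the square layout", {
  sq <- read_ld(file.path(fixtures_dir(), "clump_ld.tsv"))
  long <- data.frame(snp_a = c("snpA", "snpC", "snpC", "snpD"),
                     snp_b = c("snpB", "snpD", "snpE", "snpE"),
                     r2 = c(0.5, 0.3, 0.4, 0.2))
  path <- write_tsv(long)
  ll <- read_ld(path)
  for (pair in list(c("snpA", "snpB"), c("snpC", "snpD"), c("snpD", "snpE")))
    expect_equal(ll$r2[pair[1], pair[2]], sq$r2[pair[1], pair[2]])
  expect_equal(diag(ll$r2), setNames(rep(1, 5), ll$snp_ids))
})
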