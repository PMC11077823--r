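test_that("the Wald ratio and its first-order SE are exact arithmetic", {
  s <- harmonized_set(beta_x = 0.5, se_x = 0.01, beta_y = 0.2, se_y = 0.05)
  est <- mr_wald_ratio(s)
  expect_equal(est$beta, 0.4)
  expect_equal(est$se, 0.1)
  expect_equal(est$ci_low, 0.4 - qnorm(0.975) * 0.1)
  # zero numerator
  s0 <- harmonized_set(0.5, 0.01, 0, 0.05)
  expect_equal(mr_wald_ratio(s0)$beta, 0)
  # undefined denominator is fatal
  expect_error(mr_wald_ratio(harmonized_set(1e-300 * 0, 0.01, 0.1, 0.05)),
               "beta_x")
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  # exact case: all ratios 0.2
  s <- read_harmonized_fixture("ivw_exact.tsv")
  est <- mr_ivw(s)
  expect_equal(est$beta, 0.2)
  expect_equal(cochran_q(s)$q, 0)
  expect_equal(mr_ivw(s, "random")$se, est$se)  # Q = 0: no inflation
  expect_equal(est$se, 1 / sqrt(sum(s$beta_x^2 / s$se_y^2)))

  # random sets match the lm oracle to 1e-10
  for (seed in 1:10) {
    set.seed(seed)
    r <- sim_harmonized(k = sample(3:6, 1), theta = runif(1, -1, 1))
    expect_equal(mr_ivw(r)$beta,
                 oracle_wls_origin(r$beta_x, r$beta_y, r$se_y),
                 tolerance = 1e-10)
  }

  # contract: a single instrument is redirected to the Wald ratio
  s1 <- harmonized_set(0.5, 0.01, 0.2, 0.05)
  expect_error(mr_ivw(s1), "wald_ratio")
})

test_that("IVW point estimate is shared by fixed and random effects, with
           se_random >= se_fixed", {
  set.seed(7)
  s <- sim_harmonized(k = 20, theta = 0.3, pleio_fraction = 0.5,
                      pleio_mean = 0, pleio_sd = 0.05)
  f <- mr_ivw(s, "fixed"); r <- mr_ivw(s, "random")
  expect_equal(f$beta, r$beta)
  expect_gte(r$se, f$se)
})

test_that("MR-Egger matches the weighted-regression oracle and is affine
           equivariant in the intercept", {
  set.seed(11)
  s <- sim_harmonized(k = 5, theta = 0.4)
  est <- mr_egger(s)
  o <- oracle_egger(s$beta_x, s$beta_y, s$se_y)
  expect_equal(est$beta, o$slope, tolerance = 1e-10)
  expect_equal(est$intercept, o$intercept, tolerance = 1e-10)
  # SEs carry the residual scale truncated below at 1
  expect_equal(est$se, o$se_unit[2] * max(1, o$sigma), tolerance = 1e-8)

  # shifting every oriented outcome beta by +0.01 moves the intercept,
  # not the slope
  s2 <- s
  s2$beta_y <- s$beta_y + 0.01 * sign(s$beta_x)
  est2 <- mr_egger(s2)
  expect_equal(est2$intercept, est$intercept + 0.01, tolerance = 1e-10)
  expect_equal(est2$beta, est$beta, tolerance = 1e-10)

  # orientation: negating an instrument's allele coding changes nothing
  s3 <- s
  s3$beta_x[2] <- -s$beta_x[2]; s3$beta_y[2] <- -s$beta_y[2]
  expect_equal(mr_egger(s3)$beta, est$beta, tolerance = 1e-12)

  expect_error(mr_egger(s[1:2, ]), "at least 3")
})

test_that("with no pleiotropy and many SNPs the Egger intercept sits at 0", {
  set.seed(3)
  means <- replicate(60, mr_egger(sim_harmonized(k = 50))$intercept)
  # three Monte-Carlo standard errors of zero
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})

test_that("weighted median interpolates cumulative weight midpoints", {
  # equal weights: plain median
  s <- harmonized_set(c(1, 1, 1), rep(0.01, 3), c(1, 2, 9), rep(1, 3))
  expect_equal(mr_weighted_median(s, n_boot = 50)$beta, 2)

  # 4-SNP unequal weights: hand-computed interpolation = 3 + 0.05/0.35
  theta <- c(1, 2, 3, 4)
  w <- c(0.1, 0.2, 0.3, 0.4)
  se_y <- sqrt(1 / w)   # beta_x = 1 so w = 1/se_y^2
  s4 <- harmonized_set(rep(1, 4), rep(0.01, 4), theta, se_y)
  est <- mr_weighted_median(s4, n_boot = 50)
  expect_equal(est$beta, 3 + (0.5 - 0.45) / 0.35, tolerance = 1e-12)
  expect_equal(est$beta, oracle_weighted_median(theta, w), tolerance = 1e-12)

  # a SNP carrying nearly all weight dominates the estimate
  wdom <- c(0.996, 0.002, 0.002)
  sdom <- harmonized_set(rep(1, 3), rep(0.01, 3), c(0.7, 3, 9),
                         sqrt(1 / wdom))
  expect_equal(mr_weighted_median(sdom, n_boot = 50)$beta, 0.7,
               tolerance = 0.02)

  # bootstrap SE is seeded and reproducible
  e1 <- mr_weighted_median(s4, n_boot = 200, seed = 99)
  e2 <- mr_weighted_median(s4, n_boot = 200, seed = 99)
  expect_identical(e1$se, e2$se)
  expect_gt(e1$se, 0)
})

test_that("weighted median is (near-)invariant to duplicating every SNP", {
  set.seed(5)
  k <- 30
  theta <- rnorm(k, 0.5, 0.1)
  se_y <- runif(k, 0.05, 0.2)
  s <- harmonized_set(rep(1, k), rep(0.01, k), theta, se_y)
  sdup <- harmonized_set(rep(1, 2 * k), rep(0.01, 2 * k),
                         rep(theta, 2), rep(se_y, 2))
  expect_equal(mr_weighted_median(sdup, n_boot = 10)$beta,
               mr_weighted_median(s, n_boot = 10)$beta, tolerance = 0.02)
})

test_that("mode estimators find the dominant ratio cluster", {
  # outlier-resistant: mode stays with the 0.2 cluster
  s <- harmonized_set(rep(1, 4), rep(0.01, 4), c(0.2, 0.2, 0.2, 5),
                      rep(0.1, 4))
  expect_equal(mr_mode(s, n_boot = 20)$beta, 0.2, tolerance = 0.1)

  # equal weights: weighted and simple modes coincide
  set.seed(9)
  r <- sim_harmonized(k = 8, theta = 0.4)
  r$se_y <- rep(0.01, 8); r$beta_x <- rep(0.1, 8)
  expect_equal(mr_mode(r, weighted = TRUE, n_boot = 10)$beta,
               mr_mode(r, weighted = FALSE, n_boot = 10)$beta)

  # bimodal: 0.8 of the weight on the 1-cluster separates the two modes
  theta <- c(0, 0, 0, 1, 1)
  w <- c(0.2 / 3, 0.2 / 3, 0.2 / 3, 0.4, 0.4)
  sb <- harmonized_set(rep(1, 5), rep(0.01, 5), theta, sqrt(1 / w))
  wm <- mr_mode(sb, weighted = TRUE, n_boot = 10)$beta
  sm <- mr_mode(sb, weighted = FALSE, n_boot = 10)$beta
  expect_gt(wm, 0.5)   # weighted mode in the 1-cluster
  expect_lt(sm, 0.5)   # simple mode in the 0-cluster
  # both equal the dense-grid oracle within grid resolution
  expect_equal(wm, oracle_mode(theta, w), tolerance = 1e-6)
  expect_equal(sm, oracle_mode(theta, rep(1, 5)), tolerance = 1e-6)

  # all ratios identical: estimate exact, SE zero
  sid <- harmonized_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                        0.5 * c(0.1, 0.2, 0.3), rep(0.01, 3))
  mid <- mr_mode(sid, n_boot = 10)
  expect_equal(mid$beta, 0.5)
  expect_equal(mid$se, 0)
})

test_that("mode estimates match the independent grid oracle on random sets", {
  for (seed in 1:8) {
    set.seed(seed)
    r <- sim_harmonized(k = 6, theta = 0.5)
    rw <- list(theta = r$beta_y / r$beta_x, w = r$beta_x^2 / r$se_y^2)
    expect_equal(mr_mode(r, weighted = TRUE, n_boot = 10)$beta,
                 oracle_mode(rw$theta, rw$w), tolerance = 1e-6)
  }
})

test_that("odds-ratio conversion exponentiates the log-odds scale only", {
  s <- harmonized_set(c(0.1, 0.12, 0.15), rep(0.005, 3),
                      c(-0.18, -0.22, -0.28), rep(0.08, 3),
                      outcome_type = "binary")
  est <- mr_to_or(mr_ivw(s))
  expect_equal(unname(est$or_scale["or"]), exp(est$beta))
  expect_equal(unname(est$or_scale["or_low"]), exp(est$ci_low))
  # magnitudes as in a strong protective drug-target result
  fake <- structure(list(method = "ivw_fixed", beta = -1.826, se = 0.545,
                         ci_low = -2.900, ci_high = -0.764, pvalue = 8e-4,
                         k = 10, outcome_type = "binary"),
                    class = "mr_estimate")
  orr <- mr_to_or(fake)$or_scale
  expect_equal(unname(orr["or"]), 0.161, tolerance = 1e-3)
  expect_equal(unname(orr["or_low"]), 0.055, tolerance = 1e-2)
  expect_equal(unname(orr["or_high"]), 0.466, tolerance = 1e-3)
  # beta = 0 maps to OR = 1; larger beta, larger OR
  null <- fake; null$beta <- 0; null$ci_low <- 0; null$ci_high <- 0
  expect_equal(unname(mr_to_or(null)$or_scale["or"]), 1)
  expect_gt(unname(mr_to_or(fake)$or_scale["or_high"]),
            unname(mr_to_or(fake)$or_scale["or"]))
  # refused for quantitative outcomes
  q <- mr_ivw(read_harmonized_fixture("ivw_exact.tsv"))
  expect_error(mr_to_or(q), "binary")
})

test_that("estimators are equivariant to SNP reordering", {
  set.seed(21)
  s <- sim_harmonized(k = 8, theta = 0.4)
  perm <- sample(8)
  sp <- s[perm, ]
  expect_equal(mr_ivw(sp)$beta, mr_ivw(s)$beta)
  expect_equal(mr_egger(sp)$beta, mr_egger(s)$beta)
  expect_equal(mr_weighted_median(sp, n_boot = 10)$beta,
               mr_weighted_median(s, n_boot = 10)$beta)
  expect_equal(mr_mode(sp, n_boot = 10)$beta, mr_mode(s, n_boot = 10)$beta)
})

test_that("IVW with a single-SNP weight structure reduces to the Wald ratio", {
  # algebraic check: sum over one SNP collapses to beta_y/beta_x with
  # se = se_y/|beta_x|
  s <- harmonized_set(0.5, 0.01, 0.2, 0.05)
  w <- s$beta_x^2 / s$se_y^2
  expect_equal(sum(w * (s$beta_y / s$beta_x)) / sum(w),
               mr_wald_ratio(s)$beta)
  expect_equal(1 / sqrt(sum(w)), mr_wald_ratio(s)$se)
})

test_that("the estimator suite applies the k-based policy", {
  s1 <- harmonized_set(0.5, 0.01, 0.2, 0.05)
  expect_named(mr_all(s1), "wald_ratio")
  set.seed(2)
  s2 <- sim_harmonized(k = 2)
  expect_named(mr_all(s2), c("ivw_fixed", "ivw_random"))
  s5 <- sim_harmonized(k = 5)
  expect_setequal(names(mr_all(s5, n_boot = 10)),
                  c("ivw_fixed", "ivw_random", "egger", "weighted_median",
                    "weighted_mode", "simple_mode"))
})
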