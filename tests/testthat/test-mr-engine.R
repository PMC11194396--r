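test_that("Wald ratio matches the delta-method hand evaluation", {
  null <- wald_ratio(make_harm(0.5, 0.02, 0, 0.1))
  expect_equal(null$beta, 0)
  expect_equal(null$or_, 1)

  x <- make_harm(beta_exp = 1, se_exp = 0.02, beta_out = 0.5, se_out = 0.1)
  est <- wald_ratio(x)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$or_, exp(0.5), tolerance = 1e-12)
  expect_equal(est$or_, 1.6487, tolerance = 1e-4)
  expect_equal(est$ci_low, exp(0.5 - 1.959964 * 0.1), tolerance = 1e-12)
  expect_equal(est$ci_high, exp(0.5 + 1.959964 * 0.1), tolerance = 1e-12)
  expect_equal(est$ci_high, 2.0056, tolerance = 1e-4)
  expect_equal(est$pval, 2 * pnorm(-5), tolerance = 1e-12)

  # sign symmetry: negating the exposure effect negates the estimate only
  neg <- wald_ratio(make_harm(-1, 0.02, 0.5, 0.1))
  expect_equal(neg$beta, -0.5)
  expect_equal(neg$se, est$se)
  expect_equal(neg$pval, est$pval)

  expect_error(wald_ratio(make_harm(0, 0.02, 0.5, 0.1)),
               class = "targetmr_domain_error")

  so <- wald_ratio(x, second_order = TRUE)
  expect_gt(so$se, est$se)
})

test_that("IVW equals the analytic weighted mean of per-SNP ratios", {
  # degenerate consensus: identical ratios give the ratio back
  x <- make_harm(c(1, 2), c(0.02, 0.02), c(0.3, 0.6), c(0.1, 0.3))
  expect_equal(ivw(x, mode = "fixed")$beta, 0.3, tolerance = 1e-12)

  # hand oracle: ratios 0.2 and 0.4 with equal ratio SEs 0.1
  y <- make_harm(c(1, 1), c(0.02, 0.02), c(0.2, 0.4), c(0.1, 0.1))
  fe <- ivw(y, mode = "fixed")
  expect_equal(fe$beta, 0.3, tolerance = 1e-12)
  expect_equal(fe$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(fe$se, 0.070711, tolerance = 1e-5)

  # random instances against weighted.mean
  withr::local_seed(7)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    z <- make_harm(stats::runif(k, 0.2, 1.5) * sample(c(-1, 1), k, TRUE),
                   stats::runif(k, 0.01, 0.1),
                   stats::rnorm(k, 0, 0.3),
                   stats::runif(k, 0.02, 0.2))
    r <- z$beta_out / z$beta_exp
    s <- z$se_out / abs(z$beta_exp)
    w <- 1 / s^2
    expect_equal(ivw(z, mode = "fixed")$beta,
                 stats::weighted.mean(r, w), tolerance = 1e-12)
    expect_equal(ivw(z, mode = "fixed")$se, sqrt(1 / sum(w)),
                 tolerance = 1e-12)
  }
  expect_error(ivw(y[1, ]), class = "targetmr_domain_error")
})

test_that("multiplicative random effects never deflate the fixed-effect SE", {
  withr::local_seed(11)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    z <- make_harm(stats::runif(k, 0.2, 1.5),
                   stats::runif(k, 0.01, 0.1),
                   stats::rnorm(k, 0.1, 0.2),
                   stats::runif(k, 0.02, 0.2))
    fe <- ivw(z, mode = "fixed")
    mre <- ivw(z, mode = "multiplicative_random")
    expect_gte(mre$se, fe$se)
    expect_equal(mre$beta, fe$beta, tolerance = 1e-12)
    q <- cochran_q(z)
    if (q$q <= k - 1) expect_equal(mre$se, fe$se, tolerance = 1e-12)
    else expect_gt(mre$se, fe$se)
  }
})

test_that("Cochran's Q matches the hand chi-square evaluation", {
  same <- make_harm(c(1, 1), c(0.02, 0.02), c(0.3, 0.3), c(0.1, 0.1))
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0, tolerance = 1e-12)
  expect_equal(q0$q_pval, 1)

  y <- make_harm(c(1, 1), c(0.02, 0.02), c(0.2, 0.4), c(0.1, 0.1))
  q <- cochran_q(y)
  expect_equal(q$q, 2.0, tolerance = 1e-12)
  expect_equal(q$q_df, 1)
  expect_equal(q$q_pval, 0.1573, tolerance = 1e-4)

  # scale symmetry: rescaling all ratios and SEs leaves Q unchanged
  y2 <- y
  y2$beta_out <- y2$beta_out * 3.7
  y2$se_out <- y2$se_out * 3.7
  expect_equal(cochran_q(y2)$q, q$q, tolerance = 1e-12)
  expect_error(cochran_q(y[1, ]), class = "targetmr_domain_error")
})

test_that("Egger intercept equals the independent WLS solve", {
  # exact proportionality: intercept 0
  x <- make_harm(c(0.5, 1, 1.5), c(0.02, 0.02, 0.02),
                 0.4 * c(0.5, 1, 1.5), c(0.1, 0.12, 0.15))
  e <- suppressWarnings(egger_intercept(x))
  expect_true(e$computable)
  expect_equal(e$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(e$egger_slope, 0.4, tolerance = 1e-10)

  # constant additive offset on the outcome appears as the intercept
  y <- x
  y$beta_out <- y$beta_out + 0.1
  e2 <- suppressWarnings(egger_intercept(y))
  expect_equal(e2$egger_intercept, 0.1, tolerance = 1e-10)

  # random instances against the normal-equations oracle (with the
  # positive-exposure orientation applied first)
  withr::local_seed(13)
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    z <- make_harm(stats::rnorm(k, 0, 0.8), stats::runif(k, 0.01, 0.1),
                   stats::rnorm(k, 0, 0.3), stats::runif(k, 0.02, 0.2))
    z <- z[z$beta_exp != 0, ]
    flip <- sign(z$beta_exp)
    oracle <- wls_oracle(z$beta_out * flip, z$beta_exp * flip,
                         1 / z$se_out^2)
    got <- egger_intercept(z)
    expect_equal(got$egger_intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(got$egger_intercept_se, oracle$intercept_se,
                 tolerance = 1e-10)
    expect_equal(got$egger_slope, oracle$slope, tolerance = 1e-10)
  }

  few <- egger_intercept(x[1:2, ])
  expect_false(few$computable)
  expect_true(is.na(few$egger_intercept))
})

test_that("Steiger filter applies the strict variance-explained criterion", {
  # r2_exp 0.02 vs r2_out ~ 0.001: retained
  strong <- make_harm(1, 0.02, 0.05, 0.02, n_exp = 2449, n_out = 50000)
  r2e <- compute_pve(strong$beta_exp, strong$se_exp, strong$n_exp)
  expect_equal(r2e, 0.505, tolerance = 0.01)
  res <- steiger_filter(strong)
  expect_true(res$steiger$correct_direction)
  expect_equal(nrow(res$instruments), 1)

  # boundary: equal variance explained is removed (strict inequality)
  x <- make_harm(0.1, 0.02, 0.1, 0.02, n_exp = 10000, n_out = 10000)
  z <- 0.1 / 0.02
  expect_equal(compute_pve(0.1, 0.02, 10000), z^2 / (z^2 + 10000))
  eq <- steiger_filter(x)
  expect_false(eq$steiger$correct_direction)
  expect_equal(nrow(eq$instruments), 0)

  # reversed signal: outcome explains more
  rev <- steiger_filter(make_harm(0.02, 0.01, 0.5, 0.01,
                                  n_exp = 50000, n_out = 50000))
  expect_false(rev$steiger$correct_direction)
  expect_true(rev$steiger$steiger_pval < 1e-10)

  empty <- steiger_filter(make_harm(1, 0.02, 0.1, 0.1)[0, ])
  expect_equal(nrow(empty$instruments), 0)
  expect_equal(nrow(empty$steiger), 0)
})

test_that("Bonferroni thresholds reproduce the conventional values", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2619), 0.05 / 2619)
  expect_equal(bonferroni_threshold(0.05, 13), 0.05 / 13)
  expect_error(bonferroni_threshold(0.05, 0), class = "targetmr_domain_error")
})

test_that("fit_mr routes by instrument count and its tidiers are consistent", {
  one <- make_harm(1, 0.02, 0.5, 0.1)
  f1 <- fit_mr(one)
  expect_equal(f1$estimate$method, "wald_ratio")
  expect_equal(f1$estimate$beta, wald_ratio(one)$beta)
  expect_equal(f1$estimate$n_snps, 1L)

  many <- make_harm(c(1, 1, 0.8), c(0.02, 0.02, 0.02),
                    c(0.2, 0.4, 0.3), c(0.1, 0.1, 0.1))
  f3 <- fit_mr(many)
  expect_equal(f3$estimate$method, "ivw_mre")
  td <- tidy(f3)
  expect_equal(td, f3$estimate)
  gl <- glance(f3)
  expect_equal(gl$n_snps, 3)
  expect_equal(gl$q, cochran_q(many)$q)
  expect_true(gl$computable)

  p <- autoplot(f3)
  expect_s3_class(p, "ggplot")
})

test_that("estimate confidence intervals satisfy their defining identities", {
  withr::local_seed(17)
  for (rep in 1:30) {
    k <- sample(1:6, 1)
    x <- make_harm(stats::runif(k, 0.2, 1.5) * sample(c(-1, 1), k, TRUE),
                   stats::runif(k, 0.01, 0.1),
                   stats::rnorm(k, 0, 0.3),
                   stats::runif(k, 0.02, 0.2))
    est <- if (k == 1) wald_ratio(x) else ivw(x)
    expect_equal(est$ci_low, exp(est$beta - 1.959964 * est$se),
                 tolerance = 1e-12)
    expect_equal(est$ci_high, exp(est$beta + 1.959964 * est$se),
                 tolerance = 1e-12)
    expect_true(est$ci_low <= est$or_ && est$or_ <= est$ci_high)
    expect_identical(est$method == "wald_ratio", est$n_snps == 1L)
  }
})

test_that("reverse MR flags bidirectional genes and respects testability", {
  # disease-driven region (no reverse path): disease instruments exist but
  # expression shows nothing
  cfg0 <- sim_config(variants_per_region = 30, scenario = "reverse",
                     theta_rev = 0, n_exp = 1e5, n_out = 1e5,
                     case_fraction = 0.5, seed = 101)
  reg0 <- simulate_region(cfg0, 1)
  r0 <- reverse_mr(reg0$outcome, reg0$exposure, reg0$gene, reg0$ld)
  expect_true(r0$testable)

  # true reverse effect: bidirectional at nominal 0.05 with high power
  cfg1 <- sim_config(variants_per_region = 30, scenario = "reverse",
                     theta_rev = 0.1, n_exp = 1e5, n_out = 1e5,
                     case_fraction = 0.5, seed = 102)
  hits <- vapply(1:25, function(g) {
    reg <- simulate_region(cfg1, g)
    reverse_mr(reg$outcome, reg$exposure, reg$gene, reg$ld)$bidirectional
  }, logical(1))
  expect_gt(mean(hits), 0.8)

  # no genome-wide-significant disease variant: not testable
  cfg2 <- sim_config(variants_per_region = 30, scenario = "null",
                     seed = 103)
  reg2 <- simulate_region(cfg2, 1)
  r2 <- reverse_mr(reg2$outcome, reg2$exposure, reg2$gene, reg2$ld)
  expect_false(r2$testable)
  expect_false(r2$bidirectional)
  expect_true(is.na(r2$beta))
})

test_that("reverse MR is calibrated when the disease does not drive expression", {
  cfg <- sim_config(variants_per_region = 20, scenario = "reverse",
                    theta_rev = 0, n_exp = 1e5, n_out = 1e5,
                    case_fraction = 0.5, seed = 104)
  pvals <- vapply(1:200, function(g) {
    reg <- simulate_region(cfg, g)
    reverse_mr(reg$outcome, reg$exposure, reg$gene, reg$ld)$pval
  }, 1)
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 150)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.1)
})
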