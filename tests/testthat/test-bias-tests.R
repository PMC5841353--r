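fake_fit <- function(loglik, n_free, converged = TRUE) {
  structure(list(loglik = loglik, n_free = n_free, converged = converged),
            class = "mlcfa")
}

test_that("baseline pairs have the documented free-parameter counts", {
  pr <- free_baseline_pair(5, referent = 1, item = 2)
  expect_identical(n_free_params(pr$unrestricted), 20L)
  expect_identical(n_free_params(pr$restricted), 18L)

  pc <- constrained_baseline_pair(5, referent = 1, item = 2)
  expect_identical(n_free_params(pc$restricted), 11L)
  expect_identical(n_free_params(pc$unrestricted), 13L)
  # the cluster-invariance baseline implies a rank-one between covariance
  prm <- rand_params_for(pc$restricted)
  expect_equal(implied_between(prm),
               prm$phi_b * prm$lambda_b %o% prm$lambda_b)

  # biased-anchor design: referent 2 fixed at 1 on both levels
  pb <- free_baseline_pair(5, referent = 2, item = 4)
  expect_identical(pb$unrestricted$referent, 2L)
  expect_identical(n_free_params(pb$unrestricted) -
                   n_free_params(pb$restricted), 2L)
})

test_that("every buildable pair differs by exactly two free parameters", {
  for (referent in c(1L, 2L)) {
    for (item in setdiff(1:5, referent)) {
      pr <- free_baseline_pair(5, referent, item)
      expect_identical(n_free_params(pr$unrestricted) -
                       n_free_params(pr$restricted), 2L)
      pr0 <- free_baseline_pair(5, referent, item, referent_theta_b = "zero")
      expect_identical(n_free_params(pr0$unrestricted) -
                       n_free_params(pr0$restricted), 2L)
      pc <- constrained_baseline_pair(5, referent, item)
      expect_identical(n_free_params(pc$unrestricted) -
                       n_free_params(pc$restricted), 2L)
    }
  }
})

test_that("the referent item cannot be tested", {
  expect_error(free_baseline_pair(5, 1, 1), "identification")
  expect_error(constrained_baseline_pair(5, 2, 2), "identification")
})

test_that("LRT outcomes follow the taxonomy", {
  # statistic 7.0, closed-form p = exp(-3.5)
  r <- lr_test(fake_fit(-1046.5, 20), fake_fit(-1050.0, 18))
  expect_equal(r$statistic, 7.0)
  expect_equal(r$p_value, exp(-3.5), tolerance = 1e-12)
  expect_identical(r$status, "significant")
  expect_identical(r$df, 2L)

  # negative statistic is never clipped: inconclusive
  r <- lr_test(fake_fit(-1000.0, 20), fake_fit(-999.5, 18))
  expect_equal(r$statistic, -1.0)
  expect_identical(r$status, "inconclusive_negative")
  expect_true(is.na(r$p_value))

  # identical log-likelihoods: p = 1, non-significant
  r <- lr_test(fake_fit(-500, 13), fake_fit(-500, 11))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_identical(r$status, "non_significant")

  # any non-converged member voids the test
  r <- lr_test(fake_fit(-500, 20), fake_fit(NA_real_, 18, converged = FALSE))
  expect_identical(r$status, "non_converged")
  expect_true(is.na(r$p_value))

  # nesting with the wrong parameter-count difference is refused
  expect_error(lr_test(fake_fit(-1, 20), fake_fit(-2, 17)), "exactly 2")
})

test_that("chi-square(2) upper tail equals the exponential closed form", {
  stats <- c(0, 0.3, 1, 2.5, 5.99, 10, 25)
  for (s in stats) {
    r <- lr_test(fake_fit(-1000, 20), fake_fit(-1000 - s / 2, 18))
    expect_lt(abs(r$p_value - exp(-s / 2)), 1e-12)
  }
})

test_that("item tests under both strategies use different model pairs", {
  set.seed(51)
  cond <- bias_condition(5, 50, 0.2, 1, 0.05)
  d <- simulate_condition(cond, 3)
  a <- cluster_bias_test(d, item = 2, strategy = "free")
  b <- cluster_bias_test(d, item = 2, strategy = "constrained")
  expect_false(identical(a$fit_unrestricted$spec, b$fit_unrestricted$spec))
  expect_identical(a$fit_unrestricted$n_free - a$fit_restricted$n_free, 2L)
  expect_identical(b$fit_unrestricted$n_free - b$fit_restricted$n_free, 2L)
  # flag implies significance
  for (out in list(a, b))
    expect_identical(out$flagged_biased,
                     identical(out$lrt$status, "significant"))
})

test_that("item tests are deterministic given the data", {
  cond <- bias_condition(5, 40, 0.2, 1, 0.05)
  d <- simulate_condition(cond, 2, master_seed = 52L)
  set.seed(1); a <- cluster_bias_test(d, item = 2, strategy = "free")
  set.seed(2); b <- cluster_bias_test(d, item = 2, strategy = "free")
  expect_equal(a$lrt$statistic, b$lrt$statistic, tolerance = 1e-8)
})

test_that("mean LRT statistic increases strictly with violator size", {
  sizes <- c(0.005, 0.02, 0.08)
  means <- vapply(seq_along(sizes), function(k) {
    cond <- bias_condition(25, 50, 0.2, 1, sizes[k], cell = 900L + k)
    stats <- vapply(1:12, function(r) {
      d <- simulate_condition(cond, r, master_seed = 53L)
      cluster_bias_test(d, item = 2, strategy = "free")$lrt$statistic
    }, numeric(1))
    mean(stats, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the freed constrained model reverts all other items to baseline", {
  pc <- constrained_baseline_pair(5, 1, 2)
  expect_identical(pc$unrestricted$equal_loadings, c(3L, 4L, 5L))
  expect_identical(pc$unrestricted$zero_between_resid, c(1L, 3L, 4L, 5L))
})
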