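test_that("closed-form fits reproduce hand arithmetic", {
  cts <- genotype_counts(30, 70, 9, 42, 49)
  f0 <- fit_xhwe(cts, "H0")
  expect_equal(f0$p_m, 0.3)
  expect_equal(f0$p_f, 0.3)
  expect_identical(f0$rho, 0)
  expect_identical(f0$n_iter, 0L)
  expect_equal(fit_xhwe(genotype_counts(0, 40, 0, 0, 60), "H0")$p_m, 0)
  expect_equal(fit_xhwe(genotype_counts(10, 0, 0, 0, 10), "H0")$p_m, 10 / 30)

  f02 <- fit_xhwe(cts, "H02")
  expect_equal(f02$p_m, 0.3)
  expect_equal(f02$p_f, 0.3)
  expect_equal(fit_xhwe(genotype_counts(0, 100, 0, 0, 100), "H02")$p_f, 0)
  expect_equal(fit_xhwe(genotype_counts(100, 0, 100, 0, 0), "H02")$p_m, 1)
})

test_that("unconstrained EM fit recovers HWE data and hard boundaries", {
  # females exactly at HWE proportions: rho at the zero boundary
  f1 <- fit_xhwe(genotype_counts(30, 70, 9, 42, 49), "H1")
  expect_equal(f1$p_m, 0.3)
  expect_equal(f1$p_f, 0.3, tolerance = 1e-4)
  expect_lt(f1$rho, 1e-3)
  # no heterozygotes at all: full inbreeding
  fb <- fit_xhwe(genotype_counts(50, 50, 50, 0, 50), "H1")
  expect_equal(fb$rho, 1, tolerance = 1e-6)
  expect_equal(fb$p_f, 0.5, tolerance = 1e-6)
  # p_m is exact and unaffected by the EM configuration
  cfgs <- list(em_config(), em_config(1e-3, 5, 0.5))
  for (cfg in cfgs) {
    expect_identical(fit_xhwe(genotype_counts(13, 37, 5, 9, 7), "H1",
                              cfg)$p_m, 13 / 50)
  }
})

test_that("pooled EM fit matches the null on exact-null counts and nests", {
  f01 <- fit_xhwe(genotype_counts(30, 70, 9, 42, 49), "H01")
  expect_equal(f01$p_m, 0.3, tolerance = 1e-4)
  expect_lt(f01$rho, 1e-3)
  set.seed(7)
  for (k in 1:20) {
    cts <- random_counts()
    expect_gte(fit_xhwe(cts, "H1")$loglik - fit_xhwe(cts, "H01")$loglik,
               -1e-3)
  }
})

test_that("EM log-likelihoods agree with an independent grid search", {
  # tight tolerance isolates the estimator from its stopping rule
  cfg <- em_config(tolerance = 1e-10, max_iter = 50000)
  set.seed(11)
  for (k in 1:12) {
    cts <- random_counts(30)
    expect_equal(fit_xhwe(cts, "H1", cfg)$loglik, oracle_ll_H1(cts),
                 tolerance = 1e-6)
    expect_equal(fit_xhwe(cts, "H01", cfg)$loglik, oracle_ll_H01(cts),
                 tolerance = 1e-6)
  }
})

test_that("the EM never decreases the observed-data log-likelihood", {
  set.seed(5)
  for (k in 1:10) {
    cts <- random_counts()
    for (h in c("H1", "H01")) {
      tr <- attr(fit_xhwe(cts, h, trace = TRUE), "loglik_trace")
      expect_true(all(diff(tr) > -1e-9))
    }
  }
})

test_that("the EM beats the moment estimator in likelihood", {
  cfg <- em_config(tolerance = 1e-10, max_iter = 50000)
  set.seed(21)
  for (k in 1:20) {
    cts <- random_counts()
    z <- tryCatch(rho_moment(cts), error = function(e) NA)
    if (is.na(z)) next
    pf_mom <- (2 * cts$n2f + cts$n1f) / (2 * cts$Nf)
    ll_mom <- x_loglik(cts, cts$n1m / cts$Nm, pf_mom,
                       min(max(z, 0), 1))
    expect_gte(fit_xhwe(cts, "H1", cfg)$loglik - ll_mom, -1e-7)
  }
})

test_that("moment estimator of rho matches hand arithmetic", {
  expect_equal(rho_moment(genotype_counts(3, 7, 9, 42, 49)), 0)
  expect_equal(rho_moment(genotype_counts(0, 0, 25, 0, 25)), 1)
  expect_equal(rho_moment(genotype_counts(0, 0, 20, 60, 20)), -0.2)
  err <- tryCatch(rho_moment(genotype_counts(1, 1, 10, 0, 0)),
                  error = identity)
  expect_s3_class(err, "xhweqc_undefined")
})

test_that("degenerate female samples get flagged boundary fits", {
  # monomorphic females: rho not identifiable
  f <- fit_xhwe(genotype_counts(4, 6, 12, 0, 0), "H1")
  expect_true(f$boundary)
  expect_identical(f$rho, 0)
  expect_equal(f$p_f, 1)
  # all-heterozygous females: rho driven to zero
  fh <- fit_xhwe(genotype_counts(4, 6, 0, 20, 0), "H1")
  expect_lt(fh$rho, 1e-6)
  expect_equal(fh$p_f, 0.5, tolerance = 1e-6)
  # iteration cap is honest
  fc <- fit_xhwe(genotype_counts(30, 70, 9, 42, 49), "H1",
                 em_config(max_iter = 3))
  expect_false(fc$converged)
  expect_lte(fc$n_iter, 3L)
})

test_that("EM estimator of rho is consistent at an interior truth", {
  sc <- xhwe_scenario(p_m = 0.3, epsilon = 0.05, rho = 0.1, N = 1200,
                      r = c(1, 1), n_reps = 400)
  ex <- run_experiment(sc, tests = "LRT2", seed = 3)
  est <- ex$estimates
  m <- est$mean[est$estimator == "rho1"]
  expect_lt(abs(m - 0.1), 0.01)
  # EM estimator no less efficient than the moment estimator
  expect_lte(est$rmse[est$estimator == "rho1"],
             est$rmse[est$estimator == "rho_z"] + 1e-4)
})
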