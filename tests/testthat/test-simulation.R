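test_that("the homogeneous generator reproduces the model moments", {
  sc <- xhwe_scenario(p_m = 1, epsilon = 0, rho = 0, N = 100, r = c(1, 1))
  set.seed(1)
  d <- simulate_counts(sc, 3)
  expect_true(all(d$n1m == sc$Nm & d$n2f == sc$Nf))
  expect_true(all(d$n0m == 0 & d$n1f == 0 & d$n0f == 0))

  sc2 <- xhwe_scenario(p_m = 0.3, epsilon = 0, rho = 0.1, N = 300,
                       r = c(1, 2))
  set.seed(2)
  d2 <- simulate_counts(sc2, 10000)
  f2 <- 0.3^2 + 0.1 * 0.3 * 0.7   # 0.111
  se <- sqrt(f2 * (1 - f2) / sc2$Nf / 10000)
  expect_lt(abs(mean(d2$n2f / sc2$Nf) - f2), 3 * se)
  # multinomial variance of the M1M1 cell
  expect_lt(abs(var(d2$n2f) / (sc2$Nf * f2 * (1 - f2)) - 1), 0.1)
  expect_true(all(d2$n2f + d2$n1f + d2$n0f == sc2$Nf))
})

test_that("ratio splitting rounds the male share of N", {
  expect_equal(xhwe_scenario(N = 800, r = c(2, 1))$Nm, 533)
  expect_equal(xhwe_scenario(N = 800, r = c(2, 1))$Nf, 267)
  expect_equal(xhwe_scenario(N = 2500, r = c(0, 1))$Nm, 0)
  expect_equal(xhwe_scenario(N = 1200, r = c(1, 1.5))$Nm, 480)
})

test_that("stratified generator reduces to homogeneous when subpops match", {
  sc <- xhwe_scenario(N = 2000, stratification = list(
    p_m = c(0.4, 0.4), epsilon = c(0, 0)))
  set.seed(4)
  d <- simulate_stratified(sc, 4000)
  # marginal male frequency and overall female M1M1 rate at HWE(0.4)
  pm_hat <- mean(d$n1m / (d$n1m + d$n0m))
  expect_lt(abs(pm_hat - 0.4), 0.01)
  p2 <- mean(d$n2f / (d$n2f + d$n1f + d$n0f))
  expect_lt(abs(p2 - 0.16), 0.01)
})

test_that("subpopulation mixture induces apparent excess homozygosity", {
  sc <- xhwe_scenario(N = 1800, n_reps = 300, stratification = list(
    p_m = c(0.3, 0.5), epsilon = c(0, 0)))
  ex <- run_experiment(sc, tests = "LRT2", seed = 8)
  rho_mean <- ex$estimates$mean[ex$estimates$estimator == "rho1"]
  expect_gt(rho_mean, 0.02)  # Wahlund effect: positive inbreeding estimate
  # marginal male frequency is the mixture mean
  pm_mean <- ex$estimates$mean[ex$estimates$estimator == "pm1"]
  expect_lt(abs(pm_mean - 0.4), 0.01)
})

test_that("fixed sex split pins the male count", {
  sc <- xhwe_scenario(N = 1801, stratification = list(
    p_m = c(0.3, 0.5), epsilon = c(0, 0), fixed_sex_split = TRUE))
  set.seed(6)
  d <- simulate_stratified(sc, 50)
  expect_true(all(d$n1m + d$n0m == round(1801 * 0.5)))
})

test_that("experiments are reproducible and respect alpha extremes", {
  sc <- xhwe_scenario(p_m = 0.3, N = 200, r = c(1, 1), n_reps = 150)
  a <- run_experiment(sc, tests = c("Z1", "LRT2", "LRT2b"), boot_B = 50,
                      seed = 99)
  b <- run_experiment(sc, tests = c("Z1", "LRT2", "LRT2b"), boot_B = 50,
                      seed = 99)
  expect_identical(a$rates, b$rates)
  expect_identical(a$estimates, b$estimates)

  sc1 <- xhwe_scenario(p_m = 0.3, N = 200, r = c(1, 1), n_reps = 100,
                       alpha = 1)
  r1 <- run_experiment(sc1, tests = c("Z1", "LRT0"), seed = 1)$rates
  expect_true(all(r1$rate == 1))
})

test_that("undefined replicates are excluded and accounted for", {
  # rare allele in a tiny sample: monomorphic replicates are frequent
  sc <- xhwe_scenario(p_m = 0.03, N = 40, r = c(1, 1), n_reps = 300)
  ex <- run_experiment(sc, tests = c("Z2", "LRT2"), seed = 2)
  r <- ex$rates
  expect_true(all(r$n_used + r$n_excluded == 300))
  expect_gt(r$n_excluded[r$test == "Z2"], 0)
})

test_that("RMSE decomposes into bias and variance", {
  sc <- xhwe_scenario(p_m = 0.3, epsilon = 0.05, rho = 0.05, N = 600,
                      r = c(1, 1), n_reps = 400)
  est <- run_experiment(sc, tests = "LRT2", seed = 10)$estimates
  est <- est[!is.na(est$rmse), ]
  v <- est$sd^2 * (est$n_used - 1) / est$n_used
  expect_equal(est$rmse^2, est$bias^2 + v, tolerance = 1e-10)
})

test_that("sample size search walks the grid to the target power", {
  sc <- xhwe_scenario(p_m = 0.3, epsilon = 0, rho = 0.15, N = 100,
                      r = c(0, 1), alpha = 0.05)
  # asymptotic Z2 keeps the search cheap
  res <- sample_size_search(sc, test = "Z2", target_power = 0.8,
                            Nf_min = 100, Nf_max = 6400, Nf_step = 100,
                            n_reps = 400, seed = 12)
  expect_gte(res$power, 0.8)
  expect_true(res$Nf %in% seq(100, 6400, by = 100))
  # a grid that cannot reach the target errors out
  expect_error(
    sample_size_search(sc, test = "Z2", target_power = 0.999,
                       Nf_min = 100, Nf_max = 200, Nf_step = 100,
                       n_reps = 100, seed = 12),
    "target power")
  # degenerate target returns the grid minimum
  res0 <- sample_size_search(sc, test = "Z2", target_power = 0,
                             Nf_min = 100, Nf_max = 400, Nf_step = 100,
                             n_reps = 50, seed = 12)
  expect_equal(res0$Nf, 100)
})

test_that("a plain-text grid runs scenario by scenario", {
  grid <- data.frame(p_m = c(0.3, 0.5), epsilon = 0, rho = 0,
                     N = 200, r_m = 1, r_f = 1, n_reps = 100)
  res <- run_experiment_grid(grid, tests = c("Z1", "Z2"), seed = 3)
  expect_equal(nrow(res), 4L)
  expect_true(all(c("p_m", "test", "rate", "se") %in% names(res)))
  # round-trips through a delimited file
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res2 <- run_experiment_grid(path, tests = c("Z1", "Z2"), seed = 3)
  expect_equal(res$rate, res2$rate)
})
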