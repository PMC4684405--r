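test_that("Z1 matches the printed variance formulas", {
  expect_equal(xhwe_z1(genotype_counts(30, 70, 9, 42, 49))$statistic, 0)
  expect_equal(xhwe_z1(genotype_counts(30, 70, 9, 42, 49))$p_value, 1)
  z <- xhwe_z1(genotype_counts(50, 50, 9, 42, 49))
  expect_equal(z$statistic, 0.04 / 0.00355)
  expect_equal(z$p_value, pchisq(0.04 / 0.00355, 1, lower.tail = FALSE))
})

test_that("Z2 matches hand evaluation and ignores males", {
  expect_equal(xhwe_z2(genotype_counts(0, 0, 25, 50, 25))$statistic,
               100 * (0.25 / 200)^2 / 0.0625)
  expect_equal(xhwe_z2(genotype_counts(0, 0, 50, 0, 50))$statistic,
               100 * (0.25 + 0.00125)^2 / 0.0625)
  set.seed(3)
  ref <- xhwe_z2(genotype_counts(0, 0, 18, 41, 21))$statistic
  for (k in 1:5) {
    males <- sample.int(80, 2)
    expect_identical(
      xhwe_z2(genotype_counts(males[1], males[2], 18, 41, 21))$statistic,
      ref)
  }
})

test_that("Z0 is the sum of its components with two degrees of freedom", {
  cts <- genotype_counts(35, 65, 20, 45, 35)
  z0 <- xhwe_z0(cts)
  z1 <- xhwe_z1(cts)$statistic
  z2 <- xhwe_z2(cts)$statistic
  expect_equal(z0$statistic, z1 + z2)
  expect_gte(z0$statistic, max(z1, z2))
  expect_equal(z0$p_value, pchisq(z1 + z2, 2, lower.tail = FALSE))
})

test_that("moment statistics are reported missing at monomorphic loci", {
  mono <- genotype_counts(10, 0, 12, 0, 0)
  expect_true(is.na(xhwe_z1(mono)$statistic))
  expect_true(is.na(xhwe_z2(mono)$statistic))
  expect_true(is.na(xhwe_z0(mono)$p_value))
  # batch wrapper keeps going and reports NA rows
  res <- xhwe_tests(mono, tests = c("Z1", "LRT0"))
  expect_equal(nrow(res), 2L)
  expect_true(is.na(res$p_value[res$test == "Z1"]))
  expect_false(is.na(res$p_value[res$test == "LRT0"]))
})

test_that("LRT statistics vanish on exact-null counts and nest properly", {
  cts <- genotype_counts(30, 70, 9, 42, 49)
  for (w in c("LRT0", "LRT1", "LRT2")) {
    expect_equal(xhwe_lrt(cts, w)$statistic, 0, tolerance = 1e-6)
  }
  set.seed(13)
  for (k in 1:20) {
    r <- random_counts()
    l0 <- xhwe_lrt(r, "LRT0")$statistic
    expect_gte(l0 - xhwe_lrt(r, "LRT1")$statistic, -1e-3)
    expect_gte(l0 - xhwe_lrt(r, "LRT2")$statistic, -1e-3)
  }
})

test_that("LRT2 is invariant to male counts", {
  set.seed(17)
  ref <- xhwe_lrt(genotype_counts(0, 0, 22, 31, 17), "LRT2")$statistic
  for (k in 1:5) {
    males <- sample.int(100, 2)
    expect_equal(
      xhwe_lrt(genotype_counts(males[1], males[2], 22, 31, 17),
               "LRT2")$statistic, ref, tolerance = 1e-9)
  }
})

test_that("all asymptotic p-values are invariant to allele relabelling", {
  set.seed(19)
  for (k in 1:10) {
    a <- random_counts()
    b <- genotype_counts(a$n0m, a$n1m, a$n0f, a$n1f, a$n2f)
    expect_equal(xhwe_z1(a)$p_value, xhwe_z1(b)$p_value)
    expect_equal(xhwe_z2(a)$p_value, xhwe_z2(b)$p_value)
    for (w in c("LRT0", "LRT1", "LRT2")) {
      expect_equal(xhwe_lrt(a, w)$p_value, xhwe_lrt(b, w)$p_value,
                   tolerance = 1e-5)
    }
  }
})

test_that("Z0 approaches its chi-square(2) reference as samples grow", {
  kolmogorov <- function(N, reps) {
    sc <- xhwe_scenario(p_m = 0.3, N = N, r = c(1, 1), n_reps = reps)
    set.seed(29)
    d <- simulate_counts(sc, reps)
    z <- xhweqc:::.z_batch(d)
    u <- sort(pchisq(z$z0[!is.na(z$z0)], 2))
    n <- length(u)
    max(pmax(abs(seq_len(n) / n - u), abs((seq_len(n) - 1) / n - u)))
  }
  d_small <- kolmogorov(60, 2000)
  d_large <- kolmogorov(2000, 2000)
  expect_lt(d_large, d_small)
  expect_lt(d_large, 0.05)
})

test_that("dosage compensation only affects the pooled-frequency LRTs", {
  cts <- genotype_counts(42, 58, 30, 40, 30)
  expect_equal(xhwe_lrt(cts, "LRT2", dosage_compensation = TRUE)$statistic,
               xhwe_lrt(cts, "LRT2")$statistic, tolerance = 1e-9)
  # pooled estimate counts each male allele twice
  f0 <- fit_xhwe(cts, "H0", dosage_compensation = TRUE)
  expect_equal(f0$p_m, (2 * 42 + 2 * 30 + 40) / (2 * 100 + 2 * 100))
  # with no males the variants coincide
  fonly <- genotype_counts(0, 0, 30, 40, 30)
  expect_equal(xhwe_lrt(fonly, "LRT1", dosage_compensation = TRUE)$statistic,
               xhwe_lrt(fonly, "LRT1")$statistic, tolerance = 1e-9)
  # with males present LRT1 genuinely changes
  expect_false(isTRUE(all.equal(
    xhwe_lrt(cts, "LRT1", dosage_compensation = TRUE)$statistic,
    xhwe_lrt(cts, "LRT1")$statistic)))
})
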