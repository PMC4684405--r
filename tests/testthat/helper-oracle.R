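# Shared fixtures: random count generators, an EM-independent grid-search
# maximiser of the log-likelihood, and a PED writer.

random_counts <- function(max_cell = 40) {
  genotype_counts(sample.int(max_cell, 1), sample.int(max_cell, 1),
                  sample.int(max_cell, 1), sample.int(max_cell, 1),
                  sample.int(max_cell, 1))
}

# maximise f(a, b) over [0,1]^2 by nested grid refinement; independent of
# the EM code path it is used to check
grid_max <- function(f, passes = 6, n = 61) {
  lo1 <- 0; hi1 <- 1; lo2 <- 0; hi2 <- 1
  best <- -Inf
  for (p in seq_len(passes)) {
    x <- seq(lo1, hi1, length.out = n)
    y <- seq(lo2, hi2, length.out = n)
    g <- expand.grid(a = x, b = y)
    v <- f(g$a, g$b)
    i <- which.max(v)
    sx <- (hi1 - lo1) / (n - 1)
    sy <- (hi2 - lo2) / (n - 1)
    lo1 <- max(0, g$a[i] - 2 * sx); hi1 <- min(1, g$a[i] + 2 * sx)
    lo2 <- max(0, g$b[i] - 2 * sy); hi2 <- min(1, g$b[i] + 2 * sy)
    best <- v[i]
  }
  best
}

oracle_ll_H1 <- function(cts) {
  pm <- if (cts$Nm > 0) cts$n1m / cts$Nm else 0.5
  grid_max(function(pf, rho) x_loglik(cts, pm, pf, rho))
}

oracle_ll_H01 <- function(cts) {
  grid_max(function(p, rho) x_loglik(cts, p, p, rho))
}

# single-marker PED file realising given genotype counts, optionally with a
# non-founder child appended (must never contribute to counts)
write_ped_from_counts <- function(cts, path, m1 = "A", m2 = "B",
                                  with_child = FALSE) {
  rows <- character(0)
  i <- 0
  add <- function(sex, a, b) {
    i <<- i + 1
    sprintf("F%d I%d 0 0 %d 0 %s %s", i, i, sex, a, b)
  }
  rows <- c(
    vapply(seq_len(cts$n1m), function(k) add(1, m1, m1), ""),
    vapply(seq_len(cts$n0m), function(k) add(1, m2, m2), ""),
    vapply(seq_len(cts$n2f), function(k) add(2, m1, m1), ""),
    vapply(seq_len(cts$n1f), function(k) add(2, m1, m2), ""),
    vapply(seq_len(cts$n0f), function(k) add(2, m2, m2), "")
  )
  if (with_child) {
    rows <- c(rows, sprintf("F1 C1 I1 I2 2 0 %s %s", m1, m1))
  }
  writeLines(rows, path)
  path
}
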