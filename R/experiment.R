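# Monte-Carlo harness: rejection rates (size/power) and estimator accuracy.

`%||%` <- function(a, b) if (is.null(a)) b else a

# bootstrap p-value for one replicate, reusing the already-fitted observed
# statistic and null parameters
.boot_p_one <- function(which, n1m, n0m, n2f, n1f, n0f, obs, p_null,
                        rho_null, B, seed, tol, mi, ri, w) {
  if (!is.finite(obs)) return(NA_real_)
  Nm <- n1m + n0m
  Nf <- n2f + n1f + n0f
  set.seed(seed)
  if (which == "LRT2") {
    fem <- .sim_female(B, Nf, p_null^2, 2 * p_null * (1 - p_null),
                       (1 - p_null)^2)
    n1m_s <- rep(n1m, B); n0m_s <- rep(n0m, B)
  } else {
    n1m_s <- rbinom(B, Nm, p_null)
    n0m_s <- Nm - n1m_s
    fem <- .sim_female(B, Nf, .fgf2(p_null, rho_null),
                       .fgf1(p_null, rho_null), .fgf0(p_null, rho_null))
  }
  star <- .lrt_only(which, n1m_s, n0m_s, fem$n2f, fem$n1f, fem$n0f,
                    tol, mi, ri, w)
  mean(star$stat > obs)
}

# bootstrap p-values for all replicates; resamples are generated per
# replicate from its own derived seed (so results are independent of the
# chunking), but the EM runs on chunks of replicates at once, which
# amortises the slow boundary-convergence tail of the EM across the batch
.boot_p_chunked <- function(which, d, obs, p_null, rho_null, B, seed,
                            tol, mi, ri, w, chunk = 32L) {
  reps <- nrow(d)
  out <- rep(NA_real_, reps)
  for (start in seq(1L, reps, by = chunk)) {
    idx <- start:min(start + chunk - 1L, reps)
    idx <- idx[is.finite(obs[idx])]
    if (!length(idx)) next
    gen <- lapply(idx, function(i) {
      set.seed(.derive_seed(seed, i))
      Nm <- d$n1m[i] + d$n0m[i]
      Nf <- d$n2f[i] + d$n1f[i] + d$n0f[i]
      if (which == "LRT2") {
        p <- p_null[i]
        fem <- .sim_female(B, Nf, p^2, 2 * p * (1 - p), (1 - p)^2)
        list(n1m = rep(d$n1m[i], B), n0m = rep(d$n0m[i], B),
             n2f = fem$n2f, n1f = fem$n1f, n0f = fem$n0f)
      } else {
        n1m_s <- rbinom(B, Nm, p_null[i])
        fem <- .sim_female(B, Nf, .fgf2(p_null[i], rho_null[i]),
                           .fgf1(p_null[i], rho_null[i]),
                           .fgf0(p_null[i], rho_null[i]))
        list(n1m = n1m_s, n0m = Nm - n1m_s,
             n2f = fem$n2f, n1f = fem$n1f, n0f = fem$n0f)
      }
    })
    pool <- lapply(c("n1m", "n0m", "n2f", "n1f", "n0f"), function(f) {
      unlist(lapply(gen, `[[`, f), use.names = FALSE)
    })
    star <- .lrt_only(which, pool[[1]], pool[[2]], pool[[3]], pool[[4]],
                      pool[[5]], tol, mi, ri, w)
    for (k in seq_along(idx)) {
      seg <- ((k - 1L) * B + 1L):(k * B)
      out[idx[k]] <- mean(star$stat[seg] > obs[idx[k]])
    }
  }
  out
}

#' Run a Monte-Carlo size/power experiment
#'
#' Draws `n_reps` datasets under a scenario, applies the requested tests to
#' each, and reports per-test rejection rates at the scenario's `alpha`
#' together with Monte-Carlo standard errors and per-estimator summaries
#' (mean, SD, bias, RMSE of the EM estimators and the moment estimator
#' `rho_z`). Replicates on which a statistic is undefined (monomorphic
#' samples) are excluded for that test and counted. Results are fully
#' reproducible for a given `seed`: the generator stream and the per
#' replicate bootstrap streams are derived deterministically from it, so
#' bootstrap results do not depend on evaluation order.
#'
#' @param scenario An [xhwe_scenario()].
#' @param tests Character vector from `Z1, Z2, Z0, LRT0, LRT1, LRT2, LRT0b,
#'   LRT1b, LRT2b`.
#' @param boot_B Bootstrap resamples per replicate for the `*b` tests.
#' @param seed Integer master seed.
#' @param config An [em_config()].
#' @param n_reps Optional override of `scenario$n_reps`.
#' @param keep If `TRUE`, keep the simulated counts and per-replicate
#'   p-values in the result (memory permitting).
#' @return An object of class `"xhwe_experiment"`: list with `rates` (one
#'   row per test: `test`, `n_used`, `n_excluded`, `rate`, `se`),
#'   `estimates` (one row per estimator: `estimator`, `truth`, `mean`,
#'   `sd`, `bias`, `rmse`), `n_nonconverged`, and the inputs.
#' @examples
#' sc <- xhwe_scenario(p_m = 0.3, N = 400, r = c(1, 1), n_reps = 200)
#' run_experiment(sc, tests = c("Z1", "LRT1"), seed = 7)
#' @export
run_experiment <- function(scenario,
                           tests = c("Z1", "Z2", "Z0", "LRT0", "LRT1",
                                     "LRT2"),
                           boot_B = 1000, seed = 1L, config = em_config(),
                           n_reps = NULL, keep = FALSE) {
  stopifnot(inherits(scenario, "xhwe_scenario"), length(tests) >= 1)
  reps <- as.integer(n_reps %||% scenario$n_reps)
  w <- if (scenario$dosage_compensation) 2 else 1
  tol <- config$tolerance; mi <- config$max_iter; ri <- config$rho_init

  set.seed(.derive_seed(seed, 0L))
  d <- simulate_counts(scenario, reps)
  fit <- .fit_batch(d, tol, mi, ri, male_w = w)
  z <- .z_batch(d)

  pv <- list()
  for (tn in tests) {
    pv[[tn]] <- switch(tn,
      Z1 = pchisq(z$z1, 1, lower.tail = FALSE),
      Z2 = pchisq(z$z2, 1, lower.tail = FALSE),
      Z0 = pchisq(z$z0, 2, lower.tail = FALSE),
      LRT0 = pchisq(fit$lrt0, 2, lower.tail = FALSE),
      LRT1 = pchisq(fit$lrt1, 1, lower.tail = FALSE),
      LRT2 = pchisq(fit$lrt2, 1, lower.tail = FALSE),
      LRT0b = ,
      LRT1b = ,
      LRT2b = {
        base <- sub("b$", "", tn)
        obs <- switch(base, LRT0 = fit$lrt0, LRT1 = fit$lrt1,
                      LRT2 = fit$lrt2)
        p_null <- switch(base, LRT0 = fit$p0, LRT1 = fit$p01,
                         LRT2 = fit$pf02)
        rho_null <- switch(base, LRT0 = rep(0, reps), LRT1 = fit$rho01,
                           LRT2 = rep(0, reps))
        .boot_p_chunked(base, d, obs, p_null, rho_null, boot_B, seed,
                        tol, mi, ri, w)
      },
      stop("unknown test: ", tn)
    )
  }

  rates <- do.call(rbind, lapply(tests, function(tn) {
    p <- pv[[tn]]
    used <- sum(!is.na(p))
    rate <- if (used > 0) mean(p <= scenario$alpha, na.rm = TRUE) else
      NA_real_
    data.frame(test = tn, n_used = used, n_excluded = reps - used,
               rate = rate,
               se = sqrt(rate * (1 - rate) / max(used, 1)))
  }))

  strat <- !is.null(scenario$stratification)
  truth <- c(pm1 = if (strat) NA_real_ else scenario$p_m,
             pf1 = if (strat) NA_real_ else scenario$p_f,
             rho1 = if (strat) NA_real_ else scenario$rho,
             p01 = if (!strat && scenario$epsilon == 0) scenario$p_m else
               NA_real_,
             rho01 = if (strat) NA_real_ else scenario$rho,
             rho_z = if (strat) NA_real_ else scenario$rho)
  est_vals <- list(pm1 = fit$pm1, pf1 = fit$pf1, rho1 = fit$rho1,
                   p01 = fit$p01, rho01 = fit$rho01, rho_z = z$rho_z)
  estimates <- do.call(rbind, lapply(names(est_vals), function(e) {
    x <- est_vals[[e]]
    ok <- is.finite(x)
    tr <- truth[[e]]
    data.frame(estimator = e, truth = tr, mean = mean(x[ok]),
               sd = stats::sd(x[ok]),
               bias = if (is.na(tr)) NA_real_ else mean(x[ok]) - tr,
               rmse = if (is.na(tr)) NA_real_ else
                 sqrt(mean((x[ok] - tr)^2)),
               n_used = sum(ok))
  }))

  structure(
    list(scenario = scenario, tests = tests, alpha = scenario$alpha,
         seed = seed, n_reps = reps,
         boot_B = if (any(grepl("b$", tests))) boot_B else NA_integer_,
         rates = rates, estimates = estimates,
         n_nonconverged = sum(!fit$conv1) + sum(!fit$conv01),
         p_values = if (keep) pv, counts = if (keep) d),
    class = "xhwe_experiment")
}

#' @export
print.xhwe_experiment <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("Rejection rates at alpha = %.3g (%d replications):\n",
              x$alpha, x$n_reps))
  r <- x$rates
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-6s %6.2f%%  (SE %.2f%%%s)\n", r$test[i],
                100 * r$rate[i], 100 * r$se[i],
                if (r$n_excluded[i] > 0)
                  sprintf(", %d excluded", r$n_excluded[i]) else ""))
  }
  invisible(x)
}

#' Smallest female sample size reaching a target power
#'
#' Searches a grid of female sample sizes for the smallest `Nf` whose
#' simulated power of `test` reaches `target_power`, assuming power is
#' monotone in `Nf` for the scenario. The male count is held at the
#' scenario's `Nm` (a ratio of `c(0, 1)` gives a female-only design). The
#' search doubles `Nf` from `Nf_min` until the target is reached, then
#' bisects on
#' the grid. Each evaluation is an independent [run_experiment()] whose
#' seed is derived from `seed` and the evaluated `Nf`, so evaluations are
#' order-independent.
#'
#' @inheritParams run_experiment
#' @param test Test whose power drives the search (default `"LRT2b"`).
#' @param target_power Target power in `[0, 1]`.
#' @param Nf_min,Nf_max,Nf_step Search grid (multiples of `Nf_step` from
#'   `Nf_min`).
#' @param n_reps Replications per power evaluation.
#' @return A list with `Nf` (smallest grid value reaching the target),
#'   `power` (its simulated power) and `trace` (all evaluations).
#' @export
sample_size_search <- function(scenario, test = "LRT2b",
                               target_power = 0.8, Nf_min = 100,
                               Nf_max = 20000, Nf_step = 50,
                               n_reps = 1000, boot_B = 200, seed = 1L,
                               config = em_config()) {
  stopifnot(target_power >= 0, target_power <= 1, Nf_min <= Nf_max)
  snap <- function(x) Nf_min + Nf_step * round((x - Nf_min) / Nf_step)
  trace <- data.frame(Nf = integer(), power = numeric())
  power_at <- function(Nf) {
    hit <- trace$power[match(Nf, trace$Nf)]
    if (!is.na(hit)) return(hit)
    sc <- xhwe_scenario(p_m = scenario$p_m, epsilon = scenario$epsilon,
                        rho = scenario$rho, N = scenario$Nm + Nf,
                        r = c(scenario$Nm, Nf), n_reps = n_reps,
                        alpha = scenario$alpha,
                        dosage_compensation = scenario$dosage_compensation)
    ex <- run_experiment(sc, tests = test, boot_B = boot_B,
                         seed = .derive_seed(seed, Nf), config = config)
    p <- ex$rates$rate[1]
    trace <<- rbind(trace, data.frame(Nf = Nf, power = p))
    p
  }
  lo <- NA_integer_
  Nf <- Nf_min
  while (power_at(Nf) < target_power) {
    lo <- Nf
    if (Nf >= Nf_max) {
      stop("target power not reached within [Nf_min, Nf_max]")
    }
    Nf <- min(snap(2 * Nf), Nf_max)
  }
  hi <- Nf
  if (!is.na(lo)) {
    while (hi - lo > Nf_step) {
      mid <- snap((lo + hi) / 2)
      if (mid <= lo) mid <- lo + Nf_step
      if (mid >= hi) mid <- hi - Nf_step
      if (power_at(mid) >= target_power) hi <- mid else lo <- mid
    }
  }
  list(Nf = hi, power = power_at(hi), trace = trace[order(trace$Nf), ])
}

#' Run a grid of scenarios from a plain-text table
#'
#' Reads a whitespace- or comma-delimited table with a header containing
#' the columns `p_m, epsilon, rho, N, r_m, r_f` (optional: `n_reps`,
#' `alpha`), runs every scenario against `tests`, and returns one row per
#' scenario-test combination, suitable for writing back out with
#' [utils::write.table()].
#'
#' @param grid A data.frame, or path to a delimited text file with header.
#' @inheritParams run_experiment
#' @param out Optional path: write the result as a tab-delimited table.
#' @return A data.frame: scenario columns plus `test`, `n_used`, `rate`,
#'   `se`.
#' @export
run_experiment_grid <- function(grid,
                                tests = c("Z1", "Z2", "Z0", "LRT0",
                                          "LRT1", "LRT2"),
                                boot_B = 1000, seed = 1L,
                                config = em_config(), out = NULL) {
  if (is.character(grid)) {
    grid <- read.table(grid, header = TRUE,
                       sep = if (grepl("\\.csv$", grid)) "," else "")
  }
  need <- c("p_m", "epsilon", "rho", "N", "r_m", "r_f")
  stopifnot(all(need %in% names(grid)))
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sc <- xhwe_scenario(p_m = g$p_m, epsilon = g$epsilon, rho = g$rho,
                        N = g$N, r = c(g$r_m, g$r_f),
                        n_reps = g$n_reps %||% 10000,
                        alpha = g$alpha %||% 0.05)
    ex <- run_experiment(sc, tests = tests, boot_B = boot_B,
                         seed = .derive_seed(seed, i), config = config)
    cbind(g[need], ex$rates, row.names = NULL)
  }))
  if (!is.null(out)) {
    write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
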