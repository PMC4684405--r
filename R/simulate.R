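# Scenario definition and synthetic-data generation.

#' Define a simulation scenario
#'
#' A scenario fixes the data-generating conditions of one Monte-Carlo
#' experiment: male frequency `p_m`, female frequency `p_f = p_m + epsilon`,
#' inbreeding coefficient `rho`, total sample size `N` split into males and
#' females by the ratio Nm:Nf (`Nm = round(N * r1 / (r1 + r2))`,
#' `Nf = N - Nm`), replication count and significance level. An optional
#' two-subpopulation stratification block replaces the homogeneous
#' generator: each individual is independently assigned a subpopulation
#' (probability `mix` for the first) and a sex (`male_prob` male), with
#' subpopulation-specific `p_m` and `epsilon` and `rho = 0` within each
#' subpopulation (the pooled sample then shows excess homozygosity — the
#' Wahlund effect).
#'
#' @param p_m Male M1 allele frequency (homogeneous model).
#' @param epsilon Female-male frequency difference; `p_f = p_m + epsilon`.
#' @param rho Female inbreeding coefficient in `[0, 1]`.
#' @param N Total sample size.
#' @param r Length-2 ratio `Nm:Nf`, e.g. `c(2, 1)`. Use `c(0, 1)` for a
#'   female-only design.
#' @param n_reps Monte-Carlo replications.
#' @param alpha Significance level.
#' @param stratification Optional list with components `p_m` (length-2
#'   subpopulation male frequencies), `epsilon` (length-2 subpopulation
#'   `p_f - p_m`), `mix` (probability of the first subpopulation, default
#'   0.5), `male_prob` (probability an individual is male, default 0.5) and
#'   `fixed_sex_split` (logical, default `FALSE`: sex is Bernoulli per
#'   individual as described; `TRUE` fixes `Nm = round(N * male_prob)`).
#' @param dosage_compensation Analyse each replicate with male alleles
#'   double-counted (affects LRT0/LRT1 only).
#' @return A list of class `"xhwe_scenario"` with the resolved `Nm`, `Nf`.
#' @examples
#' xhwe_scenario(p_m = 0.3, N = 800, r = c(2, 1))
#' @export
xhwe_scenario <- function(p_m = 0.3, epsilon = 0, rho = 0, N = 800,
                          r = c(1, 1), n_reps = 10000, alpha = 0.05,
                          stratification = NULL,
                          dosage_compensation = FALSE) {
  stopifnot(length(r) == 2, all(r >= 0), sum(r) > 0, N >= 1,
            alpha >= 0, alpha <= 1, n_reps >= 1,
            rho >= 0, rho <= 1)
  if (is.null(stratification)) {
    p_f <- p_m + epsilon
    stopifnot(p_m >= 0, p_m <= 1, p_f >= 0, p_f <= 1)
  } else {
    stopifnot(length(stratification$p_m) == 2,
              length(stratification$epsilon) == 2)
    stratification$mix <- if (is.null(stratification$mix)) 0.5 else
      stratification$mix
    stratification$male_prob <- if (is.null(stratification$male_prob)) 0.5
      else stratification$male_prob
    stratification$fixed_sex_split <-
      isTRUE(stratification$fixed_sex_split)
    p_f <- NA_real_
  }
  Nm <- round(N * r[1] / sum(r))
  structure(
    list(p_m = p_m, epsilon = epsilon, p_f = p_f, rho = rho, N = N, r = r,
         Nm = Nm, Nf = N - Nm, n_reps = n_reps, alpha = alpha,
         stratification = stratification,
         dosage_compensation = dosage_compensation),
    class = "xhwe_scenario")
}

#' @export
print.xhwe_scenario <- function(x, ...) {
  if (is.null(x$stratification)) {
    cat(sprintf(
      "Scenario: p_m = %.3f, p_f = %.3f, rho = %.3f, Nm = %d, Nf = %d\n",
      x$p_m, x$p_f, x$rho, x$Nm, x$Nf))
  } else {
    s <- x$stratification
    cat(sprintf(
      "Stratified scenario: N = %d, subpop p_m = (%.2f, %.2f), epsilon = (%.2f, %.2f)\n",
      x$N, s$p_m[1], s$p_m[2], s$epsilon[1], s$epsilon[2]))
  }
  cat(sprintf("  %d replications, alpha = %.3f%s\n", x$n_reps, x$alpha,
              if (x$dosage_compensation) ", dosage compensation" else ""))
  invisible(x)
}

#' Draw genotype counts under a scenario
#'
#' Homogeneous model: `n1m ~ Binomial(Nm, p_m)`; female genotype counts
#' multinomial with the probabilities from [female_genotype_freqs()].
#' Scenarios with a stratification block delegate to
#' [simulate_stratified()]. Uses the current RNG state; callers control
#' reproducibility with `set.seed()`.
#'
#' @param scenario An [xhwe_scenario()].
#' @param n Number of independent replicates to draw.
#' @return A data.frame with columns `n1m, n0m, n2f, n1f, n0f` (`n` rows).
#' @examples
#' set.seed(1)
#' simulate_counts(xhwe_scenario(p_m = 0.3, N = 800, r = c(2, 1)), n = 3)
#' @export
simulate_counts <- function(scenario, n = 1) {
  stopifnot(inherits(scenario, "xhwe_scenario"))
  if (!is.null(scenario$stratification)) {
    return(simulate_stratified(scenario, n))
  }
  n1m <- rbinom(n, scenario$Nm, scenario$p_m)
  fr <- female_genotype_freqs(scenario$p_f, scenario$rho)
  fem <- .sim_female(n, scenario$Nf, fr[1], fr[2], fr[3])
  data.frame(n1m = n1m, n0m = scenario$Nm - n1m,
             n2f = fem$n2f, n1f = fem$n1f, n0f = fem$n0f)
}

#' Draw genotype counts under the two-subpopulation stratification model
#'
#' Each of the `N` individuals independently belongs to subpopulation 1
#' with probability `mix` and is male with probability `male_prob`; males
#' draw one allele at their subpopulation's `p_m`, females draw a
#' Hardy-Weinberg genotype at `p_f = p_m + epsilon_k` (`rho = 0` within
#' subpopulations). The pooled counts are returned, so the mixture induces
#' apparent excess homozygosity (Wahlund effect). With
#' `fixed_sex_split = TRUE` the male count is fixed at
#' `round(N * male_prob)` instead of being binomial.
#'
#' @inheritParams simulate_counts
#' @return A data.frame with columns `n1m, n0m, n2f, n1f, n0f`.
#' @export
simulate_stratified <- function(scenario, n = 1) {
  stopifnot(inherits(scenario, "xhwe_scenario"),
            !is.null(scenario$stratification))
  s <- scenario$stratification
  N <- scenario$N
  if (s$fixed_sex_split) {
    nm <- rep(round(N * s$male_prob), n)
  } else {
    nm <- rbinom(n, N, s$male_prob)
  }
  nf <- N - nm
  nm1 <- rbinom(n, nm, s$mix)
  nm2 <- nm - nm1
  nf1 <- rbinom(n, nf, s$mix)
  nf2 <- nf - nf1
  n1m <- rbinom(n, nm1, s$p_m[1]) + rbinom(n, nm2, s$p_m[2])
  pf1 <- s$p_m[1] + s$epsilon[1]
  pf2 <- s$p_m[2] + s$epsilon[2]
  stopifnot(pf1 >= 0, pf1 <= 1, pf2 >= 0, pf2 <= 1)
  g1 <- .sim_female(n, nf1, pf1^2, 2 * pf1 * (1 - pf1), (1 - pf1)^2)
  g2 <- .sim_female(n, nf2, pf2^2, 2 * pf2 * (1 - pf2), (1 - pf2)^2)
  data.frame(n1m = n1m, n0m = (nm - n1m),
             n2f = g1$n2f + g2$n2f, n1f = g1$n1f + g2$n1f,
             n0f = g1$n0f + g2$n0f)
}
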