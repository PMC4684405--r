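# Parametric-bootstrap calibration of the likelihood-ratio statistics.

# compute only the LRT statistic `which` for a batch of count vectors
# (avoids the fits the statistic does not need; LRT2 works on the female
# log-likelihood alone since the male terms cancel)
.lrt_only <- function(which, n1m, n0m, n2f, n1f, n0f, tol, max_iter,
                      rho_init, male_w = 1) {
  Nm <- n1m + n0m
  Nf <- n2f + n1f + n0f
  N <- Nm + Nf
  h1 <- .em_female(n2f, n1f, n0f, tol, max_iter, rho_init)
  nonconv <- !h1$converged
  if (which == "LRT2") {
    pf02 <- ifelse(Nf > 0, (2 * n2f + n1f) / (2 * Nf), NA_real_)
    raw <- 2 * (.ll_female(n2f, n1f, n0f, h1$pf, h1$rho) -
                  .ll_female(n2f, n1f, n0f, pf02, 0))
  } else {
    pm <- ifelse(Nm > 0, n1m / Nm, NA_real_)
    ll1 <- .ll_vec(n1m, n0m, n2f, n1f, n0f, pm, h1$pf, h1$rho, male_w)
    if (which == "LRT0") {
      p0 <- (male_w * n1m + 2 * n2f + n1f) / (male_w * Nm + 2 * Nf)
      raw <- 2 * (ll1 - .ll_vec(n1m, n0m, n2f, n1f, n0f, p0, p0, 0, male_w))
    } else { # LRT1
      h01 <- .em_pooled(n1m, n0m, n2f, n1f, n0f, tol, max_iter, rho_init,
                        male_w)
      nonconv <- nonconv | !h01$converged
      raw <- 2 * (ll1 - .ll_vec(n1m, n0m, n2f, n1f, n0f, h01$p, h01$p,
                                h01$rho, male_w))
    }
  }
  list(stat = .lrt_clip(raw, tol, N, rho_init, max_iter), nonconv = nonconv)
}

#' Parametric-bootstrap calibrated likelihood-ratio tests
#'
#' Calibrates `LRT0`, `LRT2` (and `LRT1`) against their exact null
#' distribution instead of the chi-square approximation, which is
#' conservative because `rho = 0` lies on the boundary of the parameter
#' space. Procedure for `LRT0b`: (1) compute the observed `LRT0`;
#' (2) estimate the pooled frequency `p_hat = (n1m + 2 n2f + n1f) /
#' (Nm + 2 Nf)`; (3) regenerate the alleles of the `Nm` males from
#' `Binomial(Nm, p_hat)` and the genotypes of the `Nf` females from the
#' Hardy-Weinberg proportions at `p_hat`; (4) recompute `LRT0` on each of
#' `B` resamples; (5) estimate the p-value as the fraction of resampled
#' statistics strictly exceeding the observed one. For `LRT2b` the null
#' frequencies use the female-only estimate `p_f_hat = (2 n2f + n1f) /
#' (2 Nf)`, the male alleles stay fixed at their observed values, and only
#' the female genotypes are regenerated; for `LRT1b` the null is the fitted
#' `H01` model `(p_hat01, rho_hat01)`.
#'
#' Ties (resample statistic exactly equal to the observed) do not count as
#' exceedances; no +1 continuity correction is applied.
#'
#' @inheritParams fit_xhwe
#' @param which Statistic to calibrate: `"LRT0"`, `"LRT2"` or `"LRT1"`.
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed for the resampling stream (`NULL`: continue from
#'   the current RNG state). A fixed seed makes the p-value reproducible.
#' @return An `"xhwe_test"` object with `calibration = "bootstrap"`,
#'   `n_boot = B` and `n_nonconverged` (resamples whose EM hit the
#'   iteration cap; they are still used).
#' @examples
#' xhwe_boot(genotype_counts(50, 50, 40, 30, 30), "LRT2", B = 200, seed = 1)
#' @export
xhwe_boot <- function(counts, which = c("LRT0", "LRT2", "LRT1"), B = 1000,
                      seed = NULL, config = em_config(),
                      dosage_compensation = FALSE) {
  which <- match.arg(which)
  stopifnot(B >= 1)
  d <- .counts_df(counts)
  stopifnot(nrow(d) == 1L)
  w <- if (dosage_compensation) 2 else 1
  tol <- config$tolerance; mi <- config$max_iter; ri <- config$rho_init
  obs <- .lrt_only(which, d$n1m, d$n0m, d$n2f, d$n1f, d$n0f, tol, mi, ri, w)
  if (!is.finite(obs$stat)) {
    return(.new_test(paste0(which, "b"), NA_real_, NULL, NA_real_,
                     calibration = "bootstrap", n_boot = B,
                     note = "observed statistic undefined"))
  }
  Nm <- d$n1m + d$n0m
  Nf <- d$n2f + d$n1f + d$n0f
  if (!is.null(seed)) set.seed(seed)
  if (which == "LRT2") {
    pf <- (2 * d$n2f + d$n1f) / (2 * Nf)
    fem <- .sim_female(B, Nf, pf^2, 2 * pf * (1 - pf), (1 - pf)^2)
    n1m_s <- rep(d$n1m, B); n0m_s <- rep(d$n0m, B)
  } else {
    if (which == "LRT0") {
      p <- (w * d$n1m + 2 * d$n2f + d$n1f) / (w * Nm + 2 * Nf)
      rho <- 0
    } else {
      h01 <- .em_pooled(d$n1m, d$n0m, d$n2f, d$n1f, d$n0f, tol, mi, ri, w)
      p <- h01$p
      rho <- h01$rho
    }
    n1m_s <- rbinom(B, Nm, p)
    n0m_s <- Nm - n1m_s
    fem <- .sim_female(B, Nf, .fgf2(p, rho), .fgf1(p, rho), .fgf0(p, rho))
  }
  star <- .lrt_only(which, n1m_s, n0m_s, fem$n2f, fem$n1f, fem$n0f,
                    tol, mi, ri, w)
  .new_test(paste0(which, "b"), obs$stat, NULL,
            mean(star$stat > obs$stat), calibration = "bootstrap",
            n_boot = B, n_nonconverged = sum(star$nonconv),
            observed_nonconverged = obs$nonconv)
}
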