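# Single-locus test statistics and their asymptotic p-values.

.new_test <- function(name, statistic, df, p_value,
                      calibration = "asymptotic", ...) {
  structure(c(list(name = name, statistic = statistic, df = df,
                   p_value = p_value, calibration = calibration),
              list(...)),
            class = "xhwe_test")
}

#' @export
print.xhwe_test <- function(x, ...) {
  if (is.na(x$statistic)) {
    cat(sprintf("%s: undefined (%s)\n", x$name,
                if (!is.null(x$note)) x$note else "monomorphic data"))
    return(invisible(x))
  }
  df_txt <- if (x$calibration == "asymptotic") {
    sprintf(", df = %d", x$df)
  } else {
    sprintf(", %d bootstrap resamples", x$n_boot)
  }
  cat(sprintf("%s = %.4f%s, p-value = %.4g (%s)\n",
              x$name, x$statistic, df_txt, x$p_value, x$calibration))
  invisible(x)
}

#' Z1 test: equal allele frequencies in males and females
#'
#' `Z1 = (p_m_hat - p_f_hat)^2 / (Var(p_m_hat) + Var(p_f_hat))` with
#' `Var(p_m_hat) = p_m_hat (1 - p_m_hat) / Nm` and
#' `Var(p_f_hat) = (p_f_hat - 2 p_f_hat^2 + P(M1M1)_hat) / (2 Nf)`.
#' Asymptotically chi-square with 1 df under `p_m = p_f`. Undefined (NA)
#' when the total variance estimate is zero (monomorphic sample).
#'
#' @param counts A [genotype_counts()] object (or length-5 count vector).
#' @return An `"xhwe_test"` object.
#' @examples
#' xhwe_z1(genotype_counts(50, 50, 9, 42, 49))  # 11.2676
#' @export
xhwe_z1 <- function(counts) {
  z <- .z_batch(.counts_df(counts))
  .new_test("Z1", z$z1, 1L, pchisq(z$z1, 1, lower.tail = FALSE),
            note = if (is.na(z$z1)) "zero variance (monomorphic sample)")
}

#' Z2 test: zero inbreeding coefficient in females
#'
#' Based on the disequilibrium coefficient
#' `Delta_f = P(M1M1) - p_f^2 = rho p_f q_f`:
#' `Z2 = Nf * (Delta_f_hat + p_f_hat q_f_hat / (2 Nf))^2 /
#' (p_f_hat^2 q_f_hat^2)`. Uses females only; asymptotically chi-square
#' with 1 df under `rho = 0`. Undefined (NA) for monomorphic females.
#'
#' @inheritParams xhwe_z1
#' @return An `"xhwe_test"` object.
#' @export
xhwe_z2 <- function(counts) {
  z <- .z_batch(.counts_df(counts))
  .new_test("Z2", z$z2, 1L, pchisq(z$z2, 1, lower.tail = FALSE),
            note = if (is.na(z$z2)) "monomorphic females")
}

#' Z0 test: joint test of both null hypotheses
#'
#' `Z0 = Z1 + Z2`; the two components are independent under the joint null
#' `p_m = p_f, rho = 0`, so `Z0` is asymptotically chi-square with 2 df.
#'
#' @inheritParams xhwe_z1
#' @return An `"xhwe_test"` object.
#' @export
xhwe_z0 <- function(counts) {
  z <- .z_batch(.counts_df(counts))
  .new_test("Z0", z$z0, 2L, pchisq(z$z0, 2, lower.tail = FALSE),
            note = if (is.na(z$z0)) "a component statistic is undefined")
}

#' Likelihood-ratio tests for X-linked marker quality control
#'
#' `LRT0 = 2 [l(theta1_hat) - l(theta0_hat)]` tests the joint null
#' `p_m = p_f, rho = 0` (2 df); `LRT1` tests `p_m = p_f` with `rho` free
#' (1 df); `LRT2` tests `rho = 0` with frequencies free (1 df; male terms
#' cancel, so it uses females only). The unconstrained fit is obtained by
#' EM; asymptotic p-values use the central chi-square upper tail. Because
#' `rho = 0` sits on the boundary of the parameter space, the asymptotic
#' LRT0 and LRT2 are conservative; see [xhwe_boot()] for the
#' parametric-bootstrap calibrated versions.
#'
#' @inheritParams fit_xhwe
#' @param which One of `"LRT0"`, `"LRT1"`, `"LRT2"`.
#' @return An `"xhwe_test"` object; `$fits` holds the two `"xhwe_fit"`s.
#' @examples
#' xhwe_lrt(genotype_counts(30, 70, 9, 42, 49), "LRT0")  # exact null: 0
#' @export
xhwe_lrt <- function(counts, which = c("LRT0", "LRT1", "LRT2"),
                     config = em_config(), dosage_compensation = FALSE) {
  which <- match.arg(which)
  d <- .counts_df(counts)
  w <- if (dosage_compensation) 2 else 1
  fit <- .fit_batch(d, config$tolerance, config$max_iter, config$rho_init,
                    male_w = w)
  stat <- switch(which, LRT0 = fit$lrt0, LRT1 = fit$lrt1, LRT2 = fit$lrt2)
  df <- if (which == "LRT0") 2L else 1L
  .new_test(which, stat, df, pchisq(stat, df, lower.tail = FALSE),
            converged = fit$conv1 && (which != "LRT1" || fit$conv01),
            estimates = fit)
}

#' Run a battery of X-linked QC tests on one locus
#'
#' Convenience wrapper computing any subset of the nine statistics
#' (`Z1`, `Z2`, `Z0`, `LRT0`, `LRT1`, `LRT2`, `LRT0b`, `LRT1b`, `LRT2b`).
#'
#' @inheritParams fit_xhwe
#' @param tests Character vector of statistic names.
#' @param B Bootstrap resamples for the `*b` statistics.
#' @param seed Seed for the bootstrap streams (`NULL`: current RNG state).
#' @return A data.frame with one row per test: `test`, `statistic`, `df`,
#'   `p_value`, `calibration`.
#' @examples
#' xhwe_tests(genotype_counts(50, 50, 30, 40, 30),
#'            tests = c("Z1", "Z2", "LRT0"))
#' @export
xhwe_tests <- function(counts,
                       tests = c("Z1", "Z2", "Z0", "LRT0", "LRT1", "LRT2"),
                       B = 1000, seed = NULL, config = em_config(),
                       dosage_compensation = FALSE) {
  known <- c("Z1", "Z2", "Z0", "LRT0", "LRT1", "LRT2",
             "LRT0b", "LRT1b", "LRT2b")
  bad <- setdiff(tests, known)
  if (length(bad)) stop("unknown test(s): ", paste(bad, collapse = ", "))
  res <- lapply(tests, function(tn) {
    t <- if (tn %in% c("Z1", "Z2", "Z0")) {
      switch(tn, Z1 = xhwe_z1(counts), Z2 = xhwe_z2(counts),
             Z0 = xhwe_z0(counts))
    } else if (tn %in% c("LRT0", "LRT1", "LRT2")) {
      xhwe_lrt(counts, tn, config, dosage_compensation)
    } else {
      xhwe_boot(counts, sub("b$", "", tn), B = B, seed = seed,
                config = config, dosage_compensation = dosage_compensation)
    }
    data.frame(test = tn, statistic = t$statistic,
               df = if (is.null(t$df)) NA_integer_ else t$df,
               p_value = t$p_value, calibration = t$calibration)
  })
  do.call(rbind, res)
}
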