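#' EM configuration
#'
#' Controls the EM iterations used by the likelihood fits. The defaults
#' mirror the reference software behaviour: convergence when the absolute
#' change of every parameter between consecutive iterations falls below
#' `1e-7`, at most 1000 iterations, and an initial inbreeding coefficient
#' of 0.02 (allele-frequency parameters start at their moment estimates).
#'
#' @param tolerance Convergence threshold on the maximum absolute parameter
#'   change (> 0).
#' @param max_iter Iteration cap (>= 1).
#' @param rho_init Initial value for `rho`, strictly inside (0, 1).
#' @return A list of class `"em_config"`.
#' @export
em_config <- function(tolerance = 1e-7, max_iter = 1000L, rho_init = 0.02) {
  stopifnot(tolerance > 0, max_iter >= 1, rho_init > 0, rho_init < 1)
  structure(list(tolerance = tolerance, max_iter = as.integer(max_iter),
                 rho_init = rho_init),
            class = "em_config")
}

#' Maximum-likelihood fit of the X-linked genotype model
#'
#' Fits the model `(p_m, p_f, rho)` under one of four parameter constraints:
#' \describe{
#'   \item{`"H1"`}{unconstrained (with `rho >= 0`): `p_m = n1m/Nm` in closed
#'     form; `(p_f, rho)` by EM over the latent split of the female
#'     homozygote cells.}
#'   \item{`"H0"`}{`p_m = p_f = p`, `rho = 0`: closed form,
#'     `p = (n1m + 2*n2f + n1f) / (Nm + 2*Nf)`.}
#'   \item{`"H01"`}{`p_m = p_f = p`, `rho` free: EM over `(p, rho)`.}
#'   \item{`"H02"`}{`rho = 0`, frequencies free: closed form,
#'     `p_m = n1m/Nm`, `p_f = (2*n2f + n1f) / (2*Nf)`.}
#' }
#' Degenerate female samples (no heterozygotes, or monomorphic) are resolved
#' at the analytic boundary; monomorphic females leave `rho` unidentifiable
#' and the fit is flagged via `boundary = TRUE` with `rho = 0`.
#'
#' @param counts A [genotype_counts()] object (or length-5 count vector).
#' @param hypothesis One of `"H1"`, `"H0"`, `"H01"`, `"H02"`.
#' @param config An [em_config()].
#' @param dosage_compensation If `TRUE`, male alleles are double-counted in
#'   the likelihood and in the pooled-frequency estimates (X-inactivation
#'   allele-counting convention). Affects only `"H0"`/`"H01"` estimates and
#'   all reported log-likelihoods.
#' @param trace If `TRUE` (EM hypotheses only), attach the per-iteration
#'   observed-data log-likelihood as attribute `"loglik_trace"`.
#' @return An object of class `"xhwe_fit"`: list with `hypothesis`, `p_m`,
#'   `p_f`, `rho`, `loglik`, `n_iter`, `converged`, `boundary`.
#' @examples
#' cts <- genotype_counts(30, 70, 9, 42, 49)
#' fit_xhwe(cts, "H1")
#' fit_xhwe(cts, "H0")$p_m  # pooled frequency 0.3
#' @export
fit_xhwe <- function(counts, hypothesis = c("H1", "H0", "H01", "H02"),
                     config = em_config(), dosage_compensation = FALSE,
                     trace = FALSE) {
  hypothesis <- match.arg(hypothesis)
  d <- .counts_df(counts)
  stopifnot(nrow(d) == 1L)
  w <- if (dosage_compensation) 2 else 1
  Nm <- d$n1m + d$n0m
  Nf <- d$n2f + d$n1f + d$n0f
  if (hypothesis %in% c("H1", "H02") && (Nm < 1 || Nf < 1)) {
    if (Nf < 1) stop("fit under ", hypothesis, " requires at least one female")
  }
  tol <- config$tolerance
  trace_ll <- NULL
  if (hypothesis == "H1") {
    pm <- if (Nm > 0) d$n1m / Nm else NA_real_
    f <- .em_female(d$n2f, d$n1f, d$n0f, tol, config$max_iter,
                    config$rho_init, trace = trace)
    pf <- f$pf; rho <- f$rho
    n_iter <- f$n_iter; conv <- f$converged; bound <- f$boundary
    if (trace && !is.null(f$ll_trace)) {
      trace_ll <- f$ll_trace + w * (.xlogy(d$n1m, pm) + .xlogy(d$n0m, 1 - pm))
    }
  } else if (hypothesis == "H0") {
    p <- (w * d$n1m + 2 * d$n2f + d$n1f) / (w * Nm + 2 * Nf)
    pm <- pf <- p; rho <- 0
    n_iter <- 0L; conv <- TRUE; bound <- FALSE
  } else if (hypothesis == "H01") {
    f <- .em_pooled(d$n1m, d$n0m, d$n2f, d$n1f, d$n0f, tol, config$max_iter,
                    config$rho_init, male_w = w, trace = trace)
    pm <- pf <- f$p; rho <- f$rho
    n_iter <- f$n_iter; conv <- f$converged; bound <- f$boundary
    trace_ll <- f$ll_trace
  } else { # H02
    pm <- if (Nm > 0) d$n1m / Nm else NA_real_
    pf <- (2 * d$n2f + d$n1f) / (2 * Nf)
    rho <- 0
    n_iter <- 0L; conv <- TRUE; bound <- FALSE
  }
  out <- structure(
    list(hypothesis = hypothesis, p_m = pm, p_f = pf, rho = rho,
         loglik = .ll_vec(d$n1m, d$n0m, d$n2f, d$n1f, d$n0f, pm, pf, rho, w),
         n_iter = n_iter, converged = conv, boundary = bound,
         dosage_compensation = dosage_compensation),
    class = "xhwe_fit")
  if (!is.null(trace_ll)) attr(out, "loglik_trace") <- trace_ll
  out
}

#' @export
print.xhwe_fit <- function(x, ...) {
  cat(sprintf("MLE under %s: p_m = %.6f, p_f = %.6f, rho = %.6f\n",
              x$hypothesis, x$p_m, x$p_f, x$rho))
  cat(sprintf("  log-likelihood = %.6f (%d EM iterations%s%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "" else ", NOT converged",
              if (x$boundary) ", boundary fit" else ""))
  invisible(x)
}

#' Moment estimator of the female inbreeding coefficient
#'
#' `rho_z = (P(M1M1)_hat - p_f_hat^2) / (p_f_hat * q_f_hat)` with
#' `p_f_hat = (2*n2f + n1f) / (2*Nf)` and `P(M1M1)_hat = n2f / Nf`. The
#' value is reported as-is and may be negative (heterozygote excess); it is
#' undefined for monomorphic females.
#'
#' @param counts A [genotype_counts()] object (or length-5 count vector).
#' @return The moment estimate of `rho`.
#' @examples
#' rho_moment(genotype_counts(0, 0, 25, 0, 25))   # 1: no heterozygotes
#' rho_moment(genotype_counts(0, 0, 20, 60, 20))  # -0.2: excess heterozygotes
#' @export
rho_moment <- function(counts) {
  d <- .counts_df(counts)
  z <- .z_batch(d)
  if (!is.finite(z$rho_z)) {
    stop(structure(
      class = c("xhweqc_undefined", "error", "condition"),
      list(message = "rho_z is undefined for monomorphic females",
           call = sys.call())))
  }
  z$rho_z
}
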