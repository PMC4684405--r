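#' Per-locus genotype counts for a biallelic X-chromosome marker
#'
#' Bundles the observed data at one X-linked locus. Males are hemizygous, so
#' each genotyped male contributes a single allele (`n1m` carry M1, `n0m`
#' carry M2); females contribute a full genotype (`n2f` M1M1, `n1f` M1M2,
#' `n0f` M2M2). Derived totals `Nm`, `Nf` and `N = Nm + Nf` are stored with
#' the cells.
#'
#' @param n1m Number of males carrying allele M1 (nonnegative integer).
#'   Alternatively a single vector of length 5 giving all cells in the order
#'   `(n1m, n0m, n2f, n1f, n0f)`.
#' @param n0m Number of males carrying allele M2.
#' @param n2f Number of M1M1 females.
#' @param n1f Number of M1M2 females.
#' @param n0f Number of M2M2 females.
#'
#' @return An object of class `"genotype_counts"`: a list with the five
#'   cells plus `Nm`, `Nf`, `N`.
#' @examples
#' genotype_counts(30, 70, 9, 42, 49)
#' genotype_counts(c(30, 70, 9, 42, 49))
#' @export
genotype_counts <- function(n1m, n0m, n2f, n1f, n0f) {
  if (missing(n0m) && length(n1m) == 5L) {
    v <- as.numeric(n1m)
  } else if (missing(n0m) || missing(n2f) || missing(n1f) ||
             missing(n0f)) {
    stop("genotype_counts needs the five cells (n1m, n0m, n2f, n1f, n0f)")
  } else {
    v <- c(n1m, n0m, n2f, n1f, n0f)
  }
  if (length(v) != 5L || anyNA(v)) {
    stop("genotype_counts needs the five cells (n1m, n0m, n2f, n1f, n0f)")
  }
  if (any(v < 0) || any(abs(v - round(v)) > 1e-8)) {
    stop("all genotype counts must be nonnegative integers")
  }
  v <- round(v)
  structure(
    list(n1m = v[1], n0m = v[2], n2f = v[3], n1f = v[4], n0f = v[5],
         Nm = v[1] + v[2], Nf = v[3] + v[4] + v[5], N = sum(v)),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("X-linked genotype counts\n")
  cat(sprintf("  males   : M1 = %d, M2 = %d (Nm = %d)\n", x$n1m, x$n0m, x$Nm))
  cat(sprintf("  females : M1M1 = %d, M1M2 = %d, M2M2 = %d (Nf = %d)\n",
              x$n2f, x$n1f, x$n0f, x$Nf))
  invisible(x)
}

#' @export
as.data.frame.genotype_counts <- function(x, ...) {
  data.frame(n1m = x$n1m, n0m = x$n0m, n2f = x$n2f, n1f = x$n1f, n0f = x$n0f)
}

# coerce either a genotype_counts object or a 5-vector to the internal
# one-row count data.frame used by the vectorised core
.counts_df <- function(counts) {
  if (inherits(counts, "genotype_counts")) {
    as.data.frame(counts)
  } else if (is.numeric(counts) && length(counts) == 5L) {
    as.data.frame(genotype_counts(counts))
  } else if (is.data.frame(counts)) {
    stopifnot(all(c("n1m", "n0m", "n2f", "n1f", "n0f") %in% names(counts)))
    counts
  } else {
    stop("expected a genotype_counts object or a length-5 count vector")
  }
}

#' Female genotype frequencies under the inbreeding model
#'
#' With female M1 frequency `p_f` and inbreeding coefficient `rho`, the
#' female genotype frequencies are
#' `P(M1M1) = p_f^2 + rho * p_f * q_f`,
#' `P(M1M2) = 2 * (1 - rho) * p_f * q_f`,
#' `P(M2M2) = q_f^2 + rho * p_f * q_f`, with `q_f = 1 - p_f`.
#' `rho = 0` recovers Hardy-Weinberg proportions; `rho = 1` removes all
#' heterozygotes. `rho` is restricted to `[0, 1]` (excess homozygosity).
#'
#' @param p_f Female M1 allele frequency in `[0, 1]`.
#' @param rho Female inbreeding coefficient in `[0, 1]`.
#' @return For scalar input, a named numeric vector `(M1M1, M1M2, M2M2)`;
#'   for vector input, a matrix with one row per element.
#' @examples
#' female_genotype_freqs(0.5, 0)    # HWE: 0.25 0.50 0.25
#' female_genotype_freqs(0.3, 0.1)
#' @export
female_genotype_freqs <- function(p_f, rho) {
  if (any(p_f < 0 | p_f > 1)) stop("p_f must lie in [0, 1]")
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  f2 <- .fgf2(p_f, rho)
  f1 <- .fgf1(p_f, rho)
  f0 <- .fgf0(p_f, rho)
  if (any(f2 < 0 | f1 < 0 | f0 < 0)) {
    stop("invalid parameters: a genotype frequency is negative")
  }
  if (length(p_f) == 1L && length(rho) == 1L) {
    c(M1M1 = f2, M1M2 = f1, M2M2 = f0)
  } else {
    cbind(M1M1 = f2, M1M2 = f1, M2M2 = f0)
  }
}

#' Observed-data log-likelihood of an X-linked locus
#'
#' Log of the product of the male binomial and female multinomial sampling
#' probabilities, with the combinatorial constants dropped (they cancel in
#' every likelihood ratio computed by the package). Cells with zero count
#' contribute 0 via the convention `0 * log(0) = 0`; a zero-probability cell
#' with a positive count yields `-Inf`.
#'
#' @param counts A [genotype_counts()] object (or length-5 count vector).
#' @param p_m Male M1 allele frequency.
#' @param p_f Female M1 allele frequency.
#' @param rho Female inbreeding coefficient.
#' @param dosage_compensation If `TRUE`, each male allele is counted twice
#'   (the allele-counting convention under X inactivation / dosage
#'   compensation), i.e. the male log-likelihood terms are doubled.
#' @return The log-likelihood value (may be `-Inf`).
#' @examples
#' x_loglik(genotype_counts(1, 1, 1, 1, 1), 0.5, 0.5, 0)  # -4.852030
#' @export
x_loglik <- function(counts, p_m, p_f, rho, dosage_compensation = FALSE) {
  d <- .counts_df(counts)
  .ll_vec(d$n1m, d$n0m, d$n2f, d$n1f, d$n0f, p_m, p_f, rho,
          male_w = if (dosage_compensation) 2 else 1)
}
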