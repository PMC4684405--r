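# Vectorised likelihood / EM core. Every function here operates elementwise
# on equal-length count vectors so that single loci, Monte-Carlo replicates
# and bootstrap resamples all share one code path.

.fgf2 <- function(pf, rho) pf^2 + rho * pf * (1 - pf)
.fgf1 <- function(pf, rho) 2 * (1 - rho) * pf * (1 - pf)
.fgf0 <- function(pf, rho) (1 - pf)^2 + rho * pf * (1 - pf)

# x * log(y) with the convention 0 * log(0) = 0
.xlogy <- function(x, y) {
  r <- x * log(y)
  r[x == 0] <- 0
  r
}

.ll_vec <- function(n1m, n0m, n2f, n1f, n0f, pm, pf, rho, male_w = 1) {
  male_w * (.xlogy(n1m, pm) + .xlogy(n0m, 1 - pm)) +
    .ll_female(n2f, n1f, n0f, pf, rho)
}

.ll_female <- function(n2f, n1f, n0f, pf, rho) {
  .xlogy(n2f, .fgf2(pf, rho)) + .xlogy(n1f, .fgf1(pf, rho)) +
    .xlogy(n0f, .fgf0(pf, rho))
}

# E-step: expected split of the female homozygote cells into their
# "independent-alleles" and "identical-by-descent" components.
#   w1 + w2 = n2f (M1M1), w3 + w4 = n0f (M2M2)
.estep <- function(n2f, n0f, pf, rho) {
  qf <- 1 - pf
  pq <- rho * pf * qf
  d2 <- pf^2 + pq
  d0 <- qf^2 + pq
  list(
    w1 = ifelse(d2 > 0, n2f * pf^2 / d2, 0),
    w2 = ifelse(d2 > 0, n2f * pq / d2, 0),
    w3 = ifelse(d0 > 0, n0f * qf^2 / d0, 0),
    w4 = ifelse(d0 > 0, n0f * pq / d0, 0)
  )
}

# EM for the female block (p_f, rho); the male allele frequency separates
# and never enters these updates. Degenerate female configurations are
# resolved analytically before iterating:
#   - no female data: p_f, rho not estimable (NA / 0, flagged);
#   - monomorphic females (n2f == Nf or n0f == Nf): p_f at the boundary,
#     rho not identifiable -> rho = 0, flagged.
# Females that are all heterozygous or lack heterozygotes entirely are
# handled by the iteration itself (rho -> 0 resp. rho -> 1).
.em_female <- function(n2f, n1f, n0f, tol = 1e-7, max_iter = 1000L,
                       rho_init = 0.02, trace = FALSE) {
  n <- length(n2f)
  Nf <- n2f + n1f + n0f
  pf <- ifelse(Nf > 0, (2 * n2f + n1f) / (2 * Nf), NA_real_)
  rho <- rep(rho_init, n)
  nodata <- !(Nf > 0)
  mono <- Nf > 0 & (n2f == Nf | n0f == Nf)
  rho[nodata | mono] <- 0
  active <- !(nodata | mono)
  # nudge boundary starting values so E-step ratios are defined
  pf[active] <- pmin(pmax(pf[active], 1e-6), 1 - 1e-6)
  n_iter <- integer(n)
  done <- !active
  it <- 0L
  ll_trace <- if (trace && n == 1L) .ll_female(n2f, n1f, n0f, pf, rho)
  while (any(!done) && it < max_iter) {
    it <- it + 1L
    idx <- which(!done)
    e <- .estep(n2f[idx], n0f[idx], pf[idx], rho[idx])
    pf_new <- (2 * e$w1 + e$w2 + n1f[idx] + e$w4) / (2 * Nf[idx])
    den <- e$w2 + e$w4 + n1f[idx]
    rho_new <- ifelse(den > 0, (e$w2 + e$w4) / den, 0)
    delta <- pmax(abs(pf_new - pf[idx]), abs(rho_new - rho[idx]))
    pf[idx] <- pf_new
    rho[idx] <- rho_new
    n_iter[idx] <- it
    done[idx[delta < tol]] <- TRUE
    if (!is.null(ll_trace)) {
      ll_trace <- c(ll_trace, .ll_female(n2f, n1f, n0f, pf, rho))
    }
  }
  list(pf = pf, rho = rho, n_iter = n_iter,
       converged = done, boundary = mono | nodata, ll_trace = ll_trace)
}

# EM under the pooled-frequency constraint p_m = p_f = p with rho free.
# male_w = 2 doubles every male allele (dosage-compensation convention).
# Monomorphic-female records fall back to the closed-form pooled fit with
# rho = 0 (same boundary rule as .em_female), which coincides with the
# joint-null fit there.
.em_pooled <- function(n1m, n0m, n2f, n1f, n0f, tol = 1e-7, max_iter = 1000L,
                       rho_init = 0.02, male_w = 1, trace = FALSE) {
  n <- length(n2f)
  Nm <- n1m + n0m
  Nf <- n2f + n1f + n0f
  denom <- male_w * Nm + 2 * Nf
  p <- ifelse(denom > 0, (male_w * n1m + 2 * n2f + n1f) / denom, NA_real_)
  rho <- rep(rho_init, n)
  nodata <- !(denom > 0)
  mono <- !(Nf > 0) | (n2f == Nf | n0f == Nf)
  rho[nodata | mono] <- 0
  active <- !(nodata | mono)
  p[active] <- pmin(pmax(p[active], 1e-6), 1 - 1e-6)
  n_iter <- integer(n)
  done <- !active
  it <- 0L
  ll_trace <- if (trace && n == 1L) {
    .ll_vec(n1m, n0m, n2f, n1f, n0f, p, p, rho, male_w)
  }
  while (any(!done) && it < max_iter) {
    it <- it + 1L
    idx <- which(!done)
    e <- .estep(n2f[idx], n0f[idx], p[idx], rho[idx])
    p_new <- (2 * e$w1 + e$w2 + e$w4 + n1f[idx] + male_w * n1m[idx]) /
      denom[idx]
    den <- e$w2 + e$w4 + n1f[idx]
    rho_new <- ifelse(den > 0, (e$w2 + e$w4) / den, 0)
    delta <- pmax(abs(p_new - p[idx]), abs(rho_new - rho[idx]))
    p[idx] <- p_new
    rho[idx] <- rho_new
    n_iter[idx] <- it
    done[idx[delta < tol]] <- TRUE
    if (!is.null(ll_trace)) {
      ll_trace <- c(ll_trace, .ll_vec(n1m, n0m, n2f, n1f, n0f, p, p, rho,
                                      male_w))
    }
  }
  list(p = p, rho = rho, n_iter = n_iter,
       converged = done, boundary = mono | nodata, ll_trace = ll_trace)
}

# 2 * (ll1 - ll_constrained), floored at 0. Small negatives are expected:
# the EM stops on a parameter-change criterion, so at a boundary optimum a
# parameter error of order `tol` leaves the log-likelihood short by about
# `tol * N`, and a run cut off by the iteration cap while contracting
# geometrically towards `rho = 0` can be short by up to about
# `N * rho_init / max_iter`. Anything far beyond these bounds indicates a
# genuine defect and is raised, not clipped.
.lrt_clip <- function(raw, tol, N, rho_init = 0.02, max_iter = 1000L) {
  bad <- raw < -(tol * (10 + 2 * N) + 2 * N * rho_init / max_iter)
  if (any(bad, na.rm = TRUE)) {
    stop("internal consistency failure: constrained fit exceeds the ",
         "unconstrained fit by more than the EM tolerance allows")
  }
  pmax(raw, 0)
}

# All maximum-likelihood fits and LRT statistics for a batch of count
# vectors. Returns a data.frame with one row per input record.
.fit_batch <- function(d, tol = 1e-7, max_iter = 1000L, rho_init = 0.02,
                       male_w = 1) {
  n1m <- d$n1m; n0m <- d$n0m; n2f <- d$n2f; n1f <- d$n1f; n0f <- d$n0f
  Nm <- n1m + n0m
  Nf <- n2f + n1f + n0f
  N <- Nm + Nf

  pm1 <- ifelse(Nm > 0, n1m / Nm, NA_real_)
  h1 <- .em_female(n2f, n1f, n0f, tol, max_iter, rho_init)
  ll1 <- .ll_vec(n1m, n0m, n2f, n1f, n0f, pm1, h1$pf, h1$rho, male_w)

  p0 <- (male_w * n1m + 2 * n2f + n1f) / (male_w * Nm + 2 * Nf)
  ll0 <- .ll_vec(n1m, n0m, n2f, n1f, n0f, p0, p0, 0, male_w)

  h01 <- .em_pooled(n1m, n0m, n2f, n1f, n0f, tol, max_iter, rho_init, male_w)
  ll01 <- .ll_vec(n1m, n0m, n2f, n1f, n0f, h01$p, h01$p, h01$rho, male_w)

  pf02 <- ifelse(Nf > 0, (2 * n2f + n1f) / (2 * Nf), NA_real_)
  ll02 <- .ll_vec(n1m, n0m, n2f, n1f, n0f, pm1, pf02, 0, male_w)

  data.frame(
    pm1 = pm1, pf1 = h1$pf, rho1 = h1$rho, ll1 = ll1,
    iter1 = h1$n_iter, conv1 = h1$converged, bound1 = h1$boundary,
    p0 = p0, ll0 = ll0,
    p01 = h01$p, rho01 = h01$rho, ll01 = ll01,
    iter01 = h01$n_iter, conv01 = h01$converged, bound01 = h01$boundary,
    pm02 = pm1, pf02 = pf02, ll02 = ll02,
    lrt0 = .lrt_clip(2 * (ll1 - ll0), tol, N, rho_init, max_iter),
    lrt1 = .lrt_clip(2 * (ll1 - ll01), tol, N, rho_init, max_iter),
    lrt2 = .lrt_clip(2 * (ll1 - ll02), tol, N, rho_init, max_iter)
  )
}

# Moment statistics: Z1 (allele-frequency equality), Z2 (excess female
# homozygosity), Z0 = Z1 + Z2, and the moment estimator of rho (unclipped,
# may be negative). Undefined entries are NA.
.z_batch <- function(d) {
  n1m <- d$n1m; n0m <- d$n0m; n2f <- d$n2f; n1f <- d$n1f; n0f <- d$n0f
  Nm <- n1m + n0m
  Nf <- n2f + n1f + n0f
  pm <- ifelse(Nm > 0, n1m / Nm, NA_real_)
  pf <- ifelse(Nf > 0, (2 * n2f + n1f) / (2 * Nf), NA_real_)
  qf <- 1 - pf
  P2 <- ifelse(Nf > 0, n2f / Nf, NA_real_)
  vm <- pm * (1 - pm) / Nm
  vf <- (pf - 2 * pf^2 + P2) / (2 * Nf)
  vtot <- vm + vf
  z1 <- ifelse(is.finite(vtot) & vtot > 0, (pm - pf)^2 / vtot, NA_real_)
  delta <- P2 - pf^2
  polyf <- is.finite(pf) & pf > 0 & pf < 1
  z2 <- ifelse(polyf,
               Nf * (delta + pf * qf / (2 * Nf))^2 / (pf^2 * qf^2),
               NA_real_)
  rho_z <- ifelse(polyf, delta / (pf * qf), NA_real_)
  data.frame(z1 = z1, z2 = z2, z0 = z1 + z2, rho_z = rho_z,
             pm = pm, pf = pf)
}

# draw multinomial female genotype counts by sequential binomial splitting;
# works with vector-valued sizes (one replicate per element)
.sim_female <- function(n, Nf, f2, f1, f0) {
  f2 <- pmin(pmax(f2, 0), 1)
  n2f <- rbinom(n, Nf, f2)
  rest <- Nf - n2f
  p1 <- ifelse(f2 < 1, pmin(pmax(f1 / (1 - f2), 0), 1), 0)
  n1f <- rbinom(n, rest, p1)
  list(n2f = n2f, n1f = n1f, n0f = rest - n1f)
}

# deterministic, order-independent stream seeds (kept below 2^31)
.derive_seed <- function(seed, index) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + index * 7919) %%
               2147483629) + 1L
}
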