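#' Temporal SNR of repeated b = 0 images
#'
#' tSNR = mean / sample standard deviation (denominator n - 1) across the
#' repetitions, computed voxel-wise. Zero-variance series are flagged as
#' undefined (NA) rather than returning infinity.
#'
#' @param b0_series numeric vector (one voxel) or voxels x repetitions
#'   matrix of b = 0 signals at a fixed TE
#' @return data.frame with columns `mean`, `sd`, `tsnr`, `undefined`
#' @export
tsnr <- function(b0_series) {
  if (is.vector(b0_series)) b0_series <- matrix(b0_series, nrow = 1)
  if (ncol(b0_series) < 2) stop("tSNR needs at least 2 repetitions")
  m <- rowMeans(b0_series)
  s <- apply(b0_series, 1, stats::sd)
  undef <- s == 0
  data.frame(mean = m, sd = s,
             tsnr = ifelse(undef, NA_real_, m / s), undefined = undef)
}

## first moment of the noncentral-chi magnitude (nu = underlying signal,
## sigma = per-channel sd, coils complex channels): E|M| = sigma E[sqrt(Q)]
## with Q ~ noncentral chi-square(2*coils, (nu/sigma)^2)
.ncchi_mean <- function(nu, sigma, coils = 1) {
  if (sigma == 0) return(nu)
  x <- (nu / sigma)^2
  if (coils == 1) {
    ## Rician closed form; expon.scaled Bessel terms absorb exp(-x/4)
    h <- x / 4
    sigma * sqrt(pi / 2) *
      ((1 + x / 2) * besselI(h, 0, expon.scaled = TRUE) +
         (x / 2) * besselI(h, 1, expon.scaled = TRUE))
  } else {
    sigma * stats::integrate(function(q) sqrt(q) * stats::dchisq(q, 2 * coils,
                                                                 ncp = x),
                             0, Inf, rel.tol = 1e-10)$value
  }
}

#' Correct magnitude data for Rician / noncentral-chi noise bias
#'
#' Inverts the first-moment relation of the noncentral-chi magnitude
#' distribution by bounded root finding: given an observed magnitude and
#' an estimate of the Gaussian channel standard deviation and coil count,
#' returns the underlying signal whose expected magnitude equals the
#' observation. Magnitudes at or below the pure-noise expectation map
#' to 0.
#'
#' @param magnitude observed magnitude(s), >= 0
#' @param sigma Gaussian noise standard deviation, >= 0
#' @param coils number of coils, >= 1
#' @return bias-reduced signal estimate(s)
#' @export
rician_correct <- function(magnitude, sigma, coils = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (coils < 1) stop("coils must be >= 1")
  if (sigma == 0) return(magnitude)
  floor0 <- .ncchi_mean(0, sigma, coils)
  vapply(magnitude, function(m) {
    if (m <= floor0) return(0)
    if (m > 50 * sigma) {
      ## asymptotic regime: E|M|^2 = nu^2 + (2 coils - 1) sigma^2 would be
      ## the second-moment inverse; the first-moment inverse is close and
      ## the root-finder converges in a couple of steps from this start
      lo <- max(0, m - 2 * sigma)
    } else lo <- 0
    stats::uniroot(function(nu) .ncchi_mean(nu, sigma, coils) - m,
                   lower = lo, upper = m + 3 * sigma, tol = 1e-10 * sigma)$root
  }, numeric(1))
}

#' Mono-exponential T2 fit to the b = 0 signal decay
#'
#' Nonlinear least squares of `S0 exp(-TE/T2)` against the b = 0 signals,
#' initialised from the log-linear regression and refined with bounded
#' optimisation (T2 within `t2_bounds`). A non-decaying series drives T2
#' to the upper bound, which is flagged.
#'
#' @param b0_signals positive signal values
#' @param tes echo times, ms (>= 2 distinct values)
#' @param t2_bounds T2 search interval in ms (default c(1, 2000))
#' @return list with `t2` (ms), `r2` (1/s), `s0`, `rss`, `hit_bound`
#' @export
fit_monoexp_t2 <- function(b0_signals, tes, t2_bounds = c(1, 2000)) {
  y <- as.numeric(b0_signals); te <- as.numeric(tes)
  if (length(y) != length(te)) stop("signal/TE length mismatch")
  if (length(unique(te)) < 2) stop("need at least 2 distinct TEs")
  if (any(y <= 0)) stop("b = 0 signals must be positive")
  ## log-linear start
  cf <- stats::lm.fit(cbind(1, te), log(y))$coefficients
  t2_start <- if (cf[2] < 0) -1 / cf[2] else t2_bounds[2]
  t2_start <- min(max(t2_start, t2_bounds[1]), t2_bounds[2])
  obj <- function(p) sum((y - p[1] * exp(-te / p[2]))^2)
  fit <- stats::optim(c(exp(cf[1]), t2_start), obj, method = "L-BFGS-B",
                      lower = c(1e-12, t2_bounds[1]),
                      upper = c(10 * max(y), t2_bounds[2]),
                      control = list(factr = 10, maxit = 500))
  t2 <- unname(fit$par[2])
  list(t2 = t2, r2 = 1000 / t2, s0 = unname(fit$par[1]), rss = fit$value,
       hit_bound = (t2_bounds[2] - t2) < 1e-6 * diff(t2_bounds) ||
                   (t2 - t2_bounds[1]) < 1e-6 * diff(t2_bounds))
}

## published fitting boundaries for (f, D||i, D||e, D_|_e, T2i, T2e);
## S0 is appended as a seventh free parameter with bounds (0, 10 max(y)]
.compartmental_bounds <- function(max_signal) {
  list(lower = c(f = 0, d_par_i = 0, d_par_e = 0, d_perp_e = 0,
                 t2_i = 30, t2_e = 30, s0 = 1e-9),
       upper = c(f = 1, d_par_i = 3, d_par_e = 3, d_perp_e = 2,
                 t2_i = 300, t2_e = 300, s0 = 10 * max_signal))
}

#' Bounded multi-start fit of the compartmental diffusion-T2 model
#'
#' Fits the seven-parameter stick/zeppelin model with compartmental T2
#' (delta fODF at the supplied fibre orientation) by bounded nonlinear
#' least squares. Parameters are optimised in unit-box coordinates
#' (L-BFGS-B), restarted from three deterministic start points (the
#' normalised midpoint 0.5 and 0.25/0.75), and the solution with the
#' lowest residual norm wins. Bounds are
#' `[0, 0, 0, 0, 30 ms, 30 ms]` to `[1, 3, 3, 2 um^2/ms, 300 ms, 300 ms]`
#' for (f, D||,i, D||,e, D_|_,e, T2,i, T2,e); estimates within 1e-6 of a
#' bound (normalised) raise the `hit_boundary` flag and such voxels are
#' excluded downstream.
#'
#' @param signal numeric signal vector (one per grid entry)
#' @param grid an [acquisition_grid] covering >= 2 TEs and >= 2 nonzero
#'   b-shells
#' @param n fixed unit fibre orientation (from the upstream fODF peak)
#' @return list with `params` ([tissue_params]), `r2_i`, `r2_e` (1/s),
#'   `rss`, `converged`, `hit_boundary`
#' @export
fit_compartmental <- function(signal, grid, n) {
  stopifnot(inherits(grid, "acquisition_grid"))
  .check_unit(n, "n")
  y <- as.numeric(signal)
  if (length(y) != grid$n) stop("signal length does not match grid")
  if (length(unique(grid$te)) < 2) stop("grid must cover >= 2 TEs")
  if (length(unique(grid$b[grid$b > 0])) < 2)
    stop("grid must cover >= 2 nonzero b-shells")
  if (grid$n < 8) stop("fewer observations than parameters")
  bounds <- .compartmental_bounds(max(y))
  lo <- bounds$lower; hi <- bounds$upper; rng <- hi - lo
  q <- .bgn2(grid, n)                # b (g.n)^2, fixed across iterations
  b <- grid$b; te <- grid$te
  ## canonical entry order makes the fit exactly invariant to the
  ## ordering of the acquisition table (summation order and optimizer
  ## path are then identical)
  ord <- order(te, b, q, y)
  y <- y[ord]; q <- q[ord]; b <- b[ord]; te <- te[ord]
  model <- function(p) {
    p[7] * (p[1] * exp(-te / p[5] - q * p[2]) +
            (1 - p[1]) * exp(-te / p[6] - (b - q) * p[4] - q * p[3]))
  }
  obj <- function(u) {
    r <- y - model(lo + u * rng)
    sum(r * r)
  }
  best <- NULL
  for (u0 in c(0.5, 0.25, 0.75)) {
    fit <- stats::optim(rep(u0, 7), obj, method = "L-BFGS-B",
                        lower = rep(0, 7), upper = rep(1, 7),
                        control = list(factr = 10, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  u <- best$par
  p <- unname(lo + u * rng)
  hit <- any(pmin(u[1:6], 1 - u[1:6]) < 1e-6)
  est <- tissue_params(f = p[1], d_par_i = p[2], d_par_e = p[3],
                       d_perp_e = min(p[4], p[3] + 1e-12),
                       t2_i = p[5], t2_e = p[6], s0 = p[7])
  ## L-BFGS-B code 52 (line-search failure) at the winning restart means
  ## the search hit machine resolution at an optimum of this smooth,
  ## box-bounded objective; genuine failures (iteration limit etc.) are
  ## the codes flagged here
  list(params = est, r2_i = 1000 / p[5], r2_e = 1000 / p[6],
       rss = best$value, converged = best$convergence %in% c(0L, 52L),
       hit_boundary = hit)
}

#' Single-fibre-population voxel selection
#'
#' A voxel is accepted as a single-fibre population (SFP) iff the
#' second-largest fODF peak is at most 10% of the largest, the largest
#' peak magnitude is at least 0.1 (absolute), and the CSF fraction is at
#' most 1%. Boundary values are accepted.
#'
#' @param peaks fODF peak magnitudes sorted in descending order (a single
#'   peak is allowed; the second peak then counts as 0)
#' @param csf_fraction CSF volume fraction in [0, 1]
#' @param rel_threshold,abs_threshold,csf_threshold the three selection
#'   thresholds (defaults 0.10, 0.1, 0.01)
#' @return list with `accept` (logical) and `reason` (character, "" when
#'   accepted)
#' @export
select_sfp <- function(peaks, csf_fraction,
                       rel_threshold = 0.10, abs_threshold = 0.1,
                       csf_threshold = 0.01) {
  if (length(peaks) == 0) return(list(accept = FALSE, reason = "no peaks"))
  if (is.unsorted(rev(peaks))) stop("peaks must be sorted descending")
  p1 <- peaks[1]
  p2 <- if (length(peaks) >= 2) peaks[2] else 0
  if (p1 < abs_threshold)
    return(list(accept = FALSE, reason = "largest peak below absolute threshold"))
  if (p2 > rel_threshold * p1)
    return(list(accept = FALSE, reason = "second peak above relative threshold"))
  if (csf_fraction > csf_threshold)
    return(list(accept = FALSE, reason = "CSF fraction above threshold"))
  list(accept = TRUE, reason = "")
}
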