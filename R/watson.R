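#' Watson orientation distributions
#'
#' Fibre orientation dispersion is modelled by the (bipolar) Watson
#' distribution on the sphere, `W(u) ~ exp(kappa (mu.u)^2)`, antipodally
#' symmetric with mean axis `mu` and concentration `kappa >= 0`. The
#' orientation dispersion index follows the standard convention
#' `OD = (2/pi) atan(1/kappa)`: OD = 0 is a delta (kappa -> Inf), OD = 1
#' is isotropic (kappa = 0).
#'
#' @param mu mean orientation axis (unit 3-vector)
#' @param kappa concentration parameter, >= 0 (Inf allowed: delta)
#' @param od orientation dispersion index in [0, 1] (alternative to kappa)
#' @return object of class `watson_odf` with fields `mu`, `kappa`, `od`
#' @export
watson_odf <- function(mu, kappa = NULL, od = NULL) {
  .check_unit(mu, "mu")
  if (is.null(kappa) == is.null(od))
    stop("give exactly one of kappa or od")
  if (is.null(kappa)) kappa <- od_to_kappa(od)
  if (is.na(kappa) || kappa < 0) stop("kappa must be >= 0")
  structure(list(mu = mu, kappa = kappa, od = kappa_to_od(kappa)),
            class = "watson_odf")
}

#' @rdname watson_odf
#' @export
kappa_to_od <- function(kappa) {
  stopifnot(all(kappa >= 0))
  ifelse(is.infinite(kappa), 0, (2 / pi) * atan2(1, kappa))
}

#' @rdname watson_odf
#' @export
od_to_kappa <- function(od) {
  stopifnot(all(od >= 0), all(od <= 1))
  ifelse(od == 0, Inf, 1 / tan(pi * od / 2))
}

#' Deterministic quadrature over a Watson distribution
#'
#' Builds an antipodally symmetric Fibonacci-lattice direction set and
#' weights each direction by the (unnormalised) Watson density, then
#' renormalises so the weights sum to exactly 1. Deterministic: no RNG.
#'
#' @param watson a [watson_odf]
#' @param n_dir number of quadrature directions (even; default 2048)
#' @return list with `u` (n_dir x 3 unit vectors) and `w` (weights,
#'   summing to 1)
#' @export
watson_quadrature <- function(watson, n_dir = 2048) {
  stopifnot(inherits(watson, "watson_odf"))
  u <- fibonacci_sphere(n_dir, antipodal = TRUE)
  ct2 <- drop(u %*% watson$mu)^2
  ## subtract max exponent for numerical stability at large kappa
  w <- exp(watson$kappa * (ct2 - 1))
  w <- w / sum(w)
  if (abs(sum(w) - 1) > 1e-6) stop("internal error: quadrature weights do not sum to 1")
  list(u = u, w = w)
}

#' Sample orientations from a Watson distribution
#'
#' Rejection sampler for the bipolar Watson density (used as the
#' Monte-Carlo oracle for the deterministic quadrature).
#'
#' @param n number of samples
#' @param watson a [watson_odf]
#' @return n x 3 matrix of unit vectors
#' @export
rwatson <- function(n, watson) {
  stopifnot(inherits(watson, "watson_odf"))
  k <- watson$kappa
  if (is.infinite(k)) return(matrix(rep(watson$mu, each = n), ncol = 3))
  ## sample t = cos(psi) on [-1, 1] with density ~ exp(k t^2)
  t <- numeric(0)
  while (length(t) < n) {
    m <- max(2L * (n - length(t)), 1000L)
    cand <- stats::runif(m, -1, 1)
    keep <- stats::runif(m) < exp(k * (cand^2 - 1))
    t <- c(t, cand[keep])
  }
  t <- t[seq_len(n)]
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - t^2))
  local <- cbind(st * cos(phi), st * sin(phi), t)
  local %*% t(.rotation_to(watson$mu))
}

## rotation matrix taking +z to axis v (rows orthonormal); identity when
## v is already +z, well-defined for v = -z
.rotation_to <- function(v) {
  v <- .normalize(v)
  z <- c(0, 0, 1)
  cross <- c(z[2] * v[3] - z[3] * v[2],
             z[3] * v[1] - z[1] * v[3],
             z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(cross^2)); cth <- sum(z * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))      # v = -z: rotate pi about x
  }
  K <- matrix(c(0, -cross[3], cross[2],
                cross[3], 0, -cross[1],
                -cross[2], cross[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Watson-dispersed two-compartment forward signal
#'
#' Generative-side forward model: the voxel signal is the Watson-weighted
#' average of sub-compartment signals, where each sub-orientation `u`
#' contributes a stick/zeppelin signal along `u` whose compartmental
#' relaxation rates follow the supplied R2(theta) laws evaluated at the
#' angle of `u` to B0. This lets every sub-compartment (e.g. every
#' extra-axonal zeppelin) carry its own orientation-dependent R2, which
#' the delta-fODF estimation model deliberately does not capture.
#'
#' At OD = 0 the integral collapses to [compartmental_signal()] with T2
#' taken from the representations at the angle of `mu` itself.
#'
#' @param grid an [acquisition_grid]
#' @param params a [tissue_params] (its `t2_i`, `t2_e` are ignored; the
#'   representations define the relaxation rates)
#' @param watson a [watson_odf]
#' @param r2e_rep,r2i_rep R2(theta) laws (class `r2_rep`) for the
#'   extra-axonal and intra-axonal sub-compartments, 1/s
#' @param b0_axis unit main-field axis (default +z)
#' @param n_dir quadrature directions (default 2048)
#' @return numeric signal vector, one value per grid entry
#' @export
dispersed_signal <- function(grid, params, watson, r2e_rep, r2i_rep,
                             b0_axis = c(0, 0, 1), n_dir = 2048) {
  stopifnot(inherits(grid, "acquisition_grid"), inherits(watson, "watson_odf"),
            inherits(r2e_rep, "r2_rep"), inherits(r2i_rep, "r2_rep"))
  if (!inherits(params, "tissue_params"))
    params <- do.call(tissue_params, as.list(params))
  .check_unit(b0_axis, "b0_axis")
  sub_signal <- function(u) {
    theta_u <- angle_to_b0(u, b0_axis)
    p <- params
    p$t2_i <- r2_to_t2(representation_value(r2i_rep, theta_u))
    p$t2_e <- r2_to_t2(representation_value(r2e_rep, theta_u))
    compartmental_signal(grid, p, u)
  }
  if (watson$od == 0) return(sub_signal(watson$mu))
  quad <- watson_quadrature(watson, n_dir)
  out <- numeric(grid$n)
  for (j in seq_len(n_dir)) {
    if (quad$w[j] < 1e-12) next     # negligible tail of the density
    out <- out + quad$w[j] * sub_signal(quad$u[j, ])
  }
  out
}

#' Orientational coherence p2
#'
#' The degree-2 Legendre moment of the orientation distribution about its
#' principal axis: 1 for perfectly aligned fibres (delta), 0 for an
#' isotropic distribution. From a Watson concentration it is
#' `p2 = (3 <t^2> - 1) / 2` with `<t^2>` the mean squared cosine under the
#' Watson density. From even spherical-harmonic fODF coefficients it is
#' the degree-2 rotational invariant ratio, normalised so a delta gives 1.
#'
#' @param kappa Watson concentration (scalar, >= 0; Inf allowed)
#' @param sh named list with `c00` (scalar l = 0 coefficient, > 0) and
#'   `c2` (numeric vector of the five l = 2 coefficients); alternative to
#'   `kappa`
#' @return p2 in [0, 1]
#' @export
compute_p2 <- function(kappa = NULL, sh = NULL) {
  if (is.null(kappa) == is.null(sh)) stop("give exactly one of kappa or sh")
  if (!is.null(kappa)) {
    stopifnot(length(kappa) == 1, kappa >= 0)
    if (is.infinite(kappa)) return(1)
    if (kappa == 0) return(0)
    num <- stats::integrate(function(t) t^2 * exp(kappa * (t^2 - 1)), 0, 1,
                            rel.tol = 1e-10)$value
    den <- stats::integrate(function(t) exp(kappa * (t^2 - 1)), 0, 1,
                            rel.tol = 1e-10)$value
    return((3 * num / den - 1) / 2)
  }
  if (!is.list(sh) || is.null(sh$c00) || is.null(sh$c2))
    stop("sh must be a list with elements c00 and c2")
  if (!is.finite(sh$c00) || sh$c00 <= 0 || length(sh$c2) != 5)
    stop("invalid spherical-harmonic coefficients")
  ## delta fODF: sum_m Y2m(n)^2 = 5/(4 pi), Y00 = 1/sqrt(4 pi), so the
  ## invariant ratio sqrt(sum c2m^2) / (sqrt(5) c00) equals 1 for a delta
  min(1, sqrt(sum(sh$c2^2)) / (sqrt(5) * sh$c00))
}
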