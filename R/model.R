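#' Tissue parameters of the two-compartment diffusion-T2 model
#'
#' The forward model describes the white-matter signal as intra-axonal
#' water (a "stick": axially symmetric tensor with zero perpendicular
#' diffusivity) plus extra-axonal water (a "zeppelin": axially symmetric
#' tensor with parallel and perpendicular diffusivities), each compartment
#' with its own apparent T2.
#'
#' @param f intra-axonal signal fraction, in [0, 1]
#' @param d_par_i intra-axonal parallel diffusivity, um^2/ms
#' @param d_par_e extra-axonal parallel diffusivity, um^2/ms
#' @param d_perp_e extra-axonal perpendicular diffusivity, um^2/ms
#' @param t2_i,t2_e compartmental transverse relaxation times, ms
#' @param s0 signal at b = 0, TE = 0 (arbitrary units, > 0)
#' @return object of class `tissue_params` (named list). A warning (not an
#'   error) is raised when `d_perp_e > d_par_e`, which is physically
#'   implausible but not forbidden by the fit bounds.
#' @export
tissue_params <- function(f, d_par_i, d_par_e, d_perp_e, t2_i, t2_e, s0 = 1) {
  vals <- c(f = f, d_par_i = d_par_i, d_par_e = d_par_e, d_perp_e = d_perp_e,
            t2_i = t2_i, t2_e = t2_e, s0 = s0)
  if (any(!is.finite(vals))) stop("tissue parameters must be finite")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (d_par_i < 0 || d_par_e < 0 || d_perp_e < 0) stop("diffusivities must be >= 0")
  if (t2_i <= 0 || t2_e <= 0) stop("T2 values must be > 0")
  if (s0 <= 0) stop("s0 must be > 0")
  if (d_perp_e > d_par_e)
    warning("d_perp_e > d_par_e: physically implausible zeppelin")
  structure(as.list(vals), class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params> f=", x$f,
      " D||,i=", x$d_par_i, " D||,e=", x$d_par_e, " D_|_,e=", x$d_perp_e,
      " (um^2/ms)  T2,i=", x$t2_i, " T2,e=", x$t2_e, " (ms)  S0=", x$s0,
      "\n", sep = "")
  invisible(x)
}

## b*(g.n)^2 per entry, or n'Bn when per-entry B-matrices are present.
## This is the only quantity through which the encoding enters the
## axially-symmetric attenuations.
.bgn2 <- function(grid, n) {
  if (!is.null(grid$bmatrix)) {
    vapply(grid$bmatrix, function(B) drop(crossprod(n, B %*% n)), numeric(1))
  } else {
    grid$b * drop(grid$g %*% n)^2
  }
}

#' Stick compartment attenuation
#'
#' Signal attenuation of the intra-axonal "stick" tensor: diffusion only
#' along the fibre axis, `exp(-b * D * (g.n)^2)`. With a B-matrix the
#' projection generalises to `exp(-(n' B n) * D)`.
#'
#' @param b diffusion weighting(s), ms/um^2, >= 0
#' @param g unit gradient direction (3-vector) or n x 3 matrix
#' @param n unit fibre orientation (3-vector)
#' @param d_par_i intra-axonal parallel diffusivity, um^2/ms
#' @param bmatrix optional symmetric 3x3 encoding tensor (overrides b, g)
#' @return attenuation in (0, 1]
#' @export
stick_attenuation <- function(b, g, n, d_par_i, bmatrix = NULL) {
  .check_unit(n, "n")
  if (d_par_i < 0) stop("d_par_i must be >= 0")
  if (!is.null(bmatrix)) {
    return(exp(-drop(crossprod(n, bmatrix %*% n)) * d_par_i))
  }
  if (any(b < 0)) stop("b must be >= 0")
  if (is.matrix(g)) {
    dots2 <- drop(g %*% n)^2
  } else {
    if (any(b > 0)) .check_unit(g, "g")
    dots2 <- sum(g * n)^2
  }
  exp(-b * d_par_i * dots2)
}

#' Zeppelin compartment attenuation
#'
#' Signal attenuation of the extra-axonal axially symmetric "zeppelin"
#' tensor: `exp(-b * [D_perp + (D_par - D_perp) (g.n)^2])`. The B-matrix
#' overload evaluates `exp(-tr(B D))` with
#' `D = D_perp I + (D_par - D_perp) n n'`.
#'
#' @inheritParams stick_attenuation
#' @param d_par_e,d_perp_e extra-axonal parallel/perpendicular
#'   diffusivities, um^2/ms
#' @return attenuation in (0, 1]
#' @export
zeppelin_attenuation <- function(b, g, n, d_par_e, d_perp_e, bmatrix = NULL) {
  .check_unit(n, "n")
  if (d_par_e < 0 || d_perp_e < 0) stop("diffusivities must be >= 0")
  if (!is.null(bmatrix)) {
    trB <- sum(diag(bmatrix))
    nBn <- drop(crossprod(n, bmatrix %*% n))
    return(exp(-(d_perp_e * trB + (d_par_e - d_perp_e) * nBn)))
  }
  if (any(b < 0)) stop("b must be >= 0")
  if (is.matrix(g)) {
    dots2 <- drop(g %*% n)^2
  } else {
    if (any(b > 0)) .check_unit(g, "g")
    dots2 <- sum(g * n)^2
  }
  exp(-b * (d_perp_e + (d_par_e - d_perp_e) * dots2))
}

#' Two-compartment diffusion-T2 forward signal
#'
#' Evaluates, for every grid entry,
#' `S0 * [ f exp(-TE/T2_i) A_stick + (1-f) exp(-TE/T2_e) A_zeppelin ]`
#' for a single fibre orientation `n` (delta fODF). This is the
#' estimation-side model; the generative side with orientation dispersion
#' is [dispersed_signal()].
#'
#' @param grid an [acquisition_grid]
#' @param params a [tissue_params]
#' @param n unit fibre orientation
#' @return numeric vector of signals, one per grid entry
#' @export
compartmental_signal <- function(grid, params, n) {
  stopifnot(inherits(grid, "acquisition_grid"))
  if (!inherits(params, "tissue_params"))
    params <- do.call(tissue_params, as.list(params))
  .check_unit(n, "n")
  q <- .bgn2(grid, n)                     # b (g.n)^2  (or n'Bn)
  stick <- exp(-q * params$d_par_i)
  zepp <- exp(-(grid$b - q) * params$d_perp_e - q * params$d_par_e)
  params$s0 * (params$f * exp(-grid$te / params$t2_i) * stick +
               (1 - params$f) * exp(-grid$te / params$t2_e) * zepp)
}

#' Angle of a fibre orientation to the main field B0
#'
#' Orientations are axes (antipodally symmetric), so the angle is folded
#' into [0, 90] degrees: `theta = acos(|n . b0|)`.
#'
#' @param n fibre orientation(s): 3-vector or n x 3 matrix (unit rows)
#' @param b0_axis unit vector of the main field axis (default scanner +z)
#' @return angle(s) in degrees, in [0, 90]
#' @export
angle_to_b0 <- function(n, b0_axis = c(0, 0, 1)) {
  .check_unit(b0_axis, "b0_axis")
  if (is.matrix(n)) {
    norms <- sqrt(rowSums(n^2))
    if (any(norms == 0)) stop("zero orientation vector")
    ct <- abs(drop(n %*% b0_axis)) / norms
  } else {
    .check_unit(n, "n")
    ct <- abs(sum(n * b0_axis))
  }
  rad2deg(acos(pmin(1, ct)))
}
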