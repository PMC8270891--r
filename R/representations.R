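#' R2(theta) representations
#'
#' The orientation dependence of the transverse relaxation rate is
#' summarised by `R2(theta) = R2_iso + f(theta)`, where theta is the fibre
#' angle to B0 and `f` is one of the canonical anisotropic forms:
#'
#' \describe{
#'   \item{iso}{`f = 0`}
#'   \item{sin2}{`f = R2_aniso * sin^2(theta)` (static dephasing /
#'     susceptibility-gradient interaction)}
#'   \item{sin4}{`f = R2_aniso * sin^4(theta)` (hollow-cylinder
#'     susceptibility prediction for spin echoes)}
#'   \item{magic}{`f = R2_aniso * [1 - (3 cos^2(theta) - 1)^2 / 4]`
#'     (dipole-dipole "magic angle" form, extremal at ~54.7 deg)}
#'   \item{full}{`f = R2_aniso1 * sin^2(theta) + R2_aniso2 * sin^4(theta)`}
#' }
#'
#' @param kind one of "iso", "sin2", "sin4", "magic", "full"
#' @param r2_iso isotropic rate, 1/s
#' @param r2_aniso anisotropy coefficient (sin2/sin4/magic kinds), 1/s
#' @param r2_aniso1,r2_aniso2 sin^2 and sin^4 coefficients (full kind), 1/s
#' @return object of class `r2_rep`
#' @export
r2_representation <- function(kind, r2_iso, r2_aniso = NULL,
                              r2_aniso1 = NULL, r2_aniso2 = NULL) {
  kind <- match.arg(kind, c("iso", "sin2", "sin4", "magic", "full"))
  stopifnot(is.numeric(r2_iso), is.finite(r2_iso))
  coefs <- switch(kind,
    iso = c(r2_iso = r2_iso),
    sin2 = ,
    sin4 = ,
    magic = {
      if (is.null(r2_aniso)) stop(kind, " kind needs r2_aniso")
      c(r2_iso = r2_iso, r2_aniso = r2_aniso)
    },
    full = {
      if (is.null(r2_aniso1) || is.null(r2_aniso2))
        stop("full kind needs r2_aniso1 and r2_aniso2")
      c(r2_iso = r2_iso, r2_aniso1 = r2_aniso1, r2_aniso2 = r2_aniso2)
    })
  if (any(!is.finite(coefs))) stop("coefficients must be finite")
  structure(list(kind = kind, coefs = coefs), class = "r2_rep")
}

#' @export
print.r2_rep <- function(x, ...) {
  cat("<r2_rep ", x$kind, "> ", .rep_formula(x), "\n", sep = "")
  invisible(x)
}

.rep_formula <- function(rep) {
  cf <- function(v) formatC(v, format = "g")
  k <- rep$coefs
  switch(rep$kind,
    iso = paste0("R2(theta) = ", cf(k[1])),
    sin2 = paste0("R2(theta) = ", cf(k[1]), " + ", cf(k[2]), " sin^2(theta)"),
    sin4 = paste0("R2(theta) = ", cf(k[1]), " + ", cf(k[2]), " sin^4(theta)"),
    magic = paste0("R2(theta) = ", cf(k[1]), " + ", cf(k[2]),
                   " [1 - (3cos^2 - 1)^2/4]"),
    full = paste0("R2(theta) = ", cf(k[1]), " + ", cf(k[2]),
                  " sin^2(theta) + ", cf(k[3]), " sin^4(theta)"))
}

## basis functions of each representation kind, evaluated at theta (deg);
## returns a matrix with one column per coefficient (first column = 1)
rep_basis <- function(kind, theta_deg) {
  th <- deg2rad(theta_deg)
  s2 <- sin(th)^2
  one <- rep(1, length(th))
  switch(kind,
    iso = cbind(iso = one),
    sin2 = cbind(iso = one, aniso = s2),
    sin4 = cbind(iso = one, aniso = s2^2),
    magic = cbind(iso = one, aniso = 1 - 0.25 * (3 * (1 - s2) - 1)^2),
    full = cbind(iso = one, aniso1 = s2, aniso2 = s2^2),
    stop("unknown representation kind: ", kind))
}

#' Evaluate an R2(theta) representation
#'
#' @param rep an `r2_rep` (see [r2_representation()])
#' @param theta_deg angle(s) to B0 in degrees, in [0, 90]
#' @return R2 value(s), 1/s
#' @export
representation_value <- function(rep, theta_deg) {
  stopifnot(inherits(rep, "r2_rep"))
  if (any(theta_deg < -1e-9 | theta_deg > 90 + 1e-9))
    stop("theta must lie in [0, 90] degrees")
  drop(rep_basis(rep$kind, theta_deg) %*% rep$coefs)
}

#' Anisotropy magnitude of a representation
#'
#' The difference between the absolute maximum and minimum of R2(theta)
#' over theta in [0, 90] degrees, the scalar summary used to compare
#' anisotropy across studies.
#'
#' @param rep an `r2_rep`
#' @param step grid resolution in degrees (default 0.01)
#' @return list with `magnitude` (1/s), `theta_max` and `theta_min` (deg)
#' @export
anisotropy_magnitude <- function(rep, step = 0.01) {
  th <- seq(0, 90, by = step)
  v <- representation_value(rep, th)
  list(magnitude = max(v) - min(v),
       theta_max = th[which.max(v)], theta_min = th[which.min(v)])
}

#' Convert trigonometric forms to sin-power coefficients
#'
#' The relaxation-anisotropy literature writes orientation dependence in
#' several equivalent trigonometric forms. This converts the four common
#' left-hand forms to the sin-power parameterisation
#' `A + B sin^2(theta) [+ C sin^4(theta)]`:
#'
#' \describe{
#'   \item{cos2}{`a + b cos(2 theta)` -> `A = a + b, B = -2b`}
#'   \item{cos2cos4}{`a + b cos(2 theta) - b/4 cos(4 theta)` ->
#'     `A = a + 3b/4, B = 0, C = -2b` (a pure sin^4 law)}
#'   \item{dipolar_sq}{`a + b (3 cos^2(theta) - 1)^2` ->
#'     `A = a + 4b, B = -12b, C = 9b`}
#'   \item{cos2_cos4}{`a + b cos(2 theta) + c cos(4 theta)` ->
#'     `A = a + b + c, B = -2b - 8c, C = 8c`}
#' }
#'
#' @param form one of "cos2", "cos2cos4", "dipolar_sq", "cos2_cos4"
#' @param a,b,c coefficients of the source form (`c` only for "cos2_cos4")
#' @return named numeric vector with elements `A`, `B` and (when the form
#'   carries a sin^4 term) `C`
#' @export
convert_trig_form <- function(form, a, b, c = NULL) {
  form <- match.arg(form, c("cos2", "cos2cos4", "dipolar_sq", "cos2_cos4"))
  stopifnot(is.finite(a), is.finite(b))
  switch(form,
    cos2 = c(A = a + b, B = -2 * b),
    cos2cos4 = c(A = a + 0.75 * b, B = 0, C = -2 * b),
    dipolar_sq = c(A = a + 4 * b, B = -12 * b, C = 9 * b),
    cos2_cos4 = {
      if (is.null(c)) stop("cos2_cos4 form needs coefficient c")
      c(A = a + b + c, B = -2 * b - 8 * c, C = 8 * c)
    })
}

## direct evaluation of the source trigonometric forms (test oracle support)
eval_trig_form <- function(form, a, b, c = NULL, theta_deg) {
  th <- deg2rad(theta_deg)
  switch(match.arg(form, c("cos2", "cos2cos4", "dipolar_sq", "cos2_cos4")),
    cos2 = a + b * cos(2 * th),
    cos2cos4 = a + b * cos(2 * th) - 0.25 * b * cos(4 * th),
    dipolar_sq = a + b * (3 * cos(th)^2 - 1)^2,
    cos2_cos4 = a + b * cos(2 * th) + c * cos(4 * th))
}

## evaluate sin-power coefficients A + B sin^2 + C sin^4
eval_sin_power <- function(coefs, theta_deg) {
  s2 <- sin(deg2rad(theta_deg))^2
  out <- coefs[["A"]] + coefs[["B"]] * s2
  if ("C" %in% names(coefs)) out <- out + coefs[["C"]] * s2^2
  out
}
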