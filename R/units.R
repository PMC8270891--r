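#' Unit conventions and conversions
#'
#' Internally the package uses a single convention: b-values in ms/um^2
#' (1 ms/um^2 = 1000 s/mm^2), echo times TE in ms, relaxation rates R2 in
#' 1/s and relaxation times T2 in ms. The relaxation-rate literature mixes
#' s/mm^2, ms and 1/s; all conversions live here and nowhere else.
#'
#' @param t2 transverse relaxation time(s), ms. Must be > 0.
#' @param r2 transverse relaxation rate(s), 1/s. Must be > 0.
#' @return `t2_to_r2` returns R2 in 1/s; `r2_to_t2` returns T2 in ms.
#' @examples
#' t2_to_r2(70)        # ~14.3 s^-1
#' r2_to_t2(t2_to_r2(83.3))
#' @export
t2_to_r2 <- function(t2) {
  stopifnot(is.numeric(t2), all(is.finite(t2)), all(t2 > 0))
  1000 / t2
}

#' @rdname t2_to_r2
#' @export
r2_to_t2 <- function(r2) {
  stopifnot(is.numeric(r2), all(is.finite(r2)), all(r2 > 0))
  1000 / r2
}

#' Convert b-value between s/mm^2 and ms/um^2
#'
#' @param b_si b-value(s) in s/mm^2
#' @return b in ms/um^2
#' @export
b_si_to_ms_um2 <- function(b_si) b_si / 1000

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

## unit-vector check with tolerance; used by all orientation inputs
.check_unit <- function(v, name = "vector", tol = 1e-6) {
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v)))
    stop(name, " must be a finite numeric 3-vector", call. = FALSE)
  n2 <- sqrt(sum(v^2))
  if (abs(n2 - 1) > tol)
    stop(name, " must be a unit vector (norm = ", format(n2), ")", call. = FALSE)
  invisible(v)
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}
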