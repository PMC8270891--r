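#' Akaike information criterion for least-squares fits
#'
#' `AIC = 2 K + N ln(RSS / N)`, with K the number of fitted parameters, N
#' the number of observations and RSS the residual sum of squares. An
#' RSS of exactly 0 (an exact interpolant) yields -Inf and should be
#' treated as such by the caller.
#'
#' @param k number of fitted parameters
#' @param n number of observations (> 0)
#' @param rss residual sum of squares (>= 0)
#' @return AIC value (possibly -Inf when rss = 0)
#' @export
aic_ls <- function(k, n, rss) {
  stopifnot(n > 0, rss >= 0, k >= 0)
  if (rss == 0) return(-Inf)
  2 * k + n * log(rss / n)
}

#' Rescale a set of AIC values to differences from the minimum
#'
#' @param aics numeric vector of AIC values
#' @return `delta_aic`: the vector minus its minimum.
#'   `aic_support_label`: the conventional evidence label for each
#'   difference ("substantial" for dAIC <= 2, "considerably less" for
#'   4 <= dAIC <= 7, "none" for dAIC >= 10, "intermediate" otherwise).
#' @export
delta_aic <- function(aics) {
  stopifnot(length(aics) >= 1)
  m <- min(aics)
  d <- aics - m
  d[aics == m] <- 0      # -Inf - -Inf (exact interpolants) counts as 0
  d
}

#' @rdname delta_aic
#' @param deltas vector of AIC differences
#' @export
aic_support_label <- function(deltas) {
  vapply(deltas, function(d) {
    if (d <= 2) "substantial"
    else if (d >= 10) "none"
    else if (d >= 4 && d <= 7) "considerably less"
    else "intermediate"
  }, character(1))
}

#' Fit one R2(theta) representation to pooled observations
#'
#' All representation kinds are linear in their coefficients, so the fit
#' is (weighted) linear least squares on the design matrix implied by the
#' kind. Coefficient covariance comes from the residual variance, and
#' confidence intervals use the t distribution with N - K degrees of
#' freedom (85% and 95% levels; the 85% interval drives the
#' anisotropy-discard rule of [select_model()]).
#'
#' @param theta numeric vector of fibre angles to B0, degrees in [0, 90]
#' @param r2 numeric vector of R2 observations, 1/s
#' @param kind representation kind (see [r2_representation()])
#' @param weights optional non-negative observation weights
#' @return object of class `r2_fit`: list with `rep` (an `r2_rep`),
#'   `coefs`, `covariance`, `ci85`, `ci95` (matrices with lower/upper
#'   columns), `k`, `n`, `rss`, `aic`, `kind`
#' @export
fit_representation <- function(theta, r2, kind, weights = NULL) {
  kind <- match.arg(kind, c("iso", "sin2", "sin4", "magic", "full"))
  theta <- as.numeric(theta); r2 <- as.numeric(r2)
  if (length(theta) != length(r2)) stop("theta/r2 length mismatch")
  if (any(theta < -1e-9 | theta > 90 + 1e-9))
    stop("theta must lie in [0, 90] degrees")
  X <- rep_basis(kind, theta)
  n <- nrow(X); k <- ncol(X)
  if (n < k + 1) stop("need at least K + 1 observations")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("invalid weights")
  w <- weights
  Xw <- X * sqrt(w); yw <- r2 * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < k)
    stop("degenerate design: representation '", kind,
         "' is not identifiable from these angles")
  beta <- qr.coef(qr_x, yw)
  res <- r2 - drop(X %*% beta)
  rss <- sum(w * res^2)
  dof <- n - k
  sigma2 <- rss / dof
  xtx_inv <- chol2inv(qr.R(qr_x))
  covariance <- sigma2 * xtx_inv
  se <- sqrt(diag(covariance))
  ci <- function(level) {
    tq <- stats::qt(1 - (1 - level) / 2, dof)
    cbind(lower = beta - tq * se, upper = beta + tq * se)
  }
  rep <- switch(kind,
    iso = r2_representation("iso", beta[1]),
    sin2 = r2_representation("sin2", beta[1], r2_aniso = beta[2]),
    sin4 = r2_representation("sin4", beta[1], r2_aniso = beta[2]),
    magic = r2_representation("magic", beta[1], r2_aniso = beta[2]),
    full = r2_representation("full", beta[1], r2_aniso1 = beta[2],
                             r2_aniso2 = beta[3]))
  structure(list(rep = rep, kind = kind, coefs = beta,
                 covariance = covariance, se = se,
                 ci85 = ci(0.85), ci95 = ci(0.95),
                 k = k, n = n, rss = rss, aic = aic_ls(k, n, rss)),
            class = "r2_fit")
}

#' @export
print.r2_fit <- function(x, ...) {
  cat("<r2_fit ", x$kind, "> ", .rep_formula(x$rep),
      "  (N=", x$n, ", K=", x$k, ", AIC=", formatC(x$aic, format = "g"),
      ")\n", sep = "")
  invisible(x)
}

## indices of the anisotropy coefficients of a fitted representation
.aniso_idx <- function(kind) {
  switch(kind, iso = integer(0), sin2 = 2L, sin4 = 2L, magic = 2L,
         full = c(2L, 3L))
}

#' Parsimonious representation selection by AIC with a CI discard rule
#'
#' Implements the two-stage selection used for the pooled R2(theta) fits:
#' \enumerate{
#'   \item anisotropic fits are discarded when the 85% confidence
#'     interval of an anisotropy coefficient includes zero (by default
#'     "any coefficient" for the full kind; set
#'     `discard_rule = "all"` to require every coefficient's CI to
#'     include zero before discarding);
#'   \item delta-AIC values are computed over the survivors, and among
#'     those within `delta AIC <= 2` of the best, the fit with the
#'     fewest parameters wins (ties: lower AIC, then the canonical kind
#'     order iso, sin2, sin4, magic, full).
#' }
#'
#' @param fits list of `r2_fit` objects (must include the iso kind)
#' @param discard_rule "any" (default) or "all": how the 85%-CI rule
#'   treats multi-coefficient anisotropic fits
#' @return list with `selected` (an `r2_fit`) and `audit` (data.frame
#'   with one row per candidate: kind, k, aic, delta_aic, discarded,
#'   reason)
#' @export
select_model <- function(fits, discard_rule = c("any", "all")) {
  discard_rule <- match.arg(discard_rule)
  if (length(fits) == 0) stop("empty candidate list")
  kinds <- vapply(fits, function(f) f$kind, character(1))
  if (!"iso" %in% kinds) stop("candidate set must include the iso kind")
  kind_order <- c("iso", "sin2", "sin4", "magic", "full")
  discarded <- logical(length(fits))
  reason <- character(length(fits))
  for (i in seq_along(fits)) {
    idx <- .aniso_idx(fits[[i]]$kind)
    if (length(idx) == 0) next
    inc0 <- fits[[i]]$ci85[idx, "lower"] <= 0 & fits[[i]]$ci85[idx, "upper"] >= 0
    drop_it <- if (discard_rule == "any") any(inc0) else all(inc0)
    if (drop_it) {
      discarded[i] <- TRUE
      reason[i] <- "85% CI of anisotropy coefficient includes 0"
    }
  }
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  surv <- which(!discarded)
  d <- rep(NA_real_, length(fits))
  d[surv] <- delta_aic(aics[surv])
  cand <- surv[d[surv] <= 2]
  ks <- vapply(fits[cand], function(f) f$k, numeric(1))
  cand <- cand[ks == min(ks)]
  if (length(cand) > 1) cand <- cand[order(aics[cand],
                                           match(kinds[cand], kind_order))][1]
  audit <- data.frame(kind = kinds,
                      k = vapply(fits, function(f) f$k, numeric(1)),
                      aic = aics, delta_aic = d,
                      discarded = discarded, reason = reason)
  list(selected = fits[[cand]], audit = audit)
}

#' Fit every applicable representation and select the best
#'
#' Convenience wrapper: fits the requested kinds with
#' [fit_representation()] (kinds whose design is degenerate for the given
#' angles are skipped with a note) and runs [select_model()].
#'
#' @inheritParams fit_representation
#' @param kinds representation kinds to consider (default all five)
#' @param discard_rule forwarded to [select_model()]
#' @return list with `fits` (named list), `selected`, `audit`
#' @export
fit_all_representations <- function(theta, r2, kinds = c("iso", "sin2", "sin4",
                                                         "magic", "full"),
                                    weights = NULL,
                                    discard_rule = c("any", "all")) {
  fits <- list()
  for (kk in kinds) {
    f <- tryCatch(fit_representation(theta, r2, kk, weights),
                  error = function(e) e)
    if (inherits(f, "error")) {
      if (!grepl("degenerate design", conditionMessage(f))) stop(f)
      next
    }
    fits[[kk]] <- f
  }
  sel <- select_model(fits, discard_rule)
  list(fits = fits, selected = sel$selected, audit = sel$audit)
}
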