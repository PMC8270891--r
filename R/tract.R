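## arc-length resampling of a polyline to m equidistant points
.resample_polyline <- function(pts, m) {
  pts <- as.matrix(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  if (sum(seg) == 0) stop("zero-length streamline")
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = m)
  out <- matrix(NA_real_, m, 3)
  for (j in 1:3) out[, j] <- stats::approx(s, pts[, j], xout = target)$y
  out
}

#' Core streamline and equal-arc-length segments of a bundle
#'
#' The representative core is the pointwise centroid of all streamlines
#' after arc-length resampling to a common number of points (streamlines
#' whose ordering is flipped relative to the first are reversed first).
#' The core is then subdivided into `n_segments` equal-arc-length
#' segments, each with a unit tangent vector.
#'
#' @param streamlines list of k x 3 point matrices (ordered points)
#' @param n_segments number of segments (default 20)
#' @param n_resample resampling resolution (default 100 points)
#' @return list with `core` (n_resample x 3), `arc` (arc-length position
#'   of each core point), `boundaries` (arc lengths delimiting segments),
#'   `tangents` (n_segments x 3 unit vectors), `segment_of_arc` (function
#'   mapping arc length to segment index)
#' @export
core_and_segments <- function(streamlines, n_segments = 20, n_resample = 100) {
  if (length(streamlines) < 1) stop("need at least one streamline")
  rs <- lapply(streamlines, .resample_polyline, m = n_resample)
  ref <- rs[[1]]
  rs <- lapply(rs, function(p) {
    if (sum((p[1, ] - ref[1, ])^2) > sum((p[n_resample, ] - ref[1, ])^2))
      p[n_resample:1, , drop = FALSE] else p
  })
  core <- Reduce(`+`, rs) / length(rs)
  seg_len <- sqrt(rowSums(diff(core)^2))
  arc <- c(0, cumsum(seg_len))
  total <- arc[length(arc)]
  boundaries <- seq(0, total, length.out = n_segments + 1)
  tangents <- matrix(NA_real_, n_segments, 3)
  for (s in seq_len(n_segments)) {
    mid <- (boundaries[s] + boundaries[s + 1]) / 2
    ## tangent from the core points bracketing the segment midpoint
    i <- max(1, findInterval(mid, arc))
    i <- min(i, n_resample - 1)
    tangents[s, ] <- .normalize(core[i + 1, ] - core[i, ])
  }
  segment_of_arc <- function(a) pmin(n_segments,
                                     pmax(1, findInterval(a, boundaries,
                                                          rightmost.closed = TRUE)))
  list(core = core, arc = arc, boundaries = boundaries, tangents = tangents,
       n_segments = n_segments, segment_of_arc = segment_of_arc)
}

#' Assign SFP voxels to tract segments
#'
#' A voxel joins a segment iff its centre projects into that segment's
#' arc-length bin of the core's tubular neighbourhood (within
#' `max_radius` of the core) and its orientation is within
#' `angular_threshold` of the segment tangent (antipodally folded).
#'
#' @param voxels data.frame with columns `x`, `y`, `z` (positions) and
#'   `nx`, `ny`, `nz` (unit orientations)
#' @param segments output of [core_and_segments()]
#' @param angular_threshold degrees (default 15)
#' @param max_radius tubular neighbourhood radius (default Inf: all
#'   voxels considered)
#' @return integer vector of segment indices (NA where excluded)
#' @export
assign_voxels <- function(voxels, segments, angular_threshold = 15,
                          max_radius = Inf) {
  core <- segments$core
  out <- rep(NA_integer_, nrow(voxels))
  for (i in seq_len(nrow(voxels))) {
    p <- c(voxels$x[i], voxels$y[i], voxels$z[i])
    d2 <- colSums((t(core) - p)^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > max_radius) next
    seg <- segments$segment_of_arc(segments$arc[j])
    nv <- .normalize(c(voxels$nx[i], voxels$ny[i], voxels$nz[i]))
    ang <- rad2deg(acos(pmin(1, abs(sum(nv * segments$tangents[seg, ])))))
    if (ang <= angular_threshold) out[i] <- seg
  }
  out
}

#' Per-segment statistics of assigned SFP voxels
#'
#' For each segment: voxel count, mean of every requested R2 estimate,
#' and the principal orientation (first eigenvector of the orientation
#' scatter matrix sum of n n', antipodally normalised to a positive
#' z component) with its angle to B0.
#'
#' @param voxels data.frame with orientation columns `nx`, `ny`, `nz` and
#'   the estimate columns named in `value_cols`
#' @param assignment integer segment index per voxel (NA = excluded), as
#'   returned by [assign_voxels()]
#' @param value_cols character vector of estimate column names to average
#' @param b0_axis main-field axis (default +z)
#' @param n_segments total number of segments (default max assignment)
#' @return data.frame with one row per non-empty segment: `segment`,
#'   `n_voxels`, `theta` and one `mean_<col>` column per estimate
#' @export
segment_stats <- function(voxels, assignment, value_cols,
                          b0_axis = c(0, 0, 1),
                          n_segments = max(assignment, na.rm = TRUE)) {
  stopifnot(nrow(voxels) == length(assignment))
  out <- list()
  for (s in seq_len(n_segments)) {
    idx <- which(assignment == s)
    if (length(idx) == 0) next
    N <- as.matrix(voxels[idx, c("nx", "ny", "nz"), drop = FALSE])
    scatter <- crossprod(N)                       # sum of n n'
    ev <- eigen(scatter, symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (v[3] < 0) v <- -v                         # antipodal convention
    row <- data.frame(segment = s, n_voxels = length(idx),
                      theta = angle_to_b0(v, b0_axis),
                      px = v[1], py = v[2], pz = v[3])
    for (cc in value_cols) row[[paste0("mean_", cc)]] <- mean(voxels[[cc]][idx])
    out[[length(out) + 1]] <- row
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Segment-wise tilt-difference regression
#'
#' Tests the effect of head re-orientation: for paired tract segments
#' measured in the default and tilted coil orientations, the per-segment
#' difference `y = R2(default) - R2(tilted)` is regressed through the
#' origin on `x = sin^p(theta_default) - sin^p(theta_tilted)` (p = 2 or
#' 4), weighted by the mean voxel count of the pair. Assuming R2_iso is
#' tilt-invariant, the slope estimates the anisotropy coefficient
#' R2_aniso. Endpoint segments (a fraction `endpoint_frac` on each side,
#' default 20% so segments 5-16 of 20 survive) and pairs with fewer than
#' `min_voxels` voxels in either orientation are excluded. AIC values are
#' reported for the sin^2 and sin^4 forms and for the isotropic
#' alternative (x = 0: zero slope, K = 0, residuals = y).
#'
#' @param seg_default,seg_tilted data.frames from [segment_stats()] with
#'   a shared `segment` column, `theta`, `n_voxels` and the column named
#'   by `value_col` (an optional `tract` column extends the pairing key)
#' @param value_col name of the mean-R2 column to difference
#' @param form "sin4" (default, as in the published analysis) or "sin2"
#' @param n_segments total segments per tract (default 20)
#' @param endpoint_frac endpoint exclusion fraction per side (default 0.2)
#' @param min_voxels minimum voxels per segment per orientation (default 3)
#' @return list with `slope` (1/s), `se`, `ci95`, `n` (segment pairs),
#'   `rss`, `aic_table` (data.frame for sin2, sin4, iso), `data` (the
#'   regression frame)
#' @export
tilt_regression <- function(seg_default, seg_tilted, value_col,
                            form = c("sin4", "sin2"), n_segments = 20,
                            endpoint_frac = 0.2, min_voxels = 3) {
  form <- match.arg(form)
  key <- intersect(c("tract", "segment"), names(seg_default))
  merged <- merge(seg_default, seg_tilted, by = key,
                  suffixes = c("_0", "_t"))
  lo <- floor(n_segments * endpoint_frac) + 1
  hi <- n_segments - floor(n_segments * endpoint_frac)
  keep <- merged$segment >= lo & merged$segment <= hi &
    merged$n_voxels_0 >= min_voxels & merged$n_voxels_t >= min_voxels
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) < 2) stop("fewer than 2 segment pairs survive the exclusions")
  v0 <- merged[[paste0("mean_", value_col, "_0")]]
  vt <- merged[[paste0("mean_", value_col, "_t")]]
  y <- v0 - vt
  s0 <- sin(deg2rad(merged$theta_0)); st <- sin(deg2rad(merged$theta_t))
  x2 <- s0^2 - st^2
  x4 <- s0^4 - st^4
  w <- (merged$n_voxels_0 + merged$n_voxels_t) / 2
  fit_origin <- function(x) {
    sxx <- sum(w * x^2)
    if (sxx == 0) stop("degenerate regressor: no angular contrast between tilts")
    slope <- sum(w * x * y) / sxx
    rss <- sum(w * (y - slope * x)^2)
    se <- sqrt(rss / (length(y) - 1) / sxx)
    list(slope = slope, rss = rss, se = se)
  }
  f2 <- fit_origin(x2); f4 <- fit_origin(x4)
  n <- length(y)
  rss_iso <- sum(w * y^2)
  aic_table <- data.frame(
    form = c("sin2", "sin4", "iso"),
    k = c(1, 1, 0),
    slope = c(f2$slope, f4$slope, 0),
    rss = c(f2$rss, f4$rss, rss_iso),
    aic = c(aic_ls(1, n, f2$rss), aic_ls(1, n, f4$rss),
            aic_ls(0, n, rss_iso)))
  aic_table$delta_aic <- delta_aic(aic_table$aic)
  chosen <- if (form == "sin2") f2 else f4
  tq <- stats::qt(0.975, n - 1)
  list(slope = chosen$slope, se = chosen$se,
       ci95 = c(lower = chosen$slope - tq * chosen$se,
                upper = chosen$slope + tq * chosen$se),
       n = n, rss = chosen$rss, form = form, aic_table = aic_table,
       data = data.frame(merged[key], y = y, x2 = x2, x4 = x4, w = w))
}

#' Intraclass correlation coefficient for test-retest segment estimates
#'
#' Pooled-moment ICC across paired measurements:
#' `xbar = sum(x1 + x2) / 2N`,
#' `s^2 = sum((x1 - xbar)^2 + (x2 - xbar)^2) / 2N`,
#' `ICC = sum((x1 - xbar)(x2 - xbar)) / (N s^2)`.
#' Identical vectors give 1; vectors mirrored about the pooled mean give
#' -1; independent data give ~0. Interpretation labels follow the usual
#' convention: excellent > 0.9, good 0.75-0.9, moderate 0.5-0.75, poor
#' otherwise.
#'
#' @param x_test,x_retest equal-length paired numeric vectors (N >= 2)
#' @return list with `icc`, `n`, `label`, `undefined` (TRUE when the
#'   pooled variance is zero)
#' @export
icc <- function(x_test, x_retest) {
  x1 <- as.numeric(x_test); x2 <- as.numeric(x_retest)
  if (length(x1) != length(x2)) stop("paired vectors must have equal length")
  n <- length(x1)
  if (n < 2) stop("need N >= 2 pairs")
  xbar <- sum(x1 + x2) / (2 * n)
  s2 <- sum((x1 - xbar)^2 + (x2 - xbar)^2) / (2 * n)
  if (s2 == 0)
    return(list(icc = NA_real_, n = n, label = "undefined", undefined = TRUE))
  val <- sum((x1 - xbar) * (x2 - xbar)) / (n * s2)
  label <- if (val > 0.9) "excellent" else if (val > 0.75) "good"
           else if (val > 0.5) "moderate" else "poor"
  list(icc = val, n = n, label = label, undefined = FALSE)
}
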