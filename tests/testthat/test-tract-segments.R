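test_that("core streamline and tangents follow the bundle geometry", {
  # single straight streamline: core identical, all tangents equal
  line <- cbind(0, 0, seq(0, 10, length.out = 25))
  cs <- core_and_segments(list(line), n_segments = 5)
  expect_equal(cs$core[, 1], rep(0, 100))
  expect_equal(cs$core[, 3], seq(0, 10, length.out = 100), tolerance = 1e-9)
  expect_equal(cs$tangents, matrix(rep(c(0, 0, 1), each = 5), 5),
               tolerance = 1e-9)
  # two parallel offset streamlines: core is the midline
  l1 <- cbind(1, 0, seq(0, 10, length.out = 30))
  l2 <- cbind(-1, 0, seq(0, 10, length.out = 30))
  cs2 <- core_and_segments(list(l1, l2), n_segments = 4)
  expect_equal(max(abs(cs2$core[, 1])), 0, tolerance = 1e-9)
  # synthetic arc bundle: per-segment tangents within 2 degrees of the
  # analytic arc tangent at the segment midpoint
  ph <- build_tract_phantom(phantom_spec(noise_model = "none"))
  cs3 <- core_and_segments(ph$streamlines, n_segments = 20)
  mid_angles <- (seq_len(20) - 0.5) / 20 * 90     # arc sweeps 0..90 deg
  for (s in seq_len(20)) {
    analytic <- c(0, sin(mid_angles[s] * pi / 180),
                  cos(mid_angles[s] * pi / 180))
    ang <- acos(min(1, abs(sum(cs3$tangents[s, ] * analytic)))) * 180 / pi
    expect_lt(ang, 2)
  }
  expect_error(core_and_segments(list(cbind(1, 1, 1)[c(1, 1), ])),
               "zero-length")
})

test_that("voxels are assigned by segment bin and angular threshold", {
  line <- cbind(0, 0, seq(0, 10, length.out = 50))
  cs <- core_and_segments(list(line), n_segments = 5)
  vox <- data.frame(x = c(0.1, 0.1, 0.1), y = 0,
                    z = c(1, 3, 9),
                    nx = c(0, sin(20 * pi / 180), 0), ny = 0,
                    nz = c(1, cos(20 * pi / 180), -1))
  a <- assign_voxels(vox, cs, angular_threshold = 15)
  expect_equal(a[1], 1L)          # aligned, in segment 1 (z in [0,2))
  expect_true(is.na(a[2]))        # 20 degrees off the tangent
  expect_equal(a[3], 5L)          # antipodal orientation still aligned
  # tract phantom: assignment recovers arc-position labels >= 95%
  ph <- build_tract_phantom(phantom_spec(noise_model = "none"),
                            n_voxels = 200)
  cs2 <- core_and_segments(ph$streamlines, n_segments = 20, n_resample = 1000)
  vdf <- data.frame(x = ph$voxels$x, y = ph$voxels$y, z = ph$voxels$z,
                    nx = ph$voxels$nx_tilt0, ny = ph$voxels$ny_tilt0,
                    nz = ph$voxels$nz_tilt0)
  a2 <- assign_voxels(vdf, cs2)
  truth <- pmin(20L, pmax(1L, ceiling(seq(0, 1, length.out = 200) * 20)))
  truth[1] <- 1L
  ok <- mean(!is.na(a2) & a2 == truth)
  expect_gte(ok, 0.95)
})

test_that("segment statistics use the scatter-matrix principal axis", {
  v <- c(0.3, 0.5, sqrt(1 - 0.34))
  vox <- data.frame(nx = rep(v[1], 4), ny = rep(v[2], 4), nz = rep(v[3], 4),
                    r2 = c(16, 17, 18, 19))
  st <- segment_stats(vox, rep(1L, 4), "r2", n_segments = 1)
  expect_equal(abs(sum(st[1, c("px", "py", "pz")] * v)), 1, tolerance = 1e-9)
  expect_equal(st$mean_r2, 17.5)
  expect_equal(st$n_voxels, 4)
  # antipodal pairs: principal axis is still +/- v
  vox2 <- data.frame(nx = c(v[1], -v[1]), ny = c(v[2], -v[2]),
                     nz = c(v[3], -v[3]), r2 = c(1, 2))
  st2 <- segment_stats(vox2, c(1L, 1L), "r2", n_segments = 1)
  expect_equal(abs(sum(st2[1, c("px", "py", "pz")] * v)), 1, tolerance = 1e-9)
  # dispersed set: matches a brute-force eigendecomposition oracle
  set.seed(33)
  N <- matrix(rnorm(60, sd = 0.2), 20, 3)
  N[, 3] <- N[, 3] + 1
  N <- N / sqrt(rowSums(N^2))
  vox3 <- data.frame(nx = N[, 1], ny = N[, 2], nz = N[, 3], r2 = rnorm(20, 15))
  st3 <- segment_stats(vox3, rep(1L, 20), "r2", n_segments = 1)
  ev <- eigen(t(N) %*% N, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(st3[1, c("px", "py", "pz")] * ev)), 1, tolerance = 1e-9)
})

test_that("tilt regression recovers slopes with exclusions and weights", {
  mk_seg <- function(theta, r2, n) data.frame(segment = seq_along(theta),
                                              n_voxels = n, theta = theta,
                                              mean_r2 = r2)
  th0 <- seq(5, 85, length.out = 20)
  th18 <- pmin(90, th0 + 15)
  # exact linear construction y = 2 x (sin4 differences)
  x4 <- sin(th0 * pi / 180)^4 - sin(th18 * pi / 180)^4
  s0 <- mk_seg(th0, 20 + 2 * sin(th0 * pi / 180)^4, 5)
  st <- mk_seg(th18, 20 + 2 * sin(th18 * pi / 180)^4, 5)
  tr <- tilt_regression(s0, st, "r2", form = "sin4")
  expect_equal(tr$slope, 2, tolerance = 1e-9)
  expect_equal(tr$rss, 0, tolerance = 1e-12)
  expect_equal(tr$n, 12)                 # segments 5..16 of 20 survive
  # sin4 form has the lowest AIC for a sin4 truth; iso has none
  expect_equal(tr$aic_table$form[which.min(tr$aic_table$aic)], "sin4")
  # tract phantom with the generative sin2 law: slope ~ 3 noise-free,
  # using ground-truth voxel R2 values as the segment estimates
  ph <- build_tract_phantom(phantom_spec(noise_model = "none"))
  cs <- core_and_segments(ph$streamlines, n_segments = 20)
  tabs <- list()
  for (tilt in c(0, 18)) {
    tag <- paste0("tilt", tilt)
    vdf <- data.frame(x = ph$voxels$x, y = ph$voxels$y, z = ph$voxels$z,
                      nx = ph$voxels[[paste0("nx_", tag)]],
                      ny = ph$voxels[[paste0("ny_", tag)]],
                      nz = ph$voxels[[paste0("nz_", tag)]],
                      r2 = ph$voxels[[paste0("r2_e_", tag)]])
    segs <- cs
    segs$tangents <- apply_tilt(cs$tangents, tilt)
    tabs[[tag]] <- segment_stats(vdf, assign_voxels(vdf, segs), "r2",
                                 n_segments = 20)
  }
  tr2 <- tilt_regression(tabs$tilt0, tabs$tilt18, "r2", form = "sin2")
  expect_equal(tr2$slope, 3, tolerance = 0.02)
  # isotropic ground truth: zero-slope CI and iso-minimal AIC
  s_iso0 <- mk_seg(th0, rep(18, 20), 5)
  s_iso18 <- mk_seg(th18, rep(18, 20), 5)
  s_iso0$mean_r2 <- s_iso0$mean_r2 + c(0.01, -0.01)   # tiny jitter, recycled
  tr3 <- tilt_regression(s_iso0, s_iso18, "r2", form = "sin4")
  expect_true(tr3$ci95["lower"] <= 0 && tr3$ci95["upper"] >= 0)
  expect_equal(tr3$aic_table$form[which.min(tr3$aic_table$aic)], "iso")
  # voxel-count weighting: the slope is the w-weighted origin regression
  # with w = mean voxel count across the two orientations
  s_w <- mk_seg(th0, 20 + 2 * sin(th0 * pi / 180)^4 +
                  rep(c(0.2, -0.2), 10), c(rep(4, 10), rep(8, 10)))
  st_w <- mk_seg(th18, 20 + 2 * sin(th18 * pi / 180)^4, 6)
  tr_w <- tilt_regression(s_w, st_w, "r2", form = "sin4")
  keep <- 5:16
  w <- (s_w$n_voxels[keep] + st_w$n_voxels[keep]) / 2
  yv <- s_w$mean_r2[keep] - st_w$mean_r2[keep]
  xv <- x4[keep]
  expect_equal(tr_w$slope, sum(w * xv * yv) / sum(w * xv^2), tolerance = 1e-12)
  # exclusion of sparse segments
  s_sparse <- s0; s_sparse$n_voxels[6] <- 2
  tr4 <- tilt_regression(s_sparse, st, "r2")
  expect_equal(tr4$n, 11)
  expect_error(tilt_regression(s0[1:2, ], st[1:2, ], "r2"), "fewer than 2")
})

test_that("ICC matches its closed-form limits and null behaviour", {
  x <- c(11, 12, 13, 15, 18)
  expect_equal(icc(x, x)$icc, 1)
  # mirrored about the pooled mean: exactly -1
  xbar <- mean(x)
  expect_equal(icc(x, 2 * xbar - x)$icc, -1)
  # independent pairs: |ICC| < 0.05 at N = 1e4
  set.seed(12)
  expect_lt(abs(icc(rnorm(1e4), rnorm(1e4))$icc), 0.05)
  # labels
  expect_equal(icc(x, x)$label, "excellent")
  expect_true(icc(c(1, 1), c(1, 1))$undefined)
  expect_error(icc(1:3, 1:2), "equal length")
})
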