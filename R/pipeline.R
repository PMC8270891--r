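#' Pipeline configuration
#'
#' A single configuration object drives the three pipeline stages
#' (simulate, fit, analyze). Every analysis threshold defaults to its
#' published value: SFP relative peak threshold 0.10, absolute peak
#' threshold 0.1, CSF fraction 0.01, orientational coherence p2 cut 0.5,
#' segment angular threshold 15 degrees, 20 segments with 20% endpoint
#' exclusion per side and a 3-voxel minimum. Angles are degrees at every
#' interface. The object round-trips losslessly through JSON.
#'
#' @param outdir working directory for pipeline outputs
#' @param seed integer seed used by every stochastic stage
#' @param od orientation dispersion of the simulated voxels
#' @param noise_model,snr0 noise settings of the generator
#' @param theta_list,n_voxels_per_angle angle-sweep design
#' @param tilt_angles coil tilts in degrees
#' @param n_dir,n_b0 acquisition-grid settings
#' @param n_tract_voxels voxels seeded along the tract phantom
#' @param sfp_rel,sfp_abs,sfp_csf,p2_min SFP/coherence thresholds
#' @param angular_threshold,n_segments,endpoint_frac,min_voxels
#'   tractometry settings
#' @param b0_axis main-field axis
#' @return object of class `t2o_config` (a named list)
#' @export
pipeline_config <- function(outdir = tempfile("t2orient_"), seed = 1L,
                            od = 0, noise_model = "none", snr0 = 100,
                            theta_list = seq(0, 90, by = 10),
                            n_voxels_per_angle = 1,
                            tilt_angles = c(0, 18),
                            n_dir = 30, n_b0 = 3, n_tract_voxels = 120,
                            sfp_rel = 0.10, sfp_abs = 0.1, sfp_csf = 0.01,
                            p2_min = 0.5,
                            angular_threshold = 15, n_segments = 20,
                            endpoint_frac = 0.2, min_voxels = 3,
                            b0_axis = c(0, 0, 1)) {
  cfg <- list(outdir = outdir, seed = as.integer(seed), od = od,
              noise_model = noise_model, snr0 = snr0,
              theta_list = theta_list,
              n_voxels_per_angle = n_voxels_per_angle,
              tilt_angles = tilt_angles, n_dir = n_dir, n_b0 = n_b0,
              n_tract_voxels = n_tract_voxels, sfp_rel = sfp_rel, sfp_abs = sfp_abs, sfp_csf = sfp_csf,
              p2_min = p2_min, angular_threshold = angular_threshold,
              n_segments = n_segments, endpoint_frac = endpoint_frac,
              min_voxels = min_voxels, b0_axis = b0_axis)
  structure(cfg, class = "t2o_config")
}

#' @rdname pipeline_config
#' @param config a `t2o_config`
#' @param path JSON file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

## plain-text streamline table: one row per point (streamline, point, x, y, z)
write_streamlines <- function(streamlines, path) {
  rows <- do.call(rbind, lapply(seq_along(streamlines), function(i) {
    p <- streamlines[[i]]
    data.frame(streamline = i, point = seq_len(nrow(p)),
               x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

read_streamlines <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$streamline),
         function(s) as.matrix(s[order(s$point), c("x", "y", "z")]))
}

#' Simulate a phantom dataset to disk
#'
#' Runs the synthetic-data generator end to end: writes the acquisition
#' scheme (FSL-style bval/bvec plus a TE column file), per-tilt voxel
#' signal tables and ground truth, the tract-phantom streamlines, and a
#' JSON manifest recording the seed and generation settings.
#'
#' @param config a [pipeline_config()]
#' @return the output directory, invisibly
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "t2o_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- make_default_grid(n_dir = config$n_dir, n_b0 = config$n_b0)
  write_grid(grid, file.path(config$outdir, "scheme.bval"),
             file.path(config$outdir, "scheme.bvec"),
             file.path(config$outdir, "scheme.te"))
  spec <- phantom_spec(theta_list = config$theta_list,
                       n_voxels_per_angle = config$n_voxels_per_angle,
                       od = config$od, noise_model = config$noise_model,
                       snr0 = config$snr0, seed = config$seed,
                       tilt_angles = config$tilt_angles)
  sweep <- simulate_angle_sweep(grid, spec)
  utils::write.csv(cbind(sweep$truth,
                         as.data.frame(sweep$signals)),
                   file.path(config$outdir, "sweep_signals.csv"),
                   row.names = FALSE)
  phantom <- build_tract_phantom(spec, n_voxels = config$n_tract_voxels)
  write_streamlines(phantom$streamlines,
                    file.path(config$outdir, "streamlines.csv"))
  utils::write.csv(phantom$voxels, file.path(config$outdir, "tract_voxels.csv"),
                   row.names = FALSE)
  for (tilt in config$tilt_angles) {
    sigs <- tract_phantom_signals(phantom, grid, tilt)
    utils::write.csv(as.data.frame(sigs),
                     file.path(config$outdir,
                               sprintf("tract_signals_tilt%g.csv", tilt)),
                     row.names = FALSE)
  }
  manifest <- list(seed = config$seed, od = config$od,
                   noise_model = config$noise_model, snr0 = config$snr0,
                   n_entries = grid$n, tilt_angles = config$tilt_angles,
                   package = "t2orient",
                   version = as.character(utils::packageVersion("t2orient")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$outdir)
}

## voxel-wise mono-exponential + compartmental fits over a signal matrix
.fit_voxel_matrix <- function(signals, grid, orientations) {
  nv <- nrow(signals)
  out <- vector("list", nv)
  b0 <- grid$b == 0
  for (i in seq_len(nv)) {
    y <- signals[i, ]
    n <- .normalize(orientations[i, ])
    mono <- fit_monoexp_t2(y[b0], grid$te[b0])
    comp <- fit_compartmental(y, grid, n)
    out[[i]] <- data.frame(
      voxel = i, theta = angle_to_b0(n),
      r2_m = mono$r2, t2_m = mono$t2,
      f = comp$params$f, d_par_i = comp$params$d_par_i,
      d_par_e = comp$params$d_par_e, d_perp_e = comp$params$d_perp_e,
      r2_i = comp$r2_i, r2_e = comp$r2_e,
      rss = comp$rss, converged = comp$converged,
      hit_boundary = comp$hit_boundary, mono_hit_bound = mono$hit_bound)
  }
  do.call(rbind, out)
}

#' Fit the simulated dataset voxel-wise
#'
#' Reads the simulated scheme and signal tables from `config$outdir`,
#' validates that volume counts match the gradient table, and runs the
#' mono-exponential and compartmental fits for every voxel of the angle
#' sweep and of the tract phantom (per tilt). Results are written as CSV
#' tables next to the inputs.
#'
#' @param config a [pipeline_config()] whose `outdir` holds
#'   [run_simulate()] outputs
#' @return the sweep fit table (data.frame), invisibly
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "t2o_config"))
  od <- config$outdir
  tefile <- file.path(od, "scheme.te")
  if (!file.exists(tefile)) stop("missing TE file: ", tefile)
  grid <- read_grid(file.path(od, "scheme.bval"), file.path(od, "scheme.bvec"),
                    tefile)
  sweep <- utils::read.csv(file.path(od, "sweep_signals.csv"))
  meta_cols <- c("voxel", "theta", "od", "r2_i_true", "r2_e_true", "f_true",
                 "sigma")
  sigs <- as.matrix(sweep[, setdiff(names(sweep), meta_cols)])
  if (ncol(sigs) != grid$n)
    stop("signal table has ", ncol(sigs), " volumes but the gradient table has ",
         grid$n)
  orient <- cbind(sin(deg2rad(sweep$theta)), 0, cos(deg2rad(sweep$theta)))
  fits <- cbind(.fit_voxel_matrix(sigs, grid, orient),
                sweep[, c("od", "r2_i_true", "r2_e_true")])
  utils::write.csv(fits, file.path(od, "sweep_fits.csv"), row.names = FALSE)
  vox <- utils::read.csv(file.path(od, "tract_voxels.csv"))
  for (tilt in config$tilt_angles) {
    tag <- paste0("tilt", tilt)
    f <- file.path(od, sprintf("tract_signals_tilt%g.csv", tilt))
    tsig <- as.matrix(utils::read.csv(f))
    ori <- as.matrix(vox[, paste0(c("nx_", "ny_", "nz_"), tag)])
    tf <- .fit_voxel_matrix(tsig, grid, ori)
    tf$x <- vox$x; tf$y <- vox$y; tf$z <- vox$z
    utils::write.csv(tf, file.path(od, sprintf("tract_fits_tilt%g.csv", tilt)),
                     row.names = FALSE)
  }
  invisible(fits)
}

## segment tables (one per tilt) for a fitted pipeline output directory
.segment_tables <- function(config, outdir) {
  strm <- read_streamlines(file.path(outdir, "streamlines.csv"))
  segments <- core_and_segments(strm, n_segments = config$n_segments)
  vox <- utils::read.csv(file.path(outdir, "tract_voxels.csv"))
  tables <- list()
  for (tilt in config$tilt_angles) {
    tf <- utils::read.csv(file.path(outdir,
                                    sprintf("tract_fits_tilt%g.csv", tilt)))
    tag <- paste0("tilt", tilt)
    vdf <- data.frame(x = vox$x, y = vox$y, z = vox$z,
                      nx = vox[[paste0("nx_", tag)]],
                      ny = vox[[paste0("ny_", tag)]],
                      nz = vox[[paste0("nz_", tag)]],
                      r2_m = tf$r2_m, r2_i = tf$r2_i, r2_e = tf$r2_e)
    ## the tilt rotates the tissue, not the scanner-frame core geometry:
    ## assignment uses untilted positions; the angular filter compares
    ## each tilt's orientations against the tangents rotated along
    seg_t <- segments
    seg_t$tangents <- apply_tilt(segments$tangents, tilt)
    assign <- assign_voxels(vdf, seg_t,
                            angular_threshold = config$angular_threshold)
    tables[[as.character(tilt)]] <-
      segment_stats(vdf, assign, c("r2_m", "r2_i", "r2_e"),
                    n_segments = config$n_segments)
  }
  tables
}

#' Analyse fitted outputs: representations, tilt regression, ICC
#'
#' Consumes the fit tables of [run_fit()]: pools non-boundary sweep
#' voxels and fits/selects the R2(theta) representation family for the
#' mono-exponential, intra- and extra-axonal rates; runs the segment-wise
#' tilt-difference regression on the tract phantom; and, when a retest
#' output directory is supplied (a second [run_fit()] run of the same
#' geometry), reports the segment-wise test-retest ICC of R2 and theta
#' for each tilt. Writes `analysis.json` in the output directory.
#'
#' @param config a [pipeline_config()] whose `outdir` holds [run_fit()]
#'   outputs
#' @param retest_outdir optional directory of a retest run
#' @return list with `representations` (per estimate: audit + selected
#'   kind and coefficients), `tilt` (per estimate: slope, CI, AIC table),
#'   `icc` (NULL without retest data)
#' @export
run_analyze <- function(config, retest_outdir = NULL) {
  stopifnot(inherits(config, "t2o_config"))
  od <- config$outdir
  fits <- utils::read.csv(file.path(od, "sweep_fits.csv"))
  keep <- !fits$hit_boundary & fits$converged
  if (!any(keep)) stop("no SFP voxels survive the filters")
  pooled <- fits[keep, , drop = FALSE]
  reps <- list()
  for (est in c("r2_m", "r2_i", "r2_e")) {
    res <- fit_all_representations(pooled$theta, pooled[[est]])
    reps[[est]] <- list(
      selected_kind = res$selected$kind,
      coefs = as.list(res$selected$coefs),
      audit = res$audit)
  }
  tilt_tables <- .segment_tables(config, od)
  t0 <- as.character(config$tilt_angles[1])
  t1 <- as.character(config$tilt_angles[2])
  tilt_res <- list()
  for (est in c("r2_m", "r2_i", "r2_e")) {
    tr <- tilt_regression(tilt_tables[[t0]], tilt_tables[[t1]], est,
                          n_segments = config$n_segments,
                          endpoint_frac = config$endpoint_frac,
                          min_voxels = config$min_voxels)
    tilt_res[[est]] <- tr[c("slope", "se", "ci95", "n", "form", "aic_table")]
  }
  icc_res <- NULL
  if (!is.null(retest_outdir)) {
    retest_tables <- .segment_tables(config, retest_outdir)
    icc_res <- list()
    for (tilt in c(t0, t1)) {
      a <- tilt_tables[[tilt]]; b <- retest_tables[[tilt]]
      m <- merge(a, b, by = "segment", suffixes = c("_test", "_retest"))
      icc_res[[paste0("tilt", tilt)]] <- list(
        r2_m = icc(m$mean_r2_m_test, m$mean_r2_m_retest),
        theta = icc(m$theta_test, m$theta_retest))
    }
  }
  out <- list(representations = reps, tilt = tilt_res, icc = icc_res)
  jsonlite::write_json(out, file.path(od, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out
}

#' Angle-sweep recovery experiment in memory
#'
#' Simulates an angle sweep with [simulate_angle_sweep()], fits every
#' voxel (mono-exponential and compartmental), drops boundary-hitting
#' voxels, and summarises the extra-axonal rates with a sin^2
#' representation fit. This is the package's canonical
#' simulate-estimate-summarise experiment: with no noise and no
#' dispersion it recovers the generative parameters; with increasing
#' orientation dispersion the recovered extra-axonal anisotropy shrinks.
#'
#' @param grid an [acquisition_grid] (default [make_default_grid()])
#' @param spec a [phantom_spec]
#' @return list with `fits` (per-voxel data.frame), `sin2_e` (the sin^2
#'   [fit_representation()] of the extra-axonal rates), and `summary`
#'   (named list: r2_aniso_e, r2_iso_e, mean_r2_i, mean_f, mean_d_par_i,
#'   mean_d_perp_e)
#' @export
sweep_recovery <- function(spec, grid = make_default_grid()) {
  sweep <- simulate_angle_sweep(grid, spec)
  orient <- cbind(sin(deg2rad(sweep$truth$theta)), 0,
                  cos(deg2rad(sweep$truth$theta)))
  fits <- .fit_voxel_matrix(sweep$signals, grid, orient)
  keep <- !fits$hit_boundary & fits$converged
  kept <- fits[keep, , drop = FALSE]
  if (nrow(kept) < 4) stop("too few non-boundary voxels to summarise")
  sin2_e <- fit_representation(kept$theta, kept$r2_e, "sin2")
  list(fits = fits, sin2_e = sin2_e,
       summary = list(r2_aniso_e = unname(sin2_e$coefs[2]),
                      r2_iso_e = unname(sin2_e$coefs[1]),
                      mean_r2_i = mean(kept$r2_i),
                      mean_f = mean(kept$f),
                      mean_d_par_i = mean(kept$d_par_i),
                      mean_d_perp_e = mean(kept$d_perp_e)))
}
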