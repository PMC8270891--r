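#' Diffusion-T2 acquisition grid
#'
#' An acquisition grid is the list of (b, g, TE) triplets sampled by a
#' diffusion-T2 correlation experiment: diffusion weighting b (ms/um^2),
#' unit gradient direction g, and echo time TE (ms). Optionally each entry
#' carries a symmetric 3x3 B-matrix (same trace convention as b), as
#' produced by gradient-nonlinearity correction.
#'
#' @param b numeric vector of b-values, ms/um^2, all >= 0
#' @param g numeric n x 3 matrix of gradient directions; rows with b > 0
#'   must be unit vectors (rows with b = 0 may be zero and are stored as-is)
#' @param te numeric vector of echo times, ms, all > 0
#' @param bmatrix optional list of symmetric 3x3 matrices (one per entry)
#'   with \code{trace(B) == b} within 1e-6 relative
#' @return an object of class `acquisition_grid`: a list with elements
#'   `b`, `g`, `te`, `bmatrix` (or NULL) and `n` (number of entries)
#' @export
acquisition_grid <- function(b, g, te, bmatrix = NULL) {
  b <- as.numeric(b); te <- as.numeric(te)
  g <- as.matrix(g)
  if (ncol(g) != 3L) stop("g must have 3 columns")
  n <- length(b)
  if (nrow(g) != n || length(te) != n)
    stop("b, g, te must have matching lengths (", n, ", ", nrow(g), ", ",
         length(te), ")")
  if (any(!is.finite(b)) || any(b < 0)) stop("all b-values must be finite and >= 0")
  if (any(!is.finite(te)) || any(te <= 0)) stop("all TE must be finite and > 0")
  norms <- sqrt(rowSums(g^2))
  bad <- b > 0 & abs(norms - 1) > 1e-6
  if (any(bad))
    stop(sum(bad), " gradient direction(s) with b > 0 are not unit vectors")
  if (!is.null(bmatrix)) {
    if (!is.list(bmatrix) || length(bmatrix) != n)
      stop("bmatrix must be a list with one 3x3 matrix per entry")
    for (i in seq_len(n)) {
      B <- bmatrix[[i]]
      if (!is.matrix(B) || !all(dim(B) == c(3L, 3L)))
        stop("bmatrix[[", i, "]] is not 3x3")
      if (max(abs(B - t(B))) > 1e-9 * max(1, max(abs(B))))
        stop("bmatrix[[", i, "]] is not symmetric")
      tr <- sum(diag(B))
      if (abs(tr - b[i]) > 1e-6 * max(1, abs(b[i])))
        stop("trace(bmatrix[[", i, "]]) = ", format(tr),
             " does not match b = ", format(b[i]))
    }
  }
  structure(list(b = b, g = g, te = te, bmatrix = bmatrix, n = n),
            class = "acquisition_grid")
}

#' @export
print.acquisition_grid <- function(x, ...) {
  cat("<acquisition_grid> ", x$n, " entries\n", sep = "")
  cat("  b shells (ms/um^2): ", paste(sort(unique(x$b)), collapse = ", "), "\n", sep = "")
  cat("  TEs (ms): ", paste(sort(unique(x$te)), collapse = ", "), "\n", sep = "")
  if (!is.null(x$bmatrix)) cat("  per-entry B-matrices present\n")
  invisible(x)
}

#' Deterministic unit direction sets on the sphere
#'
#' Generates `n` approximately uniform unit vectors using a Fibonacci
#' spherical lattice. With `antipodal = TRUE`, `n` must be even and the set
#' is built as n/2 lattice points plus their antipodes, so the set is
#' exactly antipodally symmetric (as required for quadrature over
#' antipodally symmetric orientation distributions).
#'
#' @param n number of directions
#' @param antipodal logical; return an exactly antipodally symmetric set
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n, antipodal = FALSE) {
  stopifnot(n >= 1)
  if (antipodal) {
    if (n %% 2L != 0L) stop("antipodal direction sets need even n")
    half <- fibonacci_sphere(n %/% 2L, antipodal = FALSE)
    return(rbind(half, -half))
  }
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (2 / (1 + sqrt(5)))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default diffusion-T2 acquisition grid
#'
#' Builds the 6-TE x 9-b sampling scheme the analysis assumes: echo times
#' spanning 54-130 ms (the 54 ms anchor is the shortest TE at which myelin
#' water is negligible), nine b-shells from 0 to 6 ms/um^2 (the maximum
#' supports intra/extra-axonal separation), a fixed number of directions
#' per nonzero shell, and b = 0 repeated `n_b0` times per TE so the
#' mono-exponential T2 fit has replicates at every TE. Diffusion timings
#' are fixed across TE and never enter the model, so they are not
#' parameters of the grid.
#'
#' @param tes echo times in ms (default 6 values spanning 54-130 ms)
#' @param bvals b-shells in ms/um^2 (default 9 values, 0 to 6)
#' @param n_dir directions per nonzero shell (default 30)
#' @param n_b0 b = 0 repetitions per TE (default 3)
#' @return an [acquisition_grid]
#' @export
make_default_grid <- function(tes = seq(54, 130, length.out = 6),
                              bvals = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4.5, 6),
                              n_dir = 30, n_b0 = 3) {
  if (length(tes) < 1 || length(bvals) < 1) stop("empty TE or b-shell list")
  if (any(bvals < 0)) stop("negative b-value")
  nz <- sort(unique(bvals[bvals > 0]))
  has0 <- any(bvals == 0)
  dirs <- fibonacci_sphere(n_dir)
  b <- c(); gx <- c(); gy <- c(); gz <- c(); te <- c()
  for (t in tes) {
    if (has0) {
      b <- c(b, rep(0, n_b0)); te <- c(te, rep(t, n_b0))
      gx <- c(gx, rep(0, n_b0)); gy <- c(gy, rep(0, n_b0)); gz <- c(gz, rep(0, n_b0))
    }
    for (bb in nz) {
      b <- c(b, rep(bb, n_dir)); te <- c(te, rep(t, n_dir))
      gx <- c(gx, dirs[, 1]); gy <- c(gy, dirs[, 2]); gz <- c(gz, dirs[, 3])
    }
  }
  acquisition_grid(b, cbind(gx, gy, gz), te)
}

#' Read and write FSL-style gradient tables with a TE column
#'
#' The on-disk scheme is the field's plain-text convention: a `bval` file
#' (one row of b-values, s/mm^2), a `bvec` file (three rows x,y,z), and a
#' TE file (one echo time per volume, ms). b-values are converted to
#' ms/um^2 on read and back to s/mm^2 on write.
#'
#' @param grid an [acquisition_grid]
#' @param bval,bvec,tefile file paths
#' @return `read_grid` returns an [acquisition_grid]; `write_grid` returns
#'   the paths invisibly.
#' @export
write_grid <- function(grid, bval, bvec, tefile) {
  stopifnot(inherits(grid, "acquisition_grid"))
  writeLines(paste(format(grid$b * 1000, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval)
  gl <- apply(t(grid$g), 1, function(row)
    paste(format(row, trim = TRUE, digits = 15), collapse = " "))
  writeLines(gl, bvec)
  writeLines(format(grid$te, trim = TRUE), tefile)
  invisible(c(bval = bval, bvec = bvec, te = tefile))
}

#' @rdname write_grid
#' @export
read_grid <- function(bval, bvec, tefile) {
  b <- scan(bval, quiet = TRUE) / 1000
  gv <- scan(bvec, quiet = TRUE)
  n <- length(b)
  if (length(gv) != 3 * n)
    stop("bvec has ", length(gv), " values; expected ", 3 * n)
  g <- t(matrix(gv, nrow = 3, byrow = TRUE))
  te <- scan(tefile, quiet = TRUE)
  if (length(te) != n)
    stop("TE file has ", length(te), " values; expected ", n)
  acquisition_grid(b, g, te)
}
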