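test_that("tSNR is mean over sd with undefined-variance flagging", {
  r <- tsnr(c(90, 100, 110))
  expect_equal(r$tsnr, 10)
  r2 <- tsnr(c(5, 5, 5, 5))
  expect_true(r2$undefined)
  expect_true(is.na(r2$tsnr))
  expect_error(tsnr(matrix(1, 3, 1)), "repetitions")
  # simulation oracle: gaussian series with known sigma over 1e4 voxels;
  # 60 repetitions keep the small-sample sd bias below the tolerance
  set.seed(8)
  m <- matrix(rnorm(1e4 * 60, mean = 50, sd = 2), 1e4, 60)
  est <- tsnr(m)
  expect_equal(median(est$tsnr), 25, tolerance = 0.02)
})

test_that("rician bias correction inverts the magnitude first moment", {
  expect_identical(rician_correct(c(0.3, 1), 0), c(0.3, 1))
  # pure-noise expectation maps to zero
  sigma <- 0.2
  expect_equal(rician_correct(sigma * sqrt(pi / 2), sigma), 0)
  expect_equal(rician_correct(0.5 * sigma, sigma), 0)   # below the floor
  # high SNR: correction smaller than 2% of the signal
  m <- 50 * sigma
  corr <- rician_correct(m, sigma)
  expect_lt(abs(corr - m), 0.02 * m)
  expect_gt(corr, 0)
  # round trip through the forward first moment at moderate SNR
  for (nu in c(0.5, 1, 3) * sigma) {
    fwd <- t2orient:::.ncchi_mean(nu, sigma, 1)
    expect_equal(rician_correct(fwd, sigma), nu, tolerance = 1e-6)
  }
  # multi-coil route agrees with the coils = 1 closed form
  expect_equal(t2orient:::.ncchi_mean(0.4, sigma, 1),
               sigma * stats::integrate(function(q)
                 sqrt(q) * stats::dchisq(q, 2, ncp = (0.4 / sigma)^2),
                 0, Inf, rel.tol = 1e-10)$value,
               tolerance = 1e-8)
  expect_error(rician_correct(1, 0.1, coils = 0), "coils")
})

test_that("mono-exponential T2 fit matches closed forms and reduces bias", {
  # two-point closed form: halving over one TE step gives T2 = dTE/ln 2
  f <- fit_monoexp_t2(c(1, 0.5), c(54, 108))
  expect_equal(f$t2, 54 / log(2), tolerance = 1e-6)
  # noise-free decay recovered to 1e-6 relative
  te <- seq(54, 130, length.out = 6)
  y <- 0.9 * exp(-te / 70)
  f2 <- fit_monoexp_t2(y, te)
  expect_equal(f2$t2, 70, tolerance = 1e-6)
  expect_equal(f2$s0, 0.9, tolerance = 1e-6)
  expect_false(f2$hit_bound)
  # non-decaying signal pins T2 at the upper bound with a flag
  f3 <- fit_monoexp_t2(c(1, 1.01, 0.99, 1, 1.02, 1), te)
  expect_true(f3$hit_bound)
  # paired simulation: Rician-corrected fits are less biased than raw ones
  set.seed(31)
  sigma <- 0.03
  err_raw <- err_corr <- numeric(150)
  for (i in seq_len(150)) {
    noisy <- add_noise(y, sigma, "rician")
    err_raw[i] <- fit_monoexp_t2(noisy, te)$t2 - 70
    corr <- rician_correct(noisy, sigma)
    corr[corr <= 0] <- 1e-6
    err_corr[i] <- fit_monoexp_t2(corr, te)$t2 - 70
  }
  expect_lt(abs(mean(err_corr)), abs(mean(err_raw)))
})

test_that("compartmental fit recovers the generative world when noise-free", {
  grid <- full_grid()
  fit <- fit_compartmental(clean_signal_at(grid, 0), grid, fibre_at(0))
  expect_false(fit$hit_boundary)
  expect_true(fit$converged)
  expect_equal(fit$params$f, 0.5, tolerance = 1e-3)
  expect_equal(fit$params$d_par_i, 2.5, tolerance = 1e-3)
  expect_equal(fit$params$d_par_e, 2.0, tolerance = 1e-3)
  expect_equal(fit$params$d_perp_e, 0.8, tolerance = 1e-3)
  expect_equal(fit$r2_i, 12, tolerance = 1e-3)
  expect_equal(fit$r2_e, 17, tolerance = 1e-3)
  # permuting grid-entry order leaves the estimates unchanged
  set.seed(14)
  perm <- sample(grid$n)
  gperm <- acquisition_grid(grid$b[perm], grid$g[perm, ], grid$te[perm])
  fp <- fit_compartmental(clean_signal_at(grid, 0)[perm], gperm, fibre_at(0))
  expect_equal(fp$params$f, fit$params$f, tolerance = 1e-10)
  expect_equal(fp$r2_e, fit$r2_e, tolerance = 1e-10)
})

test_that("boundary-truth voxels are flagged, interior-truth voxels are not", {
  grid <- full_grid()
  # f = 0: pure zeppelin, truth on the lower bound of f
  p0 <- tissue_params(0, 2.5, 2, 0.8, 1000 / 12, 1000 / 17)
  s0 <- compartmental_signal(grid, p0, fibre_at(30))
  f0 <- fit_compartmental(s0, grid, fibre_at(30))
  expect_true(f0$hit_boundary)
  # interior truth across a theta sweep is never flagged (exclusion rule
  # must not remove clean voxels)
  for (th in c(10, 50, 80)) {
    ft <- fit_compartmental(clean_signal_at(grid, th), grid, fibre_at(th))
    expect_false(ft$hit_boundary)
  }
  expect_error(fit_compartmental(1:5, grid, fibre_at(0)), "length")
})

test_that("SFP selection applies the three published thresholds", {
  expect_true(select_sfp(c(0.5, 0.04), 0)$accept)           # ratio 8%
  r1 <- select_sfp(c(0.5, 0.12), 0)
  expect_false(r1$accept)                                    # ratio 24%
  expect_match(r1$reason, "relative")
  r2 <- select_sfp(c(0.08, 0), 0)
  expect_false(r2$accept)                                    # absolute
  expect_match(r2$reason, "absolute")
  r3 <- select_sfp(c(0.5, 0.01), 0.05)
  expect_false(r3$accept)                                    # CSF 5%
  expect_match(r3$reason, "CSF")
  # boundary values are accepted
  expect_true(select_sfp(c(0.1, 0.01), 0.01)$accept)
  expect_true(select_sfp(0.4, 0)$accept)                     # single peak
  expect_false(select_sfp(numeric(0), 0)$accept)
  expect_error(select_sfp(c(0.1, 0.5), 0), "descending")
})

test_that("noisy fits stay in bounds and T2_e error is finite at SNR 100", {
  grid <- full_grid()
  set.seed(63)
  clean <- clean_signal_at(grid, 40)
  errs <- numeric(40)
  for (i in seq_along(errs)) {
    noisy <- add_noise(clean, 0.01, "gaussian")
    f <- fit_compartmental(noisy, grid, fibre_at(40))
    expect_true(f$params$t2_e >= 30 && f$params$t2_e <= 300)
    errs[i] <- f$params$t2_e - 1000 / representation_value(gen_r2e(), 40)
  }
  expect_true(is.finite(median(abs(errs))))
  expect_lt(median(abs(errs)), 20)      # ms, loose desk-scale sanity bound
})
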