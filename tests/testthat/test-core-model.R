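test_that("stick attenuation matches its closed form and limits", {
  n <- c(0, 0, 1)
  # no diffusion weighting
  expect_equal(stick_attenuation(0, c(1, 0, 0), n, 2.5), 1)
  # gradient perpendicular to the stick: no attenuation at any b
  expect_equal(stick_attenuation(3, c(1, 0, 0), n, 2.5), 1)
  # parallel gradient: pure exponential in b * D
  expect_equal(stick_attenuation(1, c(0, 0, 1), n, 2.5), exp(-2.5))
  # oblique: scalar closed form computed independently
  g <- c(1, 0, 1) / sqrt(2)
  expect_equal(stick_attenuation(2, g, n, 1.7), exp(-2 * 1.7 * 0.5))
  expect_error(stick_attenuation(-1, c(0, 0, 1), n, 2.5), "b must")
  expect_error(stick_attenuation(1, c(0, 0, 2), n, 2.5), "unit")
})

test_that("zeppelin attenuation matches its closed form and isotropic limit", {
  n <- c(0, 0, 1)
  expect_equal(zeppelin_attenuation(0, c(1, 0, 0), n, 2, 0.8), 1)
  # isotropic limit: direction-independent exp(-b D)
  for (g in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3)))
    expect_equal(zeppelin_attenuation(1.5, g, n, 1.2, 1.2), exp(-1.5 * 1.2))
  expect_equal(zeppelin_attenuation(1, c(0, 0, 1), n, 2, 0.8), exp(-2))
  expect_equal(zeppelin_attenuation(1, c(1, 0, 0), n, 2, 0.8), exp(-0.8))
})

test_that("B-matrix overloads reproduce scalar-b results exactly", {
  n <- c(sin(0.4), 0, cos(0.4))
  for (gv in list(c(0, 0, 1), c(1, 2, 2) / 3)) {
    b <- 2.5
    B <- b * tcrossprod(gv)
    expect_equal(stick_attenuation(b, gv, n, 2.1),
                 stick_attenuation(NULL, NULL, n, 2.1, bmatrix = B),
                 tolerance = 1e-12)
    expect_equal(zeppelin_attenuation(b, gv, n, 2, 0.8),
                 zeppelin_attenuation(NULL, NULL, n, 2, 0.8, bmatrix = B),
                 tolerance = 1e-12)
  }
  # grid-level: attaching bmatrix = b g g' must not change the signal
  grid <- small_grid(n_dir = 6, n_b0 = 1)
  bmats <- lapply(seq_len(grid$n), function(i)
    grid$b[i] * tcrossprod(grid$g[i, ]))
  grid_bm <- acquisition_grid(grid$b, grid$g, grid$te, bmatrix = bmats)
  p <- gen_params()
  expect_equal(compartmental_signal(grid_bm, p, n),
               compartmental_signal(grid, p, n), tolerance = 1e-12)
})

test_that("compartmental signal matches the scalar two-compartment oracle", {
  # b = 0, TE = 54 ms voxel of the generative world at theta = 0:
  # 0.5 exp(-54 * 12/1000) + 0.5 exp(-54 * 17/1000), computed by hand
  grid <- acquisition_grid(0, matrix(c(0, 0, 0), 1), 54)
  p <- gen_params()
  expect_equal(compartmental_signal(grid, p, c(0, 0, 1)),
               0.5 * exp(-54 * 0.012) + 0.5 * exp(-54 * 0.017),
               tolerance = 1e-12)
  # pure stick with perpendicular gradient: only T2 decay remains
  g2 <- acquisition_grid(3, matrix(c(1, 0, 0), 1), 80)
  p1 <- tissue_params(1, 2.5, 2, 0.8, 90, 60, s0 = 2)
  expect_equal(compartmental_signal(g2, p1, c(0, 0, 1)), 2 * exp(-80 / 90))
  # TE -> 0, b = 0 recovers S0
  g3 <- acquisition_grid(0, matrix(0, 1, 3), 1e-9)
  expect_equal(compartmental_signal(g3, p, c(0, 0, 1)), 1, tolerance = 1e-9)
})

test_that("signal is positive, bounded by S0, and monotone in b and TE", {
  grid <- full_grid()
  set.seed(11)
  for (rep in 1:5) {
    dpe <- runif(1, 0.5, 3)
    p <- tissue_params(runif(1), runif(1, 0.5, 3), dpe,
                       runif(1, 0, min(2, dpe)), runif(1, 30, 300),
                       runif(1, 30, 300), s0 = runif(1, 0.5, 2))
    th <- runif(1, 0, 90)
    s <- compartmental_signal(grid, p, fibre_at(th))
    expect_true(all(s > 0) && all(s <= p$s0))
    # monotone non-increasing in b at fixed direction and TE
    ord <- order(grid$b)
    same_dir <- abs(drop(grid$g %*% grid$g[ord[length(ord)], ])) > 0.999
    for (te in unique(grid$te)) {
      idx <- which(same_dir & grid$te == te)
      idx <- idx[order(grid$b[idx])]
      if (length(idx) > 1) expect_true(all(diff(s[idx]) <= 1e-12))
    }
    # monotone decreasing in TE at b = 0
    b0 <- which(grid$b == 0)
    b0 <- b0[!duplicated(grid$te[b0])]
    b0 <- b0[order(grid$te[b0])]
    expect_true(all(diff(s[b0]) < 0))
  }
})

test_that("angle to B0 folds antipodally into [0, 90] degrees", {
  expect_equal(angle_to_b0(c(0, 0, 1)), 0)
  expect_equal(angle_to_b0(c(1, 0, 0)), 90)
  expect_equal(angle_to_b0(c(0, 0, -1)), 0)
  expect_equal(angle_to_b0(fibre_at(35)), 35, tolerance = 1e-10)
  # alternative field axis
  expect_equal(angle_to_b0(c(1, 0, 0), b0_axis = c(1, 0, 0)), 0)
  expect_error(angle_to_b0(c(0, 0, 0)), "unit")
})

test_that("representation values follow the printed functional forms", {
  # in-vivo mono-exponential representation evaluated at 90 degrees
  full <- r2_representation("full", 13.6, r2_aniso1 = 3.3, r2_aniso2 = -1.1)
  expect_equal(representation_value(full, 90), 13.6 + 3.3 - 1.1)
  expect_equal(representation_value(full, 0), 13.6)
  # magic-angle form: bracket vanishes at 0, equals 1 at the magic angle
  magic <- r2_representation("magic", 12, r2_aniso = 0.8)
  expect_equal(representation_value(magic, 0), 12)
  th_magic <- acos(1 / sqrt(3)) * 180 / pi
  expect_equal(representation_value(magic, th_magic), 12.8, tolerance = 1e-10)
  # extremum location: argmax on a fine grid is the magic angle
  m <- anisotropy_magnitude(magic)
  expect_equal(m$theta_max, 54.74, tolerance = 0.02)
  # negative anisotropy flips max to min
  m2 <- anisotropy_magnitude(r2_representation("magic", 12, r2_aniso = -0.8))
  expect_equal(m2$theta_min, 54.74, tolerance = 0.02)
  expect_error(representation_value(full, 120), "theta")
})

test_that("trigonometric form conversions agree with direct evaluation", {
  # printed worked case: a + b cos(2 theta) with a = b = 1
  expect_equal(convert_trig_form("cos2", 1, 1), c(A = 2, B = -2))
  # all-zero coefficients map to all-zero outputs
  for (f in c("cos2", "cos2cos4", "dipolar_sq"))
    expect_true(all(convert_trig_form(f, 0, 0) == 0))
  expect_true(all(convert_trig_form("cos2_cos4", 0, 0, 0) == 0))
  # round-trip property: converted sin-power form reproduces the source
  # form pointwise at 1000 random angles to 1e-12
  set.seed(4)
  th <- runif(1000, 0, 90)
  cases <- list(list("cos2", 1.3, -0.7, NULL),
                list("cos2cos4", 14.2, 2.1, NULL),
                list("dipolar_sq", 12, 0.8, NULL),
                list("cos2_cos4", 13.6, -1.9, 0.4))
  for (cs in cases) {
    coefs <- convert_trig_form(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    direct <- t2orient:::eval_trig_form(cs[[1]], cs[[2]], cs[[3]], cs[[4]], th)
    expect_lt(max(abs(t2orient:::eval_sin_power(coefs, th) - direct)), 1e-12)
  }
  # 37-point fixed-grid variant of the same oracle
  th37 <- seq(0, 90, length.out = 37)
  coefs <- convert_trig_form("dipolar_sq", 2, 0.5)
  expect_lt(max(abs(t2orient:::eval_sin_power(coefs, th37) -
                    t2orient:::eval_trig_form("dipolar_sq", 2, 0.5, NULL, th37))),
            1e-12)
})

test_that("magic-angle representation is the dipolar-squared sin-power form", {
  # representation iv equals iso + aniso - aniso/4 (3cos^2-1)^2; its
  # sin-power coefficients follow from the dipolar_sq conversion
  iso <- 12; aniso <- 0.8
  cf <- convert_trig_form("dipolar_sq", iso + aniso, -aniso / 4)
  magic <- r2_representation("magic", iso, r2_aniso = aniso)
  th <- seq(0, 90, by = 3)
  expect_equal(representation_value(magic, th),
               t2orient:::eval_sin_power(cf, th), tolerance = 1e-12)
})
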