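## shared fixtures: small grids and the generative tissue world used
## throughout (f = 0.5, D||i = 2.5, D||e = 2, D_|_e = 0.8 um^2/ms,
## R2_i = 12 1/s isotropic, R2_e(theta) = 17 + 3 sin^2(theta) 1/s)

small_grid <- function(n_dir = 12, n_b0 = 2) {
  make_default_grid(tes = c(54, 92, 130), bvals = c(0, 1, 2.5, 6),
                    n_dir = n_dir, n_b0 = n_b0)
}

full_grid <- function() make_default_grid()

gen_params <- function() {
  tissue_params(f = 0.5, d_par_i = 2.5, d_par_e = 2, d_perp_e = 0.8,
                t2_i = 1000 / 12, t2_e = 1000 / 17, s0 = 1)
}

gen_r2i <- function() r2_representation("iso", r2_iso = 12)
gen_r2e <- function() r2_representation("sin2", r2_iso = 17, r2_aniso = 3)

fibre_at <- function(theta_deg) {
  c(sin(theta_deg * pi / 180), 0, cos(theta_deg * pi / 180))
}

## noise-free delta-fODF signal of the generative world at a fibre angle
clean_signal_at <- function(grid, theta_deg, params = gen_params()) {
  p <- params
  p$t2_e <- 1000 / representation_value(gen_r2e(), theta_deg)
  p$t2_i <- 1000 / representation_value(gen_r2i(), theta_deg)
  compartmental_signal(grid, p, fibre_at(theta_deg))
}
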