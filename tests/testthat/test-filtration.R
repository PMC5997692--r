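test_that("hydraulic permeability: ratios, zero-intercept slope, guards", {
  expect_equal(hydraulic_permeability(
    data.frame(pressure_bar = 1, flux_LMH = 64.8))$lp_LMH_bar, 64.8)
  fx <- gen_flux_pressure(3.0, noise = 0, seed = 1)
  expect_equal(hydraulic_permeability(fx)$lp_LMH_bar, 3.0,
               tolerance = 1e-12)
  expect_equal(hydraulic_permeability(
    data.frame(pressure_bar = c(1, 2), flux_LMH = c(0, 0)))$lp_LMH_bar, 0)
  # psi pressures are converted explicitly
  expect_equal(hydraulic_permeability(
    data.frame(pressure_psi = 50, flux_LMH = 3.447))$lp_LMH_bar,
    3.447 / (50 * 0.0689476), tolerance = 1e-9)
  expect_error(hydraulic_permeability(
    data.frame(pressure_bar = 1, flux_LMH = -1)), "negative")
})

test_that("observed rejection definition and flags", {
  expect_equal(observed_rejection(1, 0)$R_o, 1)
  expect_equal(observed_rejection(1, 1)$R_o, 0)
  expect_equal(observed_rejection(35, 3.5)$R_o, 0.9)
  r <- observed_rejection(1, 1.2)
  expect_equal(r$R_o, 0)
  expect_true(r$out_of_range)
  expect_error(observed_rejection(0, 1), "> 0")
})

test_that("stagnant-film correction: identities, closed form, exact inversion", {
  expect_equal(polarization_correct(0.5, 0, 10)$R_t, 0.5)
  # R_o = 0.5 at J_v/k = ln 2 gives R_t = 2/3
  expect_equal(polarization_correct(0.5, log(2), 1)$R_t, 2 / 3,
               tolerance = 1e-12)
  b <- polarization_correct(c(0, 1), 5, 10)
  expect_equal(b$R_t, c(0, 1))
  expect_true(all(b$boundary))
  # R_t >= R_o always
  ro <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(polarization_correct(ro, 3, 7)$R_t >= ro))
  # exact inverse of the generator's forward model
  d0 <- gen_rejection_dataset(noise = 0, seed = 2)
  ro0 <- observed_rejection(d0$records$c_feed, d0$records$c_permeate)$R_o
  rt <- polarization_correct(ro0, d0$records$jv_LMH,
                             d0$records$k_mt_LMH)$R_t
  expect_equal(rt, d0$truth$r_true, tolerance = 1e-12)
})

test_that("logistic MWCO fit: exact recovery, invariances, monotonicity", {
  m <- seq(100, 1100, by = 50)
  r <- 0.97 / (1 + exp(-(m - 420) / 60))
  df <- data.frame(mw_da = m, R = r)
  fit <- fit_mwco(df, use_corrected = FALSE)
  expect_equal(fit$mu, 420, tolerance = 1e-4)
  expect_equal(fit$s, 60, tolerance = 1e-4)
  expect_equal(fit$r_max, 0.97, tolerance = 1e-4)
  expect_equal(fit$sigma, pi * 60 / sqrt(3), tolerance = 1e-4)
  # record order and duplication do not change the fit
  fit_rev <- fit_mwco(df[rev(seq_len(nrow(df))), ], use_corrected = FALSE)
  expect_equal(fit_rev$mwco, fit$mwco, tolerance = 1e-6)
  fit_dup <- fit_mwco(rbind(df, df), use_corrected = FALSE)
  expect_equal(fit_dup$mwco, fit$mwco, tolerance = 1e-6)
  # mwco is monotone in mu at fixed s and R_max
  mwcos <- vapply(c(380, 420, 460), function(mu0) {
    fit_mwco(data.frame(mw_da = m,
                        R = 0.97 / (1 + exp(-(m - mu0) / 60))),
             use_corrected = FALSE)$mwco
  }, numeric(1))
  expect_true(all(diff(mwcos) > 0))
  expect_error(fit_mwco(data.frame(mw_da = m, R = rep(0.5, length(m))),
                        use_corrected = FALSE), "transition")
  expect_error(fit_mwco(df[1:3, ], use_corrected = FALSE), "at least 4")
})

test_that("corrected end-to-end fit recovers the truth MWCO and sharpness", {
  ds <- gen_rejection_dataset(true_mwco = 450,
                              spread_s = 0.29 * 450 * sqrt(3) / pi,
                              noise = 0.01, seed = 31)
  fit <- fit_mwco(ds, use_corrected = TRUE)
  expect_equal(fit$mwco, 450, tolerance = 0.03)
  expect_gt(fit$sharpness, 0.26)
  expect_lt(fit$sharpness, 0.32)
  # skipping the correction biases the cutoff upward
  fit_raw <- fit_mwco(ds, use_corrected = FALSE)
  expect_gt(fit_raw$mwco, fit$mwco)
})

test_that("pore-size distribution: normalization, mode, closed-form s.d.", {
  m <- seq(100, 1100, by = 50)
  fit <- fit_mwco(data.frame(mw_da = m,
                             R = 1 / (1 + exp(-(m - 450) / 70))),
                  use_corrected = FALSE)
  psd <- pore_size_distribution(fit)
  expect_equal(pracma::trapz(psd$mw, psd$density), 1, tolerance = 1e-6)
  expect_equal(psd$mw[which.max(psd$density)], fit$mu,
               tolerance = 0.01)
  expect_equal(psd$sd, pi * fit$s / sqrt(3), tolerance = 0.005)
  expect_equal(psd$mean, fit$mu, tolerance = 0.005)
  expect_error(pore_size_distribution(fit,
                                      mw_grid = seq(400, 500, by = 10)),
               "5 s")
})
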