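test_that("every generator is a pure function of its seed", {
  gens <- list(
    function(s) gen_scattering_trace(3.3, seed = s)$data,
    function(s) gen_fcs_curve(5, 0.4, seed = s)$data,
    function(s) gen_channel_water_trajectory(n_waters = 5, n_frames = 50,
                                             seed = s)$coords,
    function(s) gen_tilt_trajectory(15, 5, n_frames = 20, seed = s)$coords,
    function(s) gen_smd_traces(n_replicates = 1, n_out = 50,
                               seed = s)[[1]]$data,
    function(s) gen_rejection_dataset(seed = s)$records,
    function(s) gen_frap_trace(0.4, 1, 0.34, 10, seed = s)$data,
    function(s) gen_flux_pressure(3, seed = s)$data
  )
  for (g in gens) {
    expect_identical(g(42L), g(42L))
    expect_false(identical(g(42L), g(43L)))
  }
  expect_error(gen_scattering_trace(3.3), "seed")
})

test_that("scattering generator embeds the forward-model rate", {
  tr <- gen_scattering_trace(3.3, radius_nm = 100, delta_osm = 100,
                             seed = 1)
  expect_equal(tr$truth$k_per_s, 0.178, tolerance = 2e-3)
  # noiseless trace is exactly exponential
  tr0 <- gen_scattering_trace(5, noise = 0, seed = 1)
  with(tr0$data, expect_equal(
    intensity,
    tr0$truth$baseline + tr0$truth$amplitude * exp(-tr0$truth$k_per_s *
                                                     time_s),
    tolerance = 1e-12))
  expect_warning(gen_scattering_trace(3.3, duration = 0.5, seed = 1),
                 "poorly constrained")
})

test_that("FCS generator reduces to the single-species model at the limits", {
  lag <- 10^seq(-5, 0, length.out = 40)
  c1 <- gen_fcs_curve(5, fraction_slow = 1, tau_slow = 1e-3, noise = 0,
                      lag_grid = lag, seed = 1)
  expect_equal(c1$data$G,
               fcs_model(lag, 5, 1, tau_fast = 5e-5, tau_slow = 1e-3),
               tolerance = 1e-12)
  # decorrelation limit
  expect_lt(fcs_model(1e6, 5, 0.5, 1e-4, 1e-2), 1e-6)
})

test_that("Brownian water generator obeys the Einstein relation", {
  tw <- gen_channel_water_trajectory(n_waters = 100, axial_D = 0.2,
                                     channel_length = 4, dt = 0.02,
                                     n_frames = 1200, seed = 7)
  un <- unwrap_trajectory(tw, axes = 3)
  mc <- msd(un, "waters", dims = "z", fragment_length = 8)
  d <- diffusivity(mc)
  expect_equal(d$D, 0.2, tolerance = 0.05)
  expect_true(d$reliable)
  # D = 0 freezes all axial displacements
  t0 <- gen_channel_water_trajectory(n_waters = 5, axial_D = 0,
                                     n_frames = 20, seed = 1)
  expect_equal(max(abs(apply(t0$coords[, 3, ], 1, diff))), 0)
})

test_that("tilt generator respects its limits and errors", {
  t0 <- gen_tilt_trajectory(25, wobble_deg = 0, n_frames = 10, seed = 1)
  ts <- tilt_angle_series(t0, "ring")
  expect_equal(ts$angle_deg, rep(25, 10), tolerance = 1e-8)
  tz <- gen_tilt_trajectory(0, wobble_deg = 0, n_frames = 5, seed = 1)
  expect_equal(max(tilt_angle_series(tz, "ring")$angle_deg), 0,
               tolerance = 1e-8)
  expect_error(gen_tilt_trajectory(95, seed = 1), "\\[0, 90\\]")
})

test_that("SMD generator: drag force at flat potential, zero-barrier PMF, dt guard", {
  # overdamped steady state at zero temperature: F = gamma * v
  tr <- gen_smd_traces(barrier_height = 0, kT = 0, n_replicates = 1,
                       n_out = 100, seed = 1)
  f <- tr[[1]]$data$force_kcal_mol_A
  expect_equal(mean(f[-(1:10)]), 0.05 * 10, tolerance = 0.02)
  # zero barrier integrates to ~0 net PMF beyond the drag ramp
  tr0 <- gen_smd_traces(barrier_height = 0, n_replicates = 3, n_out = 100,
                        seed = 2)
  pmf <- integrate_pmf(average_forces(tr0))
  drag_ramp <- 0.05 * 10 * diff(range(pmf$z))
  expect_lt(pmf$barrier_height, drag_ramp + 2)
  expect_error(gen_smd_traces(dt = 1e-3, seed = 1), "dt too large")
})

test_that("rejection generator: polarization off is the identity, round trip recovers MWCO", {
  d0 <- gen_rejection_dataset(jv = 0, noise = 0, seed = 1)
  expect_equal(observed_rejection(d0$records$c_feed,
                                  d0$records$c_permeate)$R_o,
               d0$truth$r_true, tolerance = 1e-9)
  ds <- gen_rejection_dataset(true_mwco = 450, spread_s = 72, noise = 0.01,
                              seed = 3)
  fit <- fit_mwco(ds)
  expect_equal(fit$mwco, 450, tolerance = 0.03)
  expect_warning(gen_rejection_dataset(jv = 500, k_mt = 10, seed = 1),
                 "polarization")
})

test_that("FRAP generator: limits and simplex validation", {
  f1 <- gen_frap_trace(1, 2, 0, 10, noise = 0, seed = 1)
  with(f1$data, expect_equal(F_norm, 1 - exp(-time_s / 2),
                             tolerance = 1e-12))
  ft <- gen_frap_trace(0.4, 1, 0.34, 10, noise = 0, seed = 1)
  expect_equal(utils::tail(ft$data$F_norm, 1), 0.74, tolerance = 0.01)
  expect_error(gen_frap_trace(0.7, 1, 0.5, 10, seed = 1), "simplex|<= 1")
})

test_that("flux generator: noiseless series has the true slope", {
  fx <- gen_flux_pressure(3.0, noise = 0, seed = 1)
  expect_equal(hydraulic_permeability(fx)$lp_LMH_bar, 3.0,
               tolerance = 1e-12)
  # default pressures are 50/60/70 psi converted at 0.0689476 bar/psi
  expect_equal(fx$data$pressure_bar, c(50, 60, 70) * 0.0689476)
})
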