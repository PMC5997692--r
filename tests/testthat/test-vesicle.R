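test_that("swelling fit recovers a noiseless exponential exactly", {
  tt <- seq(0, 2, length.out = 200)
  df <- data.frame(time_s = tt, intensity = 0.2 + exp(-5 * tt))
  fit <- fit_swelling_rate(df)
  expect_equal(fit$k, 5, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.2, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
})

test_that("swelling fit rejects degenerate and non-decaying traces", {
  tt <- seq(0, 2, length.out = 50)
  expect_error(fit_swelling_rate(
    data.frame(time_s = tt, intensity = rep(1, 50))), "constant")
  expect_error(fit_swelling_rate(
    data.frame(time_s = tt, intensity = 1 + tt)), "not a swelling trace")
  expect_error(fit_swelling_rate(
    data.frame(time_s = tt[1:10], intensity = exp(-tt[1:10]))),
    "at least 20")
})

test_that("generator round trip recovers the rate within 3% at 2% noise", {
  for (s in 1:3) {
    tr <- gen_scattering_trace(3.3, noise = 0.02, seed = s)
    fit <- fit_swelling_rate(tr)
    expect_equal(fit$k, tr$truth$k_per_s, tolerance = 0.03)
  }
})

test_that("two-exponential fit reports the dominant rate", {
  tt <- seq(0, 3, length.out = 300)
  df <- data.frame(time_s = tt,
                   intensity = 0.1 + 0.8 * exp(-2 * tt) +
                     0.2 * exp(-20 * tt))
  fit <- fit_swelling_rate(df, n_exponentials = 2)
  expect_equal(fit$k, 2, tolerance = 0.02)
})

test_that("rate-to-permeability conversion and its inverse", {
  spec <- vesicle_spec(100, 100)
  expect_equal(rate_to_permeability(0.1782, spec)$pf_um_s, 3.3,
               tolerance = 1e-3)
  expect_identical(rate_to_permeability(0, spec)$pf_um_s, 0)
  # doubling the radius doubles Pf at fixed k
  expect_equal(rate_to_permeability(0.1, vesicle_spec(200, 100))$pf_um_s,
               2 * rate_to_permeability(0.1, spec)$pf_um_s,
               tolerance = 1e-12)
  expect_equal(permeability_to_rate(
    rate_to_permeability(0.37, spec)$pf_um_s, spec), 0.37,
    tolerance = 1e-12)
})

test_that("net permeability subtracts background and flags negatives", {
  expect_equal(net_permeability(3.3, 3.3)$pf_net_um_s, 0)
  n <- net_permeability(46.6, 0)
  expect_equal(n$pf_net_um_s, 46.6)
  expect_false(n$below_background)
  n <- net_permeability(1, 2, sd_sample = 0.3, sd_control = 0.4)
  expect_equal(n$pf_net_um_s, -1)
  expect_true(n$below_background)
  expect_equal(n$sd, 0.5)
})

test_that("single-channel permeability: worked example, scaling, inversion", {
  sc <- single_channel_permeability(46.6, 160, 383)
  # liposome worked example lands at ~3.3e8 molecules/s
  expect_equal(sc$pf_single_mol_s, 3.3e8, tolerance = 0.03)
  # internal consistency between the two unit systems
  expect_equal(sc$pf_single_mol_s,
               volumetric_to_molecular(sc$pf_single_vol_cm3_s),
               tolerance = 1e-9)
  # halving the channel count doubles the per-channel flow
  sc2 <- single_channel_permeability(46.6, 160, 383 / 2)
  expect_equal(sc2$pf_single_mol_s, 2 * sc$pf_single_mol_s,
               tolerance = 1e-12)
  expect_identical(single_channel_permeability(0, 160, 383)$pf_single_mol_s,
                   0)
  # inversion back to the net permeability
  pf_back <- sc$pf_single_vol_cm3_s * 1e-6 * 383 /
    (pi * (160e-9)^2) * 1e6
  expect_equal(pf_back, 46.6, tolerance = 1e-9)
  expect_error(single_channel_permeability(46.6, 160, 0), "> 0")
})

test_that("uncertainty propagation covers the delta-method terms", {
  sc <- single_channel_permeability(46.6, 160, 383, pf_sd = 13.8,
                                    n_sd = 52)
  rel <- sqrt((13.8 / 46.6)^2 + (52 / 383)^2)
  expect_equal(sc$sd_mol_s / sc$pf_single_mol_s, rel, tolerance = 1e-9)
})

test_that("insertion efficiency: simple variant worked example and guards", {
  # 2 * 4 pi 80^2 / 0.70 amphiphiles x 0.005 = ~1149 theoretical channels
  r <- insertion_efficiency(383, 0.005, 160, 0.70)
  expect_equal(r$n_theoretical, 1149, tolerance = 0.01)
  expect_equal(r$efficiency_pct, 33.3, tolerance = 0.01)
  # measured == theoretical is 100%
  r2 <- insertion_efficiency(r$n_theoretical, 0.005, 160, 0.70)
  expect_equal(r2$efficiency_pct, 100, tolerance = 1e-9)
  expect_identical(insertion_efficiency(0, 0.005, 160, 0.70)$efficiency_pct,
                   0)
  # self-consistent variant removes channel-occupied area
  r3 <- insertion_efficiency(383, 0.005, 160, 0.70, channel_area_nm2 = 1.5)
  expect_lt(r3$n_theoretical, r$n_theoretical)
  expect_error(insertion_efficiency(1e5, 0.005, 160, 0.70),
               "inconsistent")
})

test_that("full composition law: generate -> fit -> convert returns pf", {
  spec <- vesicle_spec(100, 100)
  for (pf in c(1, 3.3, 46.6)) {
    tr <- gen_scattering_trace(pf, noise = 0.02, seed = 101)
    fit <- fit_swelling_rate(tr)
    out <- rate_to_permeability(fit$k, spec, fit$k_se)
    expect_equal(out$pf_um_s, pf, tolerance = 0.05)
  }
})
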