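brownian_traj <- function(n_atoms, n_frames, d_coef, dt, seed) {
  withr::with_seed(seed, {
    arr <- array(stats::rnorm(n_atoms * 3 * n_frames,
                              sd = sqrt(2 * d_coef * dt)),
                 dim = c(n_atoms, 3, n_frames))
    arr[, , 1] <- 0
    arr <- aperm(apply(arr, c(1, 2), cumsum), c(2, 3, 1))
    trajectory(arr, dt = dt, groups = list(all = seq_len(n_atoms)))
  })
}

test_that("MSD limits: static, ballistic, Brownian", {
  # static coordinates
  arr <- array(1, dim = c(2, 3, 30))
  tr <- trajectory(arr, dt = 1, groups = list(a = 1:2))
  expect_equal(max(msd(tr, "a", fragment_length = 30)$msd), 0)
  # ballistic x = v t gives msd = v^2 lag^2
  v <- 0.3
  arr <- array(0, dim = c(1, 3, 50))
  arr[1, 1, ] <- v * (0:49)
  tr <- trajectory(arr, dt = 1, groups = list(a = 1))
  mc <- msd(tr, "a", dims = "xyz", fragment_length = 50)
  expect_equal(mc$msd, v^2 * mc$lag^2, tolerance = 1e-9)
  # Brownian slope recovers D via the Einstein relation
  tr <- brownian_traj(150, 2000, 0.1, 0.02, seed = 11)
  d <- diffusivity(msd(tr, "all", dims = "xyz", fragment_length = 4))
  expect_equal(d$D, 0.1, tolerance = 0.05)
})

test_that("fragment averaging agrees with whole-trajectory averaging", {
  tr <- brownian_traj(40, 1000, 0.1, 0.02, seed = 12)
  frag <- msd(tr, "all", fragment_length = 5)
  whole <- msd(tr, "all", fragment_length = 20)
  common <- frag$lag[frag$lag > 0 & frag$lag <= 1]
  m1 <- frag$msd[match(common, frag$lag)]
  m2 <- whole$msd[match(common, whole$lag)]
  expect_equal(m1, m2, tolerance = 0.15)
})

test_that("isotropic input decomposes into consistent diffusivities", {
  tr <- brownian_traj(80, 1500, 0.1, 0.02, seed = 13)
  d_all <- diffusivity(msd(tr, "all", "xyz", fragment_length = 6))$D
  d_lat <- diffusivity(msd(tr, "all", "xy", fragment_length = 6))$D
  d_ver <- diffusivity(msd(tr, "all", "z", fragment_length = 6))$D
  expect_equal(d_lat, d_all, tolerance = 0.1)
  expect_equal(d_ver, d_all, tolerance = 0.1)
  # component bookkeeping: 3 D_xyz ~ 2 D_xy + D_z
  expect_equal(3 * d_all, 2 * d_lat + d_ver, tolerance = 0.1)
})

test_that("wrapped coordinates are refused and unwrap repairs them", {
  tw <- gen_channel_water_trajectory(n_waters = 30, axial_D = 0.3,
                                     channel_length = 2, dt = 0.1,
                                     n_frames = 400, seed = 14)
  expect_error(msd(tw, "waters", dims = "z", fragment_length = 10),
               "unwrap")
  un <- unwrap_trajectory(tw, axes = 3)
  d <- diffusivity(msd(un, "waters", dims = "z", fragment_length = 4))
  expect_equal(d$D, 0.3, tolerance = 0.1)
})

test_that("RMSD: zero cases, rigid-motion invariance, known expansion", {
  phi <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(cos(phi), sin(phi), 0)
  arr <- array(0, dim = c(12, 3, 3))
  arr[, , 1] <- ring
  arr[, , 2] <- sweep(ring, 2, c(1, -2, 3), "+")   # pure translation
  arr[, , 3] <- 1.1 * ring                          # radial expansion
  tr <- trajectory(arr, dt = 1, groups = list(ring = 1:12))
  r <- rmsd_series(tr, "ring", superpose = TRUE)
  expect_equal(r[1], 0, tolerance = 1e-9)
  expect_equal(r[2], 0, tolerance = 1e-9)
  expect_equal(r[3], 0.1, tolerance = 1e-9)
  # without superposition the translation is visible
  r_raw <- rmsd_series(tr, "ring", superpose = FALSE)
  expect_gt(r_raw[2], 1)
  # a uniform rigid rotation applied to every frame changes nothing
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  arr2 <- arr
  for (f in 1:3) arr2[, , f] <- arr[, , f] %*% t(rot)
  tr2 <- trajectory(arr2, dt = 1, groups = list(ring = 1:12))
  expect_equal(rmsd_series(tr2, "ring"), r, tolerance = 1e-9)
  # collinear geometry cannot be superposed
  line <- array(0, dim = c(4, 3, 2))
  line[, 1, 1] <- 1:4; line[, 1, 2] <- 1:4
  trl <- trajectory(line, dt = 1, groups = list(a = 1:4))
  expect_error(rmsd_series(trl, "a"), "collinear|degenerate")
})

test_that("tilt angle follows the stated convention and symmetries", {
  phi <- seq(0, 2 * pi, length.out = 11)[-11]
  flat <- array(cbind(cos(phi), sin(phi), 0), dim = c(10, 3, 1))
  tr <- trajectory(flat, dt = 1, groups = list(ring = 1:10))
  expect_equal(tilt_angle_series(tr, "ring")$angle_deg, 0,
               tolerance = 1e-8)
  # ring containing the z-axis lies parallel to it: 90 degrees
  upright <- array(cbind(cos(phi), 0, sin(phi)), dim = c(10, 3, 1))
  tru <- trajectory(upright, dt = 1, groups = list(ring = 1:10))
  expect_equal(tilt_angle_series(tru, "ring")$angle_deg, 90,
               tolerance = 1e-8)
  # invariance under rotation about z and rigid translation
  tg <- gen_tilt_trajectory(20, wobble_deg = 0, n_frames = 4, seed = 15)
  a0 <- tilt_angle_series(tg, "ring")$angle_deg
  th <- 1.1
  rotz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
  arr <- tg$coords
  for (f in seq_len(dim(arr)[3]))
    arr[, , f] <- sweep(arr[, , f] %*% t(rotz), 2, c(5, -1, 2), "+")
  tg2 <- trajectory(arr, dt = tg$dt, groups = tg$groups)
  expect_equal(tilt_angle_series(tg2, "ring")$angle_deg, a0,
               tolerance = 1e-8)
  # generator mean recovered within the CLT bound
  tg3 <- gen_tilt_trajectory(15, wobble_deg = 5, n_frames = 2000,
                             seed = 16)
  ts <- tilt_angle_series(tg3, "ring")
  expect_equal(ts$mean, 15, tolerance = 5 * 3 / sqrt(2000) / 15)
})

test_that("collective coordinate counts slab traversals", {
  # one water crossing the full slab contributes exactly 1
  nf <- 101
  arr <- array(0, dim = c(1, 3, nf))
  arr[1, 3, ] <- seq(0, 4, length.out = nf)
  tr <- trajectory(arr, dt = 1, groups = list(waters = 1),
                   box = c(1, 1, 4))
  cs <- collective_coordinate(tr, "waters", list(z_lo = 0, z_hi = 4))
  expect_equal(cs$n[nf], 1, tolerance = 1e-9)
  # two waters each crossing half the slab also sum to 1
  arr2 <- array(0, dim = c(2, 3, nf))
  arr2[1, 3, ] <- seq(0, 2, length.out = nf)
  arr2[2, 3, ] <- seq(2, 4, length.out = nf)
  tr2 <- trajectory(arr2, dt = 1, groups = list(waters = 1:2),
                    box = c(1, 1, 4))
  cs2 <- collective_coordinate(tr2, "waters", list(z_lo = 0, z_hi = 4))
  expect_equal(cs2$n[nf], 1, tolerance = 1e-9)
  # zero net motion keeps n at zero
  arr3 <- array(2, dim = c(3, 3, 10))
  tr3 <- trajectory(arr3, dt = 1, groups = list(waters = 1:3),
                    box = c(1, 1, 4))
  expect_equal(max(abs(collective_coordinate(
    tr3, "waters", list(z_lo = 0, z_hi = 4))$n)), 0)
  # steps near the ambiguity bound are refused
  arr4 <- array(0, dim = c(1, 3, 10))
  arr4[1, 3, ] <- (0:9 * 1.5) %% 4
  tr4 <- trajectory(arr4, dt = 1, groups = list(waters = 1),
                    box = c(1, 1, 4))
  expect_error(collective_coordinate(tr4, "waters",
                                     list(z_lo = 0, z_hi = 4)),
               "finely")
})

test_that("collective permeability is zero for frozen waters and linear in N", {
  t0 <- gen_channel_water_trajectory(n_waters = 10, axial_D = 0,
                                     n_frames = 200, seed = 17)
  cs <- collective_coordinate(t0, "waters", list(z_lo = 0, z_hi = 4))
  expect_equal(collective_permeability(cs)$pf_cm3_s, 0)
  # doubling N doubles pf (same D, L)
  p <- vapply(c(20, 40), function(n) {
    tw <- gen_channel_water_trajectory(n_waters = n, axial_D = 0.2,
                                       channel_length = 4, dt = 0.02,
                                       n_frames = 6000, seed = 18)
    cs <- collective_coordinate(tw, "waters", list(z_lo = 0, z_hi = 4))
    collective_permeability(cs)$pf_molecules_s
  }, numeric(1))
  expect_equal(p[2] / p[1], 2, tolerance = 0.15)
})
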