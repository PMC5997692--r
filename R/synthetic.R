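# Seeded forward models for every input class the analysis stages consume.
# Each generator is a pure function of its arguments (seed included) and
# records its ground-truth parameters in the returned object's `truth`
# element so downstream fits can be checked against them.

.require_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed))
    stop("an explicit integer `seed` is required for every stochastic stage",
         call. = FALSE)
  as.integer(seed)
}

#' Simulate a stopped-flow light-scattering swelling trace
#'
#' Vesicles exposed to a hypotonic gradient swell; at 90 degrees scattering
#' the intensity decays approximately exponentially with rate
#' `k = Pf * (3/r) * V_w * dC` (sphere surface-to-volume ratio 3/r, `dC` the
#' osmolyte gradient in mol m^-3). The trace is
#' `I(t) = baseline + A exp(-k t) + eps` with additive Gaussian noise of
#' standard deviation `noise * A`, a detector-like model.
#'
#' @param pf_true True osmotic permeability, um s^-1 (> 0).
#' @param radius_nm Vesicle hydrodynamic radius, nm.
#' @param delta_osm Osmotic gradient, mOsm (numerically mol m^-3).
#' @param temperature K (metadata only; the decay rate does not depend on it).
#' @param duration Trace length, s; default `5/k` so the decay is resolved.
#' @param n_points Number of samples.
#' @param noise Relative noise s.d. (fraction of the decay amplitude).
#' @param baseline,amplitude Intensity offset and decay amplitude (a.u.).
#' @param seed Integer seed (required).
#' @return A `scattering_trace`: `data` (time_s, intensity), `temperature`,
#'   and `truth` (pf_um_s, k_per_s, ...).
#' @export
gen_scattering_trace <- function(pf_true, radius_nm = 100, delta_osm = 100,
                                 temperature = 283.15, duration = NULL,
                                 n_points = 400, noise = 0.02,
                                 baseline = 0.2, amplitude = 1, seed) {
  seed <- .require_seed(seed)
  .assert_scalar(pf_true, "pf_true", positive = TRUE)
  .assert_scalar(radius_nm, "radius_nm", positive = TRUE)
  .assert_scalar(delta_osm, "delta_osm", positive = TRUE)
  .assert_scalar(noise, "noise", nonneg = TRUE)
  kc <- channel_constants()
  k <- (pf_true * 1e-6) * (3 / (radius_nm * 1e-9)) *
    kc$molar_volume_water * delta_osm
  if (is.null(duration)) duration <- 5 / k
  if (duration * k < 1)
    warning("duration * k < 1: decay poorly constrained by this trace",
            call. = FALSE)
  tt <- seq(0, duration, length.out = n_points)
  ideal <- baseline + amplitude * exp(-k * tt)
  intensity <- withr::with_seed(seed,
    ideal + stats::rnorm(n_points, sd = noise * amplitude))
  structure(list(
    data = data.frame(time_s = tt, intensity = intensity),
    temperature = temperature,
    truth = list(pf_um_s = pf_true, k_per_s = k, radius_nm = radius_nm,
                 delta_osm = delta_osm, baseline = baseline,
                 amplitude = amplitude, noise = noise, seed = seed)
  ), class = "scattering_trace")
}

#' Simulate a two-species FCS autocorrelation curve
#'
#' Evaluates the standard two-species 3D Gaussian focal-volume model (see
#' [fcs_model()]) on a lag grid and applies multiplicative Gaussian noise,
#' `G_obs = G * (1 + noise * eps)`.
#'
#' @param n_particles Mean particle number in the focal volume (> 0).
#' @param fraction_slow Fraction of the slow species, in \[0, 1\].
#' @param tau_fast,tau_slow Diffusion times, s (fast < slow).
#' @param structure_param Focal-volume axial/lateral ratio (default 5).
#' @param lag_grid Lag times, s; default 120 log-spaced points 1e-5..1 s.
#' @param noise Relative noise s.d.
#' @param seed Integer seed (required).
#' @return A `correlation_curve`: `data` (lag_s, G) and `truth`.
#' @export
gen_fcs_curve <- function(n_particles, fraction_slow, tau_fast = 5e-5,
                          tau_slow = 5e-3, structure_param = 5,
                          lag_grid = 10^seq(-5, 0, length.out = 120),
                          noise = 0.01, seed) {
  seed <- .require_seed(seed)
  .assert_scalar(n_particles, "n_particles", positive = TRUE)
  .assert_scalar(fraction_slow, "fraction_slow", nonneg = TRUE)
  if (fraction_slow > 1) stop("`fraction_slow` must be in [0, 1]",
                              call. = FALSE)
  .assert_scalar(tau_fast, "tau_fast", positive = TRUE)
  .assert_scalar(tau_slow, "tau_slow", positive = TRUE)
  g <- fcs_model(lag_grid, n_particles, fraction_slow, tau_fast, tau_slow,
                 structure_param)
  g_obs <- withr::with_seed(seed,
    g * (1 + stats::rnorm(length(g), sd = noise)))
  structure(list(
    data = data.frame(lag_s = lag_grid, G = g_obs),
    truth = list(n_particles = n_particles, fraction_slow = fraction_slow,
                 tau_fast = tau_fast, tau_slow = tau_slow,
                 structure_param = structure_param, noise = noise,
                 seed = seed)
  ), class = "correlation_curve")
}

#' Simulate single-file channel waters as 1D Brownian motion
#'
#' Each of `n_waters` particles performs independent Brownian motion along
#' the membrane normal z with diffusivity `axial_D`, wrapped periodically
#' into the channel slab \[0, L) so every water stays in-region (the
#' single-file channel is treated as a periodic column of water). Lateral
#' coordinates are frozen at their initial values inside the pore radius.
#' The truth diffusivity is recorded for recovery tests of the collective
#' diffusion estimator.
#'
#' @param n_waters Number of waters.
#' @param axial_D Axial diffusivity, nm^2 ns^-1 (>= 0).
#' @param channel_length Slab length L, nm.
#' @param dt Frame spacing, ns. Must satisfy `sqrt(2 D dt) << L/2`.
#' @param n_frames Number of frames.
#' @param lateral_radius Pore radius bounding the frozen x,y positions, nm.
#' @param seed Integer seed (required).
#' @return A `trajectory` with a single group `waters` and box
#'   `c(2r, 2r, L)`; `truth` holds `axial_D` and `channel_length`.
#' @export
gen_channel_water_trajectory <- function(n_waters = 40, axial_D = 0.2,
                                         channel_length = 4, dt = 0.02,
                                         n_frames = 5000,
                                         lateral_radius = 0.25, seed) {
  seed <- .require_seed(seed)
  .assert_scalar(n_waters, "n_waters", positive = TRUE)
  .assert_scalar(axial_D, "axial_D", nonneg = TRUE)
  .assert_scalar(channel_length, "channel_length", positive = TRUE)
  .assert_scalar(dt, "dt", positive = TRUE)
  l <- channel_length
  step_sd <- sqrt(2 * axial_D * dt)
  if (step_sd > l / 6)
    warning("per-frame displacement s.d. exceeds L/6; wrapping will bias ",
            "the collective coordinate", call. = FALSE)
  coords <- withr::with_seed(seed, {
    z0 <- stats::runif(n_waters, 0, l)
    incr <- matrix(stats::rnorm(n_waters * (n_frames - 1), sd = step_sd),
                   nrow = n_waters)
    z <- cbind(z0, z0 + t(apply(incr, 1, cumsum))) %% l
    th <- stats::runif(n_waters, 0, 2 * pi)
    r <- lateral_radius * sqrt(stats::runif(n_waters))
    arr <- array(0, dim = c(n_waters, 3, n_frames))
    arr[, 1, ] <- r * cos(th) + lateral_radius
    arr[, 2, ] <- r * sin(th) + lateral_radius
    arr[, 3, ] <- z
    arr
  })
  trajectory(coords, dt = dt,
             groups = list(waters = seq_len(n_waters)),
             box = c(2 * lateral_radius, 2 * lateral_radius, l),
             truth = list(axial_D = axial_D, channel_length = l, seed = seed))
}

#' Simulate a rigidly tilting channel ring
#'
#' A rigid ring of `n_ring` points (radius 1 nm) whose plane normal makes an
#' angle `true_angle + wobble * eps_t` with the membrane normal z, with a
#' fresh uniform azimuth each frame. Used to exercise the plane-fit tilt
#' estimator.
#'
#' @param true_angle_deg Mean tilt, degrees in \[0, 90\].
#' @param wobble_deg Gaussian s.d. of the per-frame tilt, degrees.
#' @param n_frames Number of frames.
#' @param n_ring Ring size (>= 10 for a well-conditioned plane fit).
#' @param dt Frame spacing, ns (metadata).
#' @param seed Integer seed (required).
#' @return A `trajectory` with group `ring`; `truth` holds the angles.
#' @export
gen_tilt_trajectory <- function(true_angle_deg, wobble_deg = 5,
                                n_frames = 2000, n_ring = 12, dt = 0.02,
                                seed) {
  seed <- .require_seed(seed)
  .assert_scalar(true_angle_deg, "true_angle_deg", nonneg = TRUE)
  if (true_angle_deg > 90)
    stop("`true_angle_deg` must lie in [0, 90]", call. = FALSE)
  .assert_scalar(wobble_deg, "wobble_deg", nonneg = TRUE)
  phi <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  ring <- cbind(cos(phi), sin(phi), 0)         # unit ring in the xy plane
  coords <- withr::with_seed(seed, {
    ang <- true_angle_deg + stats::rnorm(n_frames, sd = wobble_deg)
    az <- stats::runif(n_frames, 0, 2 * pi)
    arr <- array(0, dim = c(n_ring, 3, n_frames))
    for (f in seq_len(n_frames)) {
      th <- ang[f] * pi / 180
      # rotate about the in-plane axis (cos az, sin az, 0) by th
      u <- c(cos(az[f]), sin(az[f]), 0)
      ct <- cos(th); st <- sin(th)
      ux <- u[1]; uy <- u[2]
      rot <- matrix(c(
        ct + ux^2 * (1 - ct), ux * uy * (1 - ct),      uy * st,
        ux * uy * (1 - ct),   ct + uy^2 * (1 - ct),   -ux * st,
        -uy * st,             ux * st,                 ct), 3, 3,
        byrow = TRUE)
      arr[, , f] <- ring %*% t(rot)
    }
    arr
  })
  trajectory(coords, dt = dt, groups = list(ring = seq_len(n_ring)),
             box = NULL,
             truth = list(true_angle_deg = true_angle_deg,
                          wobble_deg = wobble_deg, seed = seed))
}

.gaussian_barrier <- function(height, center, width) {
  force(height); force(center); force(width)
  list(
    u = function(z) height * exp(-(z - center)^2 / (2 * width^2)),
    du = function(z) -height * (z - center) / width^2 *
      exp(-(z - center)^2 / (2 * width^2))
  )
}

#' Simulate constant-velocity pulling force traces over a Gaussian barrier
#'
#' An overdamped (Brownian) particle at position z is dragged by a moving
#' harmonic restraint `z_r(t) = z_start + v t` across a Gaussian free-energy
#' barrier `U(z) = H exp(-(z - z0)^2 / 2 w^2)`. Euler-Maruyama integration
#' of `gamma dz = [-U'(z) + k_s (z_r - z)] dt + sqrt(2 gamma kT dt) xi`.
#' The recorded force is `F = k_s (z_r - z)`, block-averaged onto `n_out`
#' points along the restraint coordinate (instantaneous forces at a stiff
#' spring are dominated by thermal chatter; block means are what the
#' average-then-integrate estimator consumes). The friction-work bias of
#' that estimator is `gamma * v` per unit distance and is part of the
#' recorded truth.
#'
#' @param barrier_height H, kcal mol^-1 (>= 0).
#' @param barrier_center,barrier_width z0 and w, Angstrom.
#' @param z_start,z_end Pulling window, Angstrom.
#' @param spring_k Restraint stiffness k_s, kcal mol^-1 A^-2.
#' @param velocity Pulling speed v, A ns^-1.
#' @param friction gamma, kcal mol^-1 ns A^-2.
#' @param kT Thermal energy, kcal mol^-1 (0.602 at 303 K).
#' @param n_replicates Number of independent pulls.
#' @param dt Integration step, ns; must satisfy `k_s dt / gamma <= 0.1`.
#' @param n_out Output points per trace.
#' @param seed Integer seed (required).
#' @return List of `force_trace` objects (data: z_angstrom,
#'   force_kcal_mol_A) with shared `truth` attached as an attribute.
#' @export
gen_smd_traces <- function(barrier_height = 50, barrier_center = 0,
                           barrier_width = 2, z_start = -6, z_end = 6,
                           spring_k = 1000, velocity = 10, friction = 0.05,
                           kT = 0.602, n_replicates = 10, dt = 5e-6,
                           n_out = 400, seed) {
  seed <- .require_seed(seed)
  .assert_scalar(barrier_height, "barrier_height", nonneg = TRUE)
  .assert_scalar(spring_k, "spring_k", positive = TRUE)
  .assert_scalar(velocity, "velocity", positive = TRUE)
  .assert_scalar(friction, "friction", positive = TRUE)
  .assert_scalar(dt, "dt", positive = TRUE)
  if (spring_k * dt / friction > 0.1)
    stop("dt too large for the restraint stiffness: require ",
         "spring_k * dt / friction <= 0.1", call. = FALSE)
  pot <- .gaussian_barrier(barrier_height, barrier_center, barrier_width)
  total_t <- (z_end - z_start) / velocity
  n_steps <- floor(total_t / dt / n_out) * n_out
  stride <- n_steps %/% n_out
  noise_sd <- sqrt(2 * kT * dt / friction)
  traces <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep) {
      z <- z_start
      fsum <- numeric(n_out)
      zrsum <- numeric(n_out)
      xi <- stats::rnorm(n_steps, sd = noise_sd)
      inv_g <- dt / friction
      for (i in seq_len(n_steps)) {
        zr <- z_start + velocity * (i - 1) * dt
        f <- spring_k * (zr - z)
        blk <- ((i - 1) %/% stride) + 1
        fsum[blk] <- fsum[blk] + f
        zrsum[blk] <- zrsum[blk] + zr
        z <- z + inv_g * (f - pot$du(z)) + xi[i]
      }
      structure(list(
        data = data.frame(z_angstrom = zrsum / stride,
                          force_kcal_mol_A = fsum / stride),
        velocity = velocity, spring_k = spring_k, replicate = rep
      ), class = "force_trace")
    })
  })
  attr(traces, "truth") <- list(
    barrier_height = barrier_height, barrier_center = barrier_center,
    barrier_width = barrier_width, friction = friction, velocity = velocity,
    kT = kT, drag_force = friction * velocity, potential = pot$u,
    seed = seed)
  traces
}

#' Simulate a dye rejection dataset under concentration polarization
#'
#' True rejection follows a logistic curve in molecular weight,
#' `R_t(M) = R_max / (1 + exp(-(M - mu)/s))`, with `mu` placed so the
#' 90%-rejection crossing sits at `true_mwco`. The observed rejection is
#' derived by the stagnant-film forward model
#' `R_o = 1 / (1 + ((1 - R_t)/R_t) exp(J_v/k_mt))`, then additive Gaussian
#' noise truncated to \[0, 1\] is applied. [polarization_correct()] inverts
#' the forward model exactly when noiseless.
#'
#' @param true_mwco MWCO (90% crossing), Da.
#' @param spread_s Logistic scale s, Da; the pore-size s.d. is `pi s/sqrt(3)`.
#' @param rmax Rejection plateau, in (0.9, 1\].
#' @param jv Permeate flux, LMH.
#' @param k_mt Mass-transfer coefficient, LMH.
#' @param mw_grid Solute molecular weights, Da.
#' @param noise Additive noise s.d. on the observed rejection.
#' @param c_feed Feed concentration (a.u.) used to materialise permeate
#'   concentrations.
#' @param seed Integer seed (required).
#' @return A `rejection_dataset`: `records` data.frame (solute, mw_da,
#'   c_feed, c_permeate, jv_LMH, k_mt_LMH) and `truth`.
#' @export
gen_rejection_dataset <- function(true_mwco = 450, spread_s = 72, rmax = 1,
                                  jv = 30, k_mt = 30,
                                  mw_grid = seq(300, 1100, by = 25),
                                  noise = 0.01, c_feed = 35, seed) {
  seed <- .require_seed(seed)
  .assert_scalar(true_mwco, "true_mwco", positive = TRUE)
  .assert_scalar(spread_s, "spread_s", positive = TRUE)
  .assert_scalar(rmax, "rmax", positive = TRUE)
  if (rmax <= 0.9 || rmax > 1)
    stop("`rmax` must lie in (0.9, 1] so the 90% crossing exists",
         call. = FALSE)
  .assert_scalar(jv, "jv", nonneg = TRUE)
  .assert_scalar(k_mt, "k_mt", positive = TRUE)
  if (jv / k_mt > 10)
    warning("jv/k_mt > 10: extreme concentration polarization", call. = FALSE)
  mu <- true_mwco + spread_s * log(rmax / 0.9 - 1)
  r_t <- rmax / (1 + exp(-(mw_grid - mu) / spread_s))
  r_o <- 1 / (1 + (1 - r_t) / r_t * exp(jv / k_mt))
  r_obs <- withr::with_seed(seed, {
    pmin(1, pmax(0, r_o + stats::rnorm(length(r_o), sd = noise)))
  })
  structure(list(
    records = data.frame(
      solute = sprintf("dye_%04d", round(mw_grid)),
      mw_da = mw_grid, c_feed = c_feed,
      c_permeate = c_feed * (1 - r_obs),
      jv_LMH = jv, k_mt_LMH = k_mt),
    truth = list(true_mwco = true_mwco, spread_s = spread_s, mu = mu,
                 rmax = rmax, sigma = pi * spread_s / sqrt(3),
                 jv = jv, k_mt = k_mt, r_true = r_t, r_obs_noiseless = r_o,
                 noise = noise, seed = seed)
  ), class = "rejection_dataset")
}

#' Simulate a two-component FRAP recovery trace
#'
#' `F(t) = f1 (1 - exp(-t/tau1)) + f2 (1 - exp(-t/tau2)) + eps`, with the
#' immobile fraction `1 - f1 - f2`. The trace is normalised to pre-bleach 1
#' and post-bleach 0 at t = 0.
#'
#' @param frac_fast,frac_slow Mobile fractions (on the simplex with the
#'   implied immobile remainder).
#' @param tau_fast,tau_slow Recovery times, s.
#' @param duration Trace length, s; default `5 * tau_slow`.
#' @param n_points Samples.
#' @param noise Additive Gaussian noise s.d.
#' @param seed Integer seed (required).
#' @return A `frap_trace`: `data` (time_s, F_norm) and `truth`.
#' @export
gen_frap_trace <- function(frac_fast, tau_fast, frac_slow, tau_slow,
                           duration = NULL, n_points = 300, noise = 0.01,
                           seed) {
  seed <- .require_seed(seed)
  .assert_scalar(frac_fast, "frac_fast", nonneg = TRUE)
  .assert_scalar(frac_slow, "frac_slow", nonneg = TRUE)
  if (frac_fast + frac_slow > 1 + 1e-12)
    stop("mobile fractions must satisfy frac_fast + frac_slow <= 1",
         call. = FALSE)
  .assert_scalar(tau_fast, "tau_fast", positive = TRUE)
  .assert_scalar(tau_slow, "tau_slow", positive = TRUE)
  if (is.null(duration)) duration <- 5 * tau_slow
  tt <- seq(0, duration, length.out = n_points)
  f <- frac_fast * (1 - exp(-tt / tau_fast)) +
    frac_slow * (1 - exp(-tt / tau_slow))
  fobs <- withr::with_seed(seed, f + stats::rnorm(n_points, sd = noise))
  structure(list(
    data = data.frame(time_s = tt, F_norm = fobs),
    truth = list(frac_fast = frac_fast, tau_fast = tau_fast,
                 frac_slow = frac_slow, tau_slow = tau_slow,
                 frac_immobile = 1 - frac_fast - frac_slow,
                 noise = noise, seed = seed)
  ), class = "frap_trace")
}

#' Simulate a flux-pressure series for hydraulic permeability
#'
#' `J = Lp * P + eps` with `eps` Gaussian of s.d. `noise * Lp * P`
#' (relative error, as flux meters behave).
#'
#' @param lp_true True hydraulic permeability, LMH bar^-1.
#' @param pressures_bar Applied pressures, bar. The conventional test
#'   pressures 50/60/70 psi convert via 0.0689476 bar/psi.
#' @param noise Relative noise s.d.
#' @param seed Integer seed (required).
#' @return A `flux_pressure_series`: `data` (pressure_bar, flux_LMH), `truth`.
#' @export
gen_flux_pressure <- function(lp_true,
                              pressures_bar = c(50, 60, 70) *
                                channel_constants()$psi_to_bar,
                              noise = 0.02, seed) {
  seed <- .require_seed(seed)
  .assert_scalar(lp_true, "lp_true", positive = TRUE)
  if (any(pressures_bar <= 0)) stop("pressures must be > 0", call. = FALSE)
  j <- lp_true * pressures_bar
  jobs <- withr::with_seed(seed,
    j * (1 + stats::rnorm(length(j), sd = noise)))
  structure(list(
    data = data.frame(pressure_bar = pressures_bar, flux_LMH = jobs),
    truth = list(lp_true = lp_true, noise = noise, seed = seed)
  ), class = "flux_pressure_series")
}
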