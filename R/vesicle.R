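# Stopped-flow swelling kinetics -> net and single-channel permeability.
# This is the core experimental inference chain: fit the exponential decay
# rate, convert to an osmotic permeability through vesicle geometry,
# subtract the channel-free background, and divide the membrane flow among
# the FCS-counted channels.

#' Vesicle specification for the osmotic permeability conversion
#'
#' @param radius_nm Hydrodynamic radius (DLS), nm.
#' @param delta_osm Osmotic gradient, mOsm (numerically osmol m^-3).
#' @param temperature Assay temperature, K.
#' @param molar_ratio Channel-to-amphiphile molar ratio (mCPR/mCLR),
#'   optional metadata.
#' @return Object of class `vesicle_spec`.
#' @export
vesicle_spec <- function(radius_nm, delta_osm, temperature = 283.15,
                         molar_ratio = NA_real_) {
  .assert_scalar(radius_nm, "radius_nm", positive = TRUE)
  .assert_scalar(delta_osm, "delta_osm", positive = TRUE)
  .assert_scalar(temperature, "temperature", positive = TRUE)
  structure(list(radius_nm = radius_nm, delta_osm = delta_osm,
                 temperature = temperature, molar_ratio = molar_ratio),
            class = "vesicle_spec")
}

.validate_trace_df <- function(df, time_col, value_col) {
  if (!all(c(time_col, value_col) %in% names(df)))
    stop(sprintf("trace must have columns `%s` and `%s`", time_col,
                 value_col), call. = FALSE)
  if (nrow(df) < 20)
    stop("trace must have at least 20 points", call. = FALSE)
  if (any(diff(df[[time_col]]) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(df[[value_col]])))
    stop("trace values must be finite", call. = FALSE)
  invisible(df)
}

#' Fit the swelling rate of a stopped-flow scattering trace
#'
#' Least-squares fit of `I(t) = baseline + sum_i A_i exp(-k_i t)`. The
#' default is a single exponential; a two-exponential variant is available
#' for traces with fast mixing artifacts, in which case the rate of the
#' dominant (largest-amplitude) component is reported. The initializer is
#' deterministic: baseline from the mean of the final 5% of points, then a
#' log-linear regression on the baseline-subtracted first half of the decay.
#'
#' @param trace A [gen_scattering_trace()] object or a data.frame with
#'   columns `time_s`, `intensity`.
#' @param n_exponentials 1 (default) or 2.
#' @return A `rate_fit`: `k` (s^-1, dominant), `k_se`, `amplitude`,
#'   `baseline`, `rmse`, `n_exponentials`, and the underlying `fit`.
#' @export
fit_swelling_rate <- function(trace, n_exponentials = 1) {
  df <- if (inherits(trace, "scattering_trace")) trace$data else trace
  .validate_trace_df(df, "time_s", "intensity")
  if (!n_exponentials %in% c(1, 2))
    stop("`n_exponentials` must be 1 or 2", call. = FALSE)
  tt <- df$time_s; ii <- df$intensity
  rng <- diff(range(ii))
  if (rng < 1e-10 * max(abs(ii), 1))
    stop("constant trace: no decay to fit", call. = FALSE)
  # smoothed trend check: a swelling trace decays
  sm <- stats::lowess(tt, ii, f = 0.3)$y
  if (sm[length(sm)] > sm[1] + 0.25 * rng)
    stop("intensity increases over the trace: not a swelling trace",
         call. = FALSE)
  n_tail <- max(3L, ceiling(0.05 * length(ii)))
  b0 <- mean(utils::tail(ii, n_tail))
  y <- ii - b0
  first_half <- seq_len(floor(length(tt) / 2))
  pos <- first_half[y[first_half] > 0]
  if (length(pos) < 5)
    stop("cannot initialize: too few points above baseline", call. = FALSE)
  lin <- stats::lm(log(y[pos]) ~ tt[pos])
  k0 <- max(1e-8, -unname(stats::coef(lin)[2]))
  a0 <- exp(unname(stats::coef(lin)[1]))
  fit <- tryCatch({
    if (n_exponentials == 1) {
      minpack.lm::nlsLM(
        ii ~ b + a * exp(-k * tt),
        start = list(b = b0, a = a0, k = k0),
        lower = c(b = -Inf, a = 0, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        ii ~ b + a1 * exp(-k1 * tt) + a2 * exp(-k2 * tt),
        start = list(b = b0, a1 = a0 * 0.8, k1 = k0,
                     a2 = a0 * 0.2, k2 = 5 * k0),
        lower = c(b = -Inf, a1 = 0, k1 = 0, a2 = 0, k2 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 400))
    }
  }, error = function(e)
    stop("swelling fit did not converge: ", conditionMessage(e),
         call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (n_exponentials == 1) {
    k <- unname(cf["k"]); k_se <- unname(se["k"])
    amp <- unname(cf["a"])
  } else {
    dom <- if (cf["a1"] >= cf["a2"]) c("a1", "k1") else c("a2", "k2")
    k <- unname(cf[dom[2]]); k_se <- unname(se[dom[2]])
    amp <- unname(cf[dom[1]])
  }
  structure(list(k = k, k_se = k_se, amplitude = amp,
                 baseline = unname(cf["b"]),
                 rmse = sqrt(mean(stats::resid(fit)^2)),
                 n_exponentials = n_exponentials, fit = fit),
            class = "rate_fit")
}

#' Convert a swelling rate to an osmotic permeability
#'
#' `Pf = k * r / (3 V_w dC)`: the exponential swelling rate of a spherical
#' vesicle (surface-to-volume ratio 3/r) under a gradient dC. The inverse
#' operation is [permeability_to_rate()].
#'
#' @param k Swelling rate, s^-1 (>= 0).
#' @param spec A [vesicle_spec()].
#' @param k_sd Optional s.d. of `k` for first-order propagation.
#' @return List: `pf_um_s`, `sd` (NA without `k_sd`).
#' @export
rate_to_permeability <- function(k, spec, k_sd = NULL) {
  .assert_scalar(k, "k", nonneg = TRUE)
  stopifnot(inherits(spec, "vesicle_spec"))
  kc <- channel_constants()
  scale <- (spec$radius_nm * 1e-9) /
    (3 * kc$molar_volume_water * spec$delta_osm) * 1e6  # m/s -> um/s
  list(pf_um_s = k * scale,
       sd = if (is.null(k_sd)) NA_real_ else k_sd * scale)
}

#' @rdname rate_to_permeability
#' @param pf_um_s Osmotic permeability, um/s.
#' @export
permeability_to_rate <- function(pf_um_s, spec) {
  .assert_scalar(pf_um_s, "pf_um_s", nonneg = TRUE)
  stopifnot(inherits(spec, "vesicle_spec"))
  kc <- channel_constants()
  (pf_um_s * 1e-6) * (3 / (spec$radius_nm * 1e-9)) *
    kc$molar_volume_water * spec$delta_osm
}

#' Background-subtracted net permeability
#'
#' Channel-attributable permeability is the sample minus the channel-free
#' control. Negative differences are returned as-is with a
#' `below_background` flag rather than clamped.
#'
#' @param pf_sample,pf_control Permeabilities, um/s (>= 0).
#' @param sd_sample,sd_control Optional s.d. values for propagation.
#' @return List: `pf_net_um_s`, `sd`, `below_background`.
#' @export
net_permeability <- function(pf_sample, pf_control,
                             sd_sample = NULL, sd_control = NULL) {
  .assert_scalar(pf_sample, "pf_sample", nonneg = TRUE)
  .assert_scalar(pf_control, "pf_control", nonneg = TRUE)
  net <- pf_sample - pf_control
  sd <- if (is.null(sd_sample) && is.null(sd_control)) NA_real_ else
    sqrt(sum(c(sd_sample, 0)^2) + sum(c(sd_control, 0)^2))
  list(pf_net_um_s = net, sd = sd, below_background = net < 0)
}

#' Single-channel water permeability from net permeability and channel count
#'
#' The total water flow through a vesicle of diameter d is the net
#' permeation velocity times its surface area; dividing by the number of
#' channels gives the per-channel volumetric flow
#' `pf_single = Pf_net * pi d^2 / N`, also reported as molecules/s.
#' Uncertainty is first-order (delta-method) propagation over the supplied
#' s.d. values.
#'
#' @param pf_net_um_s Net osmotic permeability, um/s (>= 0).
#' @param vesicle_diameter_nm Vesicle diameter, nm (> 0).
#' @param n_channels Channels per vesicle (> 0).
#' @param pf_sd,n_sd Optional s.d. of net permeability and channel count.
#' @return A `single_channel_result`: `pf_single_vol_cm3_s`,
#'   `pf_single_mol_s`, `sd_vol_cm3_s`, `sd_mol_s`, `n_channels`.
#' @export
single_channel_permeability <- function(pf_net_um_s, vesicle_diameter_nm,
                                        n_channels, pf_sd = NULL,
                                        n_sd = NULL) {
  .assert_scalar(pf_net_um_s, "pf_net_um_s", nonneg = TRUE)
  .assert_scalar(vesicle_diameter_nm, "vesicle_diameter_nm", positive = TRUE)
  if (!is.numeric(n_channels) || n_channels <= 0)
    stop("`n_channels` must be > 0", call. = FALSE)
  area_m2 <- pi * (vesicle_diameter_nm * 1e-9)^2
  vol_m3_s <- (pf_net_um_s * 1e-6) * area_m2 / n_channels
  pf_vol <- vol_m3_s * 1e6                     # -> cm^3/s
  rel2 <- 0
  if (!is.null(pf_sd) && pf_net_um_s > 0) rel2 <- rel2 +
      (pf_sd / pf_net_um_s)^2
  if (!is.null(n_sd)) rel2 <- rel2 + (n_sd / n_channels)^2
  sd_vol <- if (rel2 > 0) pf_vol * sqrt(rel2) else NA_real_
  structure(list(
    pf_single_vol_cm3_s = pf_vol,
    pf_single_mol_s = volumetric_to_molecular(pf_vol),
    sd_vol_cm3_s = sd_vol,
    sd_mol_s = if (is.na(sd_vol)) NA_real_ else
      volumetric_to_molecular(sd_vol),
    n_channels = n_channels
  ), class = "single_channel_result")
}

#' Channel insertion efficiency
#'
#' Measured channels per vesicle divided by the theoretical count if every
#' channel in the reconstitution mixture inserted. The theoretical count is
#' `molar_ratio * n_amphiphiles` with the amphiphile number from both
#' bilayer leaflets: `n = 2 A / a_amph` in the simple variant
#' (`channel_area_nm2 = 0`, the default), or self-consistently
#' `n = (2 A / a_amph) / (1 + 2 mr a_ch / a_amph)` when the area displaced
#' by inserted channels is accounted for.
#'
#' @param n_measured Channels per vesicle from FCS (>= 0).
#' @param molar_ratio Channel-to-amphiphile molar ratio (< 1).
#' @param vesicle_diameter_nm Vesicle diameter, nm.
#' @param area_per_amphiphile_nm2 Area per lipid/polymer at the midplane,
#'   nm^2.
#' @param channel_area_nm2 Channel cross-section, nm^2; 0 selects the simple
#'   variant.
#' @return List: `efficiency_pct`, `n_theoretical`, `n_amphiphiles`.
#' @export
insertion_efficiency <- function(n_measured, molar_ratio,
                                 vesicle_diameter_nm,
                                 area_per_amphiphile_nm2,
                                 channel_area_nm2 = 0) {
  .assert_scalar(n_measured, "n_measured", nonneg = TRUE)
  .assert_scalar(molar_ratio, "molar_ratio", positive = TRUE)
  if (molar_ratio >= 1) stop("`molar_ratio` must be < 1", call. = FALSE)
  .assert_scalar(vesicle_diameter_nm, "vesicle_diameter_nm", positive = TRUE)
  .assert_scalar(area_per_amphiphile_nm2, "area_per_amphiphile_nm2",
                 positive = TRUE)
  .assert_scalar(channel_area_nm2, "channel_area_nm2", nonneg = TRUE)
  a_mid <- 4 * pi * (vesicle_diameter_nm / 2)^2          # nm^2
  n_amph <- (2 * a_mid / area_per_amphiphile_nm2) /
    (1 + 2 * molar_ratio * channel_area_nm2 / area_per_amphiphile_nm2)
  n_theor <- molar_ratio * n_amph
  eff <- n_measured / n_theor * 100
  if (eff > 150)
    stop(sprintf("efficiency %.0f%% > 150%%: inputs are inconsistent", eff),
         call. = FALSE)
  list(efficiency_pct = eff, n_theoretical = n_theor, n_amphiphiles = n_amph)
}
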