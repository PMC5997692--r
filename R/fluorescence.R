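# FCS two-species autocorrelation fitting and channels-per-vesicle
# counting; FRAP two-component recovery analysis.

#' Two-species 3D-diffusion FCS autocorrelation model
#'
#' Standard 3D Gaussian focal volume, two freely diffusing species:
#' `G(tau) = (1/N) sum_i f_i (1 + tau/tau_i)^-1 (1 + tau/(S^2 tau_i))^-1/2`
#' with `f_fast + f_slow = 1`. The amplitude identity `N G(0) = 1` holds for
#' any parameter set. Triplet/blinking terms are omitted.
#'
#' @param lag Lag times, s (vectorised).
#' @param n_particles Mean particle number N in the focal volume.
#' @param fraction_slow Fraction of the slow species (fast = 1 - slow).
#' @param tau_fast,tau_slow Diffusion times, s.
#' @param structure_param Axial/lateral focal volume ratio S.
#' @return G values.
#' @export
fcs_model <- function(lag, n_particles, fraction_slow, tau_fast, tau_slow,
                      structure_param = 5) {
  f2 <- fraction_slow; f1 <- 1 - f2
  s2 <- structure_param^2
  comp <- function(f, tau)
    f / (1 + lag / tau) / sqrt(1 + lag / (s2 * tau))
  (comp(f1, tau_fast) + comp(f2, tau_slow)) / n_particles
}

#' Fit the two-species FCS model to an autocorrelation curve
#'
#' Weighted least squares with weights `1/G^2` (multiplicative detector
#' noise), lags below `min_lag` excluded (detector afterpulsing region).
#' The structure parameter is held fixed: floating it alongside two species
#' is ill-conditioned. Species are ordered so `tau_fast < tau_slow` on
#' return; parameters that finish at a bound are flagged.
#'
#' @param curve A [gen_fcs_curve()] object or data.frame with `lag_s`, `G`.
#' @param init Optional named list overriding the deterministic initializer
#'   (`n_particles`, `fraction_slow`, `tau_fast`, `tau_slow`).
#' @param structure_param Fixed S (default 5).
#' @param min_lag Smallest lag used, s (default 1e-5, i.e. 10 us).
#' @return An `fcs_fit`: `n_particles`, `fraction_fast`, `fraction_slow`,
#'   `tau_fast`, `tau_slow`, `structure_param`, `rmse`, `se` (named),
#'   `at_bounds`.
#' @export
fit_fcs <- function(curve, init = NULL, structure_param = 5, min_lag = 1e-5) {
  df <- if (inherits(curve, "correlation_curve")) curve$data else curve
  if (!all(c("lag_s", "G") %in% names(df)))
    stop("curve must have columns `lag_s` and `G`", call. = FALSE)
  if (any(df$lag_s <= 0)) stop("lags must be > 0", call. = FALSE)
  if (any(!is.finite(df$G))) stop("G must be finite", call. = FALSE)
  df <- df[df$lag_s >= min_lag, , drop = FALSE]
  if (nrow(df) < 8)
    stop("fewer than 8 usable lags after the min_lag cut", call. = FALSE)
  if (df$G[which.min(df$lag_s)] <= 0)
    stop("non-positive short-lag amplitude: invalid correlation curve",
         call. = FALSE)
  lag <- df$lag_s; g <- df$G
  n0 <- 1 / g[which.min(lag)]
  # lag at half the zero-lag amplitude seeds the two diffusion times
  half_idx <- which.min(abs(g - 0.5 / n0))
  tau_half <- lag[half_idx]
  start <- list(n_particles = n0, fraction_slow = 0.5,
                tau_fast = tau_half / 5, tau_slow = tau_half * 5)
  if (!is.null(init)) start[names(init)] <- init
  w <- 1 / pmax(g, 1e-3 / n0)^2
  fit <- tryCatch(minpack.lm::nlsLM(
    g ~ fcs_model(lag, n_particles, fraction_slow, tau_fast, tau_slow,
                  structure_param),
    start = start, weights = w,
    lower = c(n_particles = 1e-8, fraction_slow = 0, tau_fast = 1e-9,
              tau_slow = 1e-9),
    upper = c(n_particles = Inf, fraction_slow = 1, tau_fast = Inf,
              tau_slow = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e)
      stop("FCS fit did not converge: ", conditionMessage(e), call. = FALSE))
  cf <- as.list(stats::coef(fit))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  if (cf$tau_fast > cf$tau_slow) {            # reorder species
    cf[c("tau_fast", "tau_slow")] <- cf[c("tau_slow", "tau_fast")]
    cf$fraction_slow <- 1 - cf$fraction_slow
  }
  at_bounds <- cf$fraction_slow %in% c(0, 1)
  structure(list(
    n_particles = cf$n_particles,
    fraction_fast = 1 - cf$fraction_slow,
    fraction_slow = cf$fraction_slow,
    tau_fast = cf$tau_fast, tau_slow = cf$tau_slow,
    structure_param = structure_param,
    rmse = sqrt(mean(stats::resid(fit)^2)),
    se = se, at_bounds = at_bounds, fit = fit
  ), class = "fcs_fit")
}

#' Channels per vesicle from paired before/after FCS fits
#'
#' Vesicles are the slow species before detergent solubilization; labeled
#' channel micelles are the slow species after. The ratio
#' `N_micelles / N_vesicles` counts inserted channels per vesicle; the
#' micelle count is first reduced by the supplied free-dye fraction (the
#' fast component carries the residual free fluorophore). Both
#' fits must share the focal volume, in which case the calibration cancels
#' in the ratio.
#'
#' @param fit_before,fit_after [fit_fcs()] results before/after
#'   solubilization.
#' @param free_dye_fraction Fraction of the after-curve slow count that is
#'   free dye, in \[0, 1).
#' @return A `channel_count`: `n_vesicle`, `n_micelle`,
#'   `channels_per_vesicle`.
#' @export
channels_per_vesicle <- function(fit_before, fit_after,
                                 free_dye_fraction = 0) {
  stopifnot(inherits(fit_before, "fcs_fit"), inherits(fit_after, "fcs_fit"))
  if (free_dye_fraction < 0 || free_dye_fraction >= 1)
    stop("`free_dye_fraction` must lie in [0, 1)", call. = FALSE)
  n_ves <- fit_before$n_particles * fit_before$fraction_slow
  if (n_ves <= 0)
    stop("zero vesicle count in the before-solubilization fit",
         call. = FALSE)
  n_mic <- fit_after$n_particles * fit_after$fraction_slow *
    (1 - free_dye_fraction)
  structure(list(n_vesicle = n_ves, n_micelle = n_mic,
                 channels_per_vesicle = n_mic / n_ves),
            class = "channel_count")
}

#' Fit a two-component FRAP recovery
#'
#' `F(t) = f1 (1 - exp(-t/tau1)) + f2 (1 - exp(-t/tau2))`, immobile
#' fraction `1 - f1 - f2`. Components are ordered fast (small tau, large D)
#' first; diffusion coefficients via `D = w^2 / (4 tau)` for bleach-spot
#' radius w. The trace must be normalised to pre-bleach 1, post-bleach 0 at
#' t = 0. The two-exponential form approximates the exact spot-recovery
#' solution; it matches the two-regime reporting convention (one D per
#' regime).
#'
#' A single exponential is fitted alongside. When the second component does
#' not reduce the residual (under 2% relative improvement) or the two
#' recovery times land within 10% of each other, the split is degenerate:
#' the single-component result is returned with `frac_slow = 0` and
#' `single_component_preferred = TRUE`.
#'
#' @param trace A [gen_frap_trace()] object or data.frame with `time_s`,
#'   `F_norm`.
#' @param spot_radius_um Bleach spot radius w, um.
#' @return A `frap_fit`: `frac_fast`, `frac_slow`, `frac_immobile`,
#'   `tau_fast`, `tau_slow`, `D_fast_um2_s`, `D_slow_um2_s`,
#'   `spot_radius_um`, `rmse`, `single_component_preferred`.
#' @export
fit_frap <- function(trace, spot_radius_um) {
  df <- if (inherits(trace, "frap_trace")) trace$data else trace
  .validate_trace_df(df, "time_s", "F_norm")
  .assert_scalar(spot_radius_um, "spot_radius_um", positive = TRUE)
  tt <- df$time_s; ff <- df$F_norm
  plateau <- mean(utils::tail(ff, max(3L, ceiling(0.05 * length(ff)))))
  t_half <- tt[which.min(abs(ff - plateau / 2))]
  start <- list(f1 = plateau * 0.6, tau1 = max(t_half / 3, min(diff(tt))),
                f2 = plateau * 0.4, tau2 = t_half * 3)
  fit1 <- tryCatch(minpack.lm::nlsLM(
    ff ~ f1 * (1 - exp(-tt / tau1)),
    start = list(f1 = plateau, tau1 = max(t_half, min(diff(tt)))),
    lower = c(f1 = 0, tau1 = 1e-12), upper = c(f1 = 1, tau1 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  fit <- tryCatch(minpack.lm::nlsLM(
    ff ~ f1 * (1 - exp(-tt / tau1)) + f2 * (1 - exp(-tt / tau2)),
    start = start,
    lower = c(f1 = 0, tau1 = 1e-12, f2 = 0, tau2 = 1e-12),
    upper = c(f1 = 1, tau1 = Inf, f2 = 1, tau2 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e)
      stop("FRAP fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- as.list(stats::coef(fit))
  if (cf$tau1 > cf$tau2) cf <- list(f1 = cf$f2, tau1 = cf$tau2,
                                    f2 = cf$f1, tau2 = cf$tau1)
  single_pref <- abs(cf$tau1 - cf$tau2) <= 0.1 * max(cf$tau1, cf$tau2)
  if (!is.null(fit1)) {
    rmse1 <- sqrt(mean(stats::resid(fit1)^2))
    rmse2 <- sqrt(mean(stats::resid(fit)^2))
    if (single_pref || rmse2 > 0.98 * rmse1) {
      cf1 <- as.list(stats::coef(fit1))
      cf <- list(f1 = cf1$f1, tau1 = cf1$tau1, f2 = 0, tau2 = cf1$tau1)
      fit <- fit1
      single_pref <- TRUE
    }
  }
  w2 <- spot_radius_um^2
  structure(list(
    frac_fast = cf$f1, frac_slow = cf$f2,
    frac_immobile = max(0, 1 - cf$f1 - cf$f2),
    tau_fast = cf$tau1, tau_slow = cf$tau2,
    D_fast_um2_s = w2 / (4 * cf$tau1),
    D_slow_um2_s = w2 / (4 * cf$tau2),
    spot_radius_um = spot_radius_um,
    rmse = sqrt(mean(stats::resid(fit)^2)),
    single_component_preferred = single_pref, fit = fit
  ), class = "frap_fit")
}
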