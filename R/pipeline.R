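# End-to-end pipeline driver: executes selected analysis stages from a
# config, produces a unit-tagged report, and serializes it to JSON.

.q <- function(value, unit) list(value = unname(value), unit = unit)

#' Run the analysis pipeline from a configuration
#'
#' Executes the selected stages in dependency order and assembles a report
#' in which every numeric result carries a unit string. Stages:
#' \describe{
#'   \item{stopped_flow}{`trace` (CSV path, scattering schema), `radius_nm`,
#'     `delta_osm`, `temperature`, optional `pf_control_um_s`.}
#'   \item{fcs}{`before`, `after` (CSV paths, fcs schema), optional
#'     `free_dye_fraction`. Combined with a completed stopped_flow stage
#'     and `vesicle_diameter_nm`, yields the single-channel permeability.}
#'   \item{frap}{`trace` (CSV path, frap schema), `spot_radius_um`.}
#'   \item{flux}{`series` (CSV path, flux schema).}
#'   \item{mwco}{`records` (CSV path, rejection schema), optional
#'     `use_corrected`, `mwco_rejection`.}
#'   \item{pmf}{`traces` (character vector of CSV paths, smd schema),
#'     optional `grid_spacing`, `pass_threshold`, `block_threshold`.}
#' }
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Top level: `stages` (named list as above), optional
#'   `vesicle_diameter_nm`, `seed`.
#' @return An `analysis_report` list: one element per executed stage, each
#'   a list of `list(value, unit)` entries, plus `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  report <- list()

  if (!is.null(stages$stopped_flow)) {
    sf <- stages$stopped_flow
    df <- read_trace_csv(sf$trace, "scattering")
    spec <- vesicle_spec(sf$radius_nm, sf$delta_osm,
                         temperature = sf$temperature %||% 283.15)
    rf <- fit_swelling_rate(df, n_exponentials = sf$n_exponentials %||% 1)
    pf <- rate_to_permeability(rf$k, spec, k_sd = rf$k_se)
    res <- list(k = .q(rf$k, "s^-1"),
                pf = .q(pf$pf_um_s, "um s^-1"),
                pf_sd = .q(pf$sd, "um s^-1"))
    if (!is.null(sf$pf_control_um_s)) {
      net <- net_permeability(pf$pf_um_s, sf$pf_control_um_s,
                              sd_sample = pf$sd)
      res$pf_net <- .q(net$pf_net_um_s, "um s^-1")
      res$pf_net_LMH_bar <- .q(
        osmotic_to_hydraulic(max(0, net$pf_net_um_s), spec$temperature),
        "LMH bar^-1")
    }
    report$stopped_flow <- res
  }

  if (!is.null(stages$fcs)) {
    fc <- stages$fcs
    fit_b <- fit_fcs(read_trace_csv(fc$before, "fcs"))
    fit_a <- fit_fcs(read_trace_csv(fc$after, "fcs"))
    cnt <- channels_per_vesicle(fit_b, fit_a,
                                free_dye_fraction =
                                  fc$free_dye_fraction %||% 0)
    res <- list(
      n_vesicle = .q(cnt$n_vesicle, "count"),
      n_micelle = .q(cnt$n_micelle, "count"),
      channels_per_vesicle = .q(cnt$channels_per_vesicle, "count"))
    if (!is.null(report$stopped_flow$pf_net) &&
        !is.null(config$vesicle_diameter_nm)) {
      sc <- single_channel_permeability(
        max(0, report$stopped_flow$pf_net$value),
        config$vesicle_diameter_nm, cnt$channels_per_vesicle)
      res$pf_single_vol <- .q(sc$pf_single_vol_cm3_s, "cm^3 s^-1")
      res$pf_single_mol <- .q(sc$pf_single_mol_s, "molecules s^-1")
    }
    report$fcs <- res
  }

  if (!is.null(stages$frap)) {
    fr <- stages$frap
    ft <- fit_frap(read_trace_csv(fr$trace, "frap"), fr$spot_radius_um)
    report$frap <- list(
      frac_fast = .q(ft$frac_fast, "fraction"),
      frac_slow = .q(ft$frac_slow, "fraction"),
      frac_immobile = .q(ft$frac_immobile, "fraction"),
      D_fast = .q(ft$D_fast_um2_s, "um^2 s^-1"),
      D_slow = .q(ft$D_slow_um2_s, "um^2 s^-1"))
  }

  if (!is.null(stages$flux)) {
    fx <- stages$flux
    hp <- hydraulic_permeability(read_trace_csv(fx$series, "flux"))
    report$flux <- list(lp = .q(hp$lp_LMH_bar, "LMH bar^-1"),
                        lp_sd = .q(hp$sd, "LMH bar^-1"))
  }

  if (!is.null(stages$mwco)) {
    mw <- stages$mwco
    fit <- fit_mwco(read_trace_csv(mw$records, "rejection"),
                    use_corrected = mw$use_corrected %||% TRUE,
                    mwco_rejection = mw$mwco_rejection %||% 0.9)
    report$mwco <- list(
      mwco = .q(fit$mwco, "Da"),
      sigma = .q(fit$sigma, "Da"),
      sharpness = .q(fit$sharpness, "dimensionless"),
      r_max = .q(fit$r_max, "fraction"))
  }

  if (!is.null(stages$pmf)) {
    pm <- stages$pmf
    traces <- lapply(pm$traces, read_trace_csv, schema = "smd")
    prof <- average_forces(traces,
                           grid_spacing = pm$grid_spacing %||% 0.1)
    pmf <- integrate_pmf(prof)
    cls <- classify_translocation(
      pmf, pass_threshold = pm$pass_threshold %||% 100,
      block_threshold = pm$block_threshold %||% 1500)
    report$pmf <- list(
      barrier = .q(pmf$barrier_height, "kcal mol^-1"),
      n_replicates = .q(pmf$n_replicates, "count"),
      classification = cls)
  }

  report$provenance <- list(
    package = "channelflux",
    version = as.character(utils::packageVersion("channelflux")),
    seed = config$seed %||% NA)
  class(report) <- "analysis_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an analysis report to JSON
#'
#' @param report An [run_pipeline()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Check that every numeric report field carries a unit
#'
#' Used by the validation suite; walks the report and confirms each leaf
#' numeric result is a `list(value, unit)` pair with a non-empty unit
#' string.
#'
#' @param report An [run_pipeline()] result.
#' @return TRUE, or an error describing the offending field.
#' @export
validate_report_units <- function(report) {
  walk <- function(x, path) {
    if (is.list(x) && identical(sort(names(x)), c("unit", "value"))) {
      if (!is.character(x$unit) || !nzchar(x$unit))
        stop("field ", path, " lacks a unit string", call. = FALSE)
      return(invisible(NULL))
    }
    if (is.numeric(x) && length(x) == 1 &&
        !grepl("provenance|classification", path))
      stop("bare numeric field without unit at ", path, call. = FALSE)
    if (is.list(x))
      for (nm in names(x)) walk(x[[nm]], paste(path, nm, sep = "/"))
  }
  walk(unclass(report), "")
  TRUE
}
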