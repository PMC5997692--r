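# Constant-velocity pulling analysis: average force traces across
# replicates on a common reaction-coordinate grid, integrate to a potential
# of mean force, classify translocation barriers.

.trace_df <- function(x) {
  df <- if (inherits(x, "force_trace")) x$data else x
  if (!all(c("z_angstrom", "force_kcal_mol_A") %in% names(df)))
    stop("force trace needs columns `z_angstrom`, `force_kcal_mol_A`",
         call. = FALSE)
  if (any(diff(df$z_angstrom) <= 0))
    stop("reaction coordinate must be strictly monotone increasing",
         call. = FALSE)
  if (any(!is.finite(df$force_kcal_mol_A)))
    stop("forces must be finite", call. = FALSE)
  df
}

#' Average pulling force traces onto a common grid
#'
#' Each replicate trace is linearly resampled onto a regular grid covering
#' the intersection of all replicate coordinate ranges; the pointwise mean
#' and standard error of the mean are returned. This is the
#' average-then-integrate estimator's first half.
#'
#' @param traces List of force traces (or a single one), each with columns
#'   `z_angstrom`, `force_kcal_mol_A`.
#' @param grid_spacing Grid step, Angstrom (default 0.1).
#' @return A `mean_force_profile`: `z` (A), `mean_force` (kcal/mol/A),
#'   `sem`, `n_replicates`.
#' @export
average_forces <- function(traces, grid_spacing = 0.1) {
  if (inherits(traces, "force_trace")) traces <- list(traces)
  if (length(traces) < 1) stop("need at least one trace", call. = FALSE)
  dfs <- lapply(traces, .trace_df)
  lo <- max(vapply(dfs, function(d) min(d$z_angstrom), numeric(1)))
  hi <- min(vapply(dfs, function(d) max(d$z_angstrom), numeric(1)))
  if (hi <= lo)
    stop("replicate coordinate ranges do not overlap", call. = FALSE)
  grid <- seq(lo, hi, by = grid_spacing)
  fmat <- vapply(dfs, function(d)
    stats::approx(d$z_angstrom, d$force_kcal_mol_A, xout = grid)$y,
    numeric(length(grid)))
  fmat <- matrix(fmat, nrow = length(grid))
  m <- rowMeans(fmat)
  sem <- if (ncol(fmat) > 1)
    apply(fmat, 1, stats::sd) / sqrt(ncol(fmat)) else rep(NA_real_,
                                                          length(grid))
  structure(list(z = grid, mean_force = m, sem = sem,
                 n_replicates = length(traces)),
            class = "mean_force_profile")
}

#' Integrate a mean force profile into a potential of mean force
#'
#' Cumulative trapezoidal integration of the mean force along the pulling
#' coordinate, anchored at `G(z_start) = 0`. The barrier height is
#' `max G - G(z_start)`. Note the constant-velocity estimator carries a
#' friction-work bias of (friction x velocity) per unit distance, which
#' inflates barriers at fast pulling.
#'
#' @param profile An [average_forces()] result.
#' @return A `pmf_profile`: `z`, `G` (kcal/mol), `barrier_height`,
#'   `n_replicates`.
#' @export
integrate_pmf <- function(profile) {
  stopifnot(inherits(profile, "mean_force_profile"))
  g <- pracma::cumtrapz(profile$z, profile$mean_force)[, 1]
  structure(list(z = profile$z, G = g,
                 barrier_height = max(g) - g[1],
                 n_replicates = profile$n_replicates),
            class = "pmf_profile")
}

#' Classify translocation from a PMF barrier
#'
#' Solutes with a barrier below `pass_threshold` are classified permeant;
#' above `block_threshold`, excluded; in between, indeterminate. In the
#' reference dye pair, the small permeant dye shows barriers below
#' 100 kcal/mol while the rejected bulky dye exceeds 1500 kcal/mol.
#'
#' @param pmf A [integrate_pmf()] result (or a list with `barrier_height`).
#' @param pass_threshold,block_threshold kcal/mol, `pass < block`.
#' @return `"permeant"`, `"excluded"`, or `"indeterminate"`.
#' @export
classify_translocation <- function(pmf, pass_threshold = 100,
                                   block_threshold = 1500) {
  .assert_scalar(pass_threshold, "pass_threshold", positive = TRUE)
  .assert_scalar(block_threshold, "block_threshold", positive = TRUE)
  if (pass_threshold >= block_threshold)
    stop("`pass_threshold` must be below `block_threshold`", call. = FALSE)
  b <- pmf$barrier_height
  if (b < pass_threshold) "permeant"
  else if (b > block_threshold) "excluded"
  else "indeterminate"
}
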