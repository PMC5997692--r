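# Trajectory container and observables: blocked MSD / diffusivities,
# Kabsch-superposed RMSD, tilt angles, and the collective diffusion
# permeability for single-file water transport.

#' Frame-indexed trajectory of named atom groups
#'
#' The convention throughout is z = membrane normal. Coordinates are in nm,
#' time in ns.
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames`.
#' @param dt Frame spacing, ns.
#' @param groups Named list of atom index vectors (e.g. `channel_backbone`,
#'   `waters`, `membrane`).
#' @param box Optional length-3 box vector (nm), or `n_frames x 3` matrix.
#' @param truth Optional ground-truth metadata from a generator.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, dt, groups, box = NULL, truth = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("`coords` must be an n_atoms x 3 x n_frames array", call. = FALSE)
  if (any(!is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  .assert_scalar(dt, "dt", positive = TRUE)
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list of atom index vectors", call. = FALSE)
  n_atoms <- dim(coords)[1]
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (any(idx < 1 | idx > n_atoms))
      stop(sprintf("group '%s' references atoms outside 1..%d", g, n_atoms),
           call. = FALSE)
  }
  if (!is.null(box)) {
    if (is.matrix(box)) {
      if (ncol(box) != 3L || nrow(box) != dim(coords)[3])
        stop("`box` matrix must be n_frames x 3", call. = FALSE)
    } else if (length(box) != 3L) {
      stop("`box` must be length 3 or an n_frames x 3 matrix", call. = FALSE)
    }
  }
  structure(list(coords = coords, dt = dt, groups = groups, box = box,
                 truth = truth),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d atoms, %d frames, dt = %g ns\n",
              d[1], d[3], x$dt))
  cat("  groups:", paste(sprintf("%s (%d)", names(x$groups),
                                 lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

.n_frames <- function(traj) dim(traj$coords)[3]

.group_coords <- function(traj, group) {
  if (!group %in% names(traj$groups))
    stop(sprintf("no group '%s' in trajectory (have: %s)", group,
                 paste(names(traj$groups), collapse = ", ")), call. = FALSE)
  traj$coords[traj$groups[[group]], , , drop = FALSE]
}

.box_vec <- function(traj, frame = 1L) {
  if (is.null(traj$box)) return(NULL)
  if (is.matrix(traj$box)) traj$box[frame, ] else traj$box
}

#' Unwrap periodic coordinates along selected axes
#'
#' Reconstructs continuous coordinates by accumulating minimum-image
#' per-frame increments: any per-frame jump larger than half the box is
#' interpreted as a periodic wrap. Analysis operators refuse wrapped input
#' rather than guessing, so run this first on trajectories stored in a
#' periodic box.
#'
#' @param traj A [trajectory()].
#' @param axes Integer axes to unwrap (1 = x, 2 = y, 3 = z).
#' @return A `trajectory` with unwrapped coordinates (box retained).
#' @export
unwrap_trajectory <- function(traj, axes = 1:3) {
  stopifnot(inherits(traj, "trajectory"))
  box <- .box_vec(traj)
  if (is.null(box))
    stop("trajectory has no box; unwrapping is undefined", call. = FALSE)
  coords <- traj$coords
  nf <- dim(coords)[3]
  for (ax in axes) {
    l <- box[ax]
    x <- coords[, ax, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    d <- x[, -1, drop = FALSE] - x[, -nf, drop = FALSE]
    d <- d - l * round(d / l)                 # minimum-image increments
    coords[, ax, ] <- cbind(x[, 1], x[, 1] + t(apply(d, 1, cumsum)))
  }
  trajectory(coords, dt = traj$dt, groups = traj$groups, box = traj$box,
             truth = traj$truth)
}

.check_unwrapped <- function(x, box, axes) {
  # x: n_atoms x n_frames per-axis handled by caller; here full n x 3 x f
  if (is.null(box)) return(invisible(TRUE))
  nf <- dim(x)[3]
  if (nf < 2) return(invisible(TRUE))
  for (ax in axes) {
    xi <- matrix(x[, ax, ], nrow = dim(x)[1])
    d <- abs(xi[, -1, drop = FALSE] - xi[, -nf, drop = FALSE])
    if (any(d > box[ax] / 2))
      stop("per-frame jumps exceed box/2: coordinates look wrapped; ",
           "run unwrap_trajectory() first", call. = FALSE)
  }
  invisible(TRUE)
}

.dims_axes <- function(dims) {
  switch(dims, xyz = 1:3, xy = 1:2, z = 3L,
         stop("`dims` must be one of 'xyz', 'xy', 'z'", call. = FALSE))
}

.msd_one <- function(x, lags) {
  # x: n_frames x d matrix of positions; time-origin averaged MSD
  nf <- nrow(x)
  vapply(lags, function(l) {
    d <- x[(1 + l):nf, , drop = FALSE] - x[1:(nf - l), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
}

#' Blocked mean-squared displacement of an atom group
#'
#' The trajectory is divided into fragments of `fragment_length` ns, each
#' fragment's MSD is computed with full time-origin averaging, and the
#' fragment curves are averaged. Blocking caps the lag range at a scale where
#' the time-origin statistics are dense, the standard practice for membrane
#' diffusion estimates.
#'
#' @param traj A [trajectory()] with unwrapped coordinates.
#' @param group Group name.
#' @param dims `"xyz"` (overall), `"xy"` (lateral) or `"z"` (vertical).
#' @param fragment_length Fragment length in ns (default 20).
#' @return An `msd_curve`: `lag` (ns), `msd` (nm^2, with msd\[lag 0\] = 0),
#'   `dims`, `ndims`, `fragment_length`, `n_fragments`.
#' @export
msd <- function(traj, group, dims = "xyz", fragment_length = 20) {
  stopifnot(inherits(traj, "trajectory"))
  axes <- .dims_axes(dims)
  xg <- .group_coords(traj, group)
  .check_unwrapped(xg, .box_vec(traj), axes)
  nf <- dim(xg)[3]
  frag_frames <- max(2L, round(fragment_length / traj$dt))
  n_frag <- nf %/% frag_frames
  if (n_frag < 1)
    stop("trajectory shorter than one fragment; reduce fragment_length",
         call. = FALSE)
  lags <- seq_len(frag_frames - 1)
  acc <- matrix(0, nrow = length(lags), ncol = n_frag)
  n_atoms <- dim(xg)[1]
  for (f in seq_len(n_frag)) {
    fr <- ((f - 1) * frag_frames + 1):(f * frag_frames)
    per_atom <- matrix(0, nrow = length(lags), ncol = n_atoms)
    for (a in seq_len(n_atoms)) {
      x <- t(matrix(xg[a, axes, fr], nrow = length(axes)))
      per_atom[, a] <- .msd_one(x, lags)
    }
    acc[, f] <- rowMeans(per_atom)
  }
  structure(list(lag = c(0, lags * traj$dt),
                 msd = c(0, rowMeans(acc)),
                 dims = dims, ndims = length(axes),
                 fragment_length = frag_frames * traj$dt,
                 n_fragments = n_frag),
            class = "msd_curve")
}

#' Diffusion coefficient from an MSD curve (Einstein relation)
#'
#' Least-squares line over a window of lags; `D = slope / (2 * ndims)`.
#' The default window \[10%, 50%\] of the fragment avoids both the short-lag
#' regime and the statistics-poor tail.
#'
#' @param msd_curve An [msd()] result.
#' @param fit_window Length-2 fractions of the maximum lag.
#' @return List: `D` (nm^2/ns), `D_um2_s` (um^2/s), `slope`, `r_squared`,
#'   `reliable` (FALSE when r^2 < 0.9), `fit_window`.
#' @export
diffusivity <- function(msd_curve, fit_window = c(0.1, 0.5)) {
  stopifnot(inherits(msd_curve, "msd_curve"))
  lag <- msd_curve$lag
  lo <- fit_window[1] * max(lag); hi <- fit_window[2] * max(lag)
  sel <- lag >= lo & lag <= hi
  if (sum(sel) < 2)
    stop("fit window contains fewer than two lags", call. = FALSE)
  fit <- stats::lm(msd_curve$msd[sel] ~ lag[sel])
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  d <- max(0, slope / (2 * msd_curve$ndims))
  list(D = d, D_um2_s = d * 1e3,               # nm^2/ns -> um^2/s
       slope = slope, r_squared = r2,
       reliable = r2 >= 0.9, fit_window = fit_window)
}

.kabsch_rotation <- function(p, q) {
  # rotation m minimising ||p m - q|| for centred p, q (n x 3)
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Per-frame RMSD of a group with optional Kabsch superposition
#'
#' RMSD against a reference frame, after optimal rigid-body superposition
#' (translation + Kabsch rotation) when `superpose = TRUE`. With
#' superposition the series is invariant under rigid-body motion of the
#' whole group, so it isolates internal configurational change.
#'
#' @param traj A [trajectory()].
#' @param group Group name (>= 3 non-collinear atoms when superposing).
#' @param reference_frame Frame index used as reference (default 1).
#' @param superpose Apply Kabsch superposition first (default TRUE).
#' @return Numeric vector of per-frame RMSD values (nm).
#' @export
rmsd_series <- function(traj, group, reference_frame = 1, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  xg <- .group_coords(traj, group)
  n_atoms <- dim(xg)[1]
  nf <- dim(xg)[3]
  if (superpose && n_atoms < 3)
    stop("superposition needs >= 3 atoms", call. = FALSE)
  ref <- matrix(xg[, , reference_frame], ncol = 3)
  refc <- sweep(ref, 2, colMeans(ref))
  if (superpose) {
    sv <- svd(refc)$d
    if (sv[2] < 1e-10 * sv[1])
      stop("reference geometry is degenerate (collinear); cannot superpose",
           call. = FALSE)
  }
  vapply(seq_len(nf), function(f) {
    p <- matrix(xg[, , f], ncol = 3)
    if (superpose) {
      pc <- sweep(p, 2, colMeans(p))
      rot <- .kabsch_rotation(pc, refc)
      sqrt(mean(rowSums((pc %*% rot - refc)^2)))
    } else {
      sqrt(mean(rowSums((p - ref)^2)))
    }
  }, numeric(1))
}

#' Tilt angle of a channel ring relative to the membrane normal
#'
#' The channel axis is the normal of the best-fit plane through the ring
#' atoms (the smallest principal component), robust to ring puckering. The
#' angle against z is folded into \[0, 90\] degrees: 0 degrees means the
#' channel stands perpendicular to the membrane surface, 90 degrees lies
#' parallel to it.
#'
#' @param traj A [trajectory()].
#' @param ring_group Group name (>= 3 atoms).
#' @return A `tilt_series` list: `angle_deg` per frame, `mean`, `sd`,
#'   and `histogram` (a [hist()] object, not plotted).
#' @export
tilt_angle_series <- function(traj, ring_group) {
  stopifnot(inherits(traj, "trajectory"))
  xg <- .group_coords(traj, ring_group)
  if (dim(xg)[1] < 3)
    stop("ring group needs >= 3 atoms", call. = FALSE)
  nf <- dim(xg)[3]
  ang <- vapply(seq_len(nf), function(f) {
    p <- matrix(xg[, , f], ncol = 3)
    pc <- sweep(p, 2, colMeans(p))
    sv <- svd(pc)
    if (sv$d[2] < 1e-10 * sv$d[1])
      stop("degenerate ring geometry in frame ", f, call. = FALSE)
    axis <- sv$v[, 3]                         # smallest principal component
    acos(min(1, abs(axis[3]))) * 180 / pi
  }, numeric(1))
  # FD binning fails on (near-)constant series; fall back to Sturges
  h <- tryCatch(graphics::hist(ang, breaks = "FD", plot = FALSE),
                error = function(e)
                  graphics::hist(ang, breaks = "Sturges", plot = FALSE))
  structure(list(angle_deg = ang, mean = mean(ang), sd = stats::sd(ang),
                 histogram = h),
            class = "tilt_series")
}

#' Collective water-displacement coordinate of a channel
#'
#' For single-file transport, the dimensionless collective coordinate
#' accumulates `dn = sum_i dz_i / L` over waters inside the channel slab,
#' per frame pair. A water contributes only when it is inside the slab in
#' both frames of the pair (entry/exit partial displacements are excluded;
#' at fine sampling the omitted contribution is bounded by one step).
#' Per-frame displacements are taken minimum-image with period L, so the
#' wrapped storage convention of [gen_channel_water_trajectory()] is
#' handled; displacements must stay below L/2 per frame.
#'
#' @param traj A [trajectory()].
#' @param waters Group name of the water oxygens.
#' @param region List or vector with `z_lo`, `z_hi` (nm) defining the slab.
#' @return A `collective_series`: `time` (ns), `n` (dimensionless, n\[1\]=0),
#'   `L` (nm), `dt`.
#' @export
collective_coordinate <- function(traj, waters = "waters", region) {
  stopifnot(inherits(traj, "trajectory"))
  z_lo <- region[["z_lo"]]; z_hi <- region[["z_hi"]]
  if (is.null(z_lo) || is.null(z_hi) || z_hi <= z_lo)
    stop("`region` must provide z_lo < z_hi", call. = FALSE)
  l <- z_hi - z_lo
  xg <- .group_coords(traj, waters)
  z <- matrix(xg[, 3, ], nrow = dim(xg)[1])   # n_waters x n_frames
  nf <- ncol(z)
  inreg <- z >= z_lo & z <= z_hi
  dz <- z[, -1, drop = FALSE] - z[, -nf, drop = FALSE]
  dz <- dz - l * round(dz / l)                # minimum image with period L
  both <- inreg[, -nf, drop = FALSE] & inreg[, -1, drop = FALSE]
  # steps approaching the L/2 ambiguity bound mean wrap events cannot be
  # told apart from genuine displacements
  big <- abs(dz[both]) > l / 4
  if (length(big) && mean(big) > 0.01)
    stop("per-frame water displacements approach L/2: wrap events are ",
         "ambiguous; sample frames more finely", call. = FALSE)
  dn <- colSums(dz * both) / l
  structure(list(time = (seq_len(nf) - 1) * traj$dt,
                 n = c(0, cumsum(dn)), L = l, dt = traj$dt),
            class = "collective_series")
}

#' Single-channel permeability from the collective diffusion model
#'
#' The collective coordinate performs 1D diffusion with coefficient `D_n`;
#' its MSD obeys `<n^2(t)> = 2 D_n t`, and the osmotic single-channel
#' permeability is `pf = v_w * D_n` with `v_w` the molecular volume of
#' water. For N independent waters of axial diffusivity D in a channel of
#' length L the analytic value is `D_n = N D / L^2`.
#'
#' @param series A [collective_coordinate()] result.
#' @param v_w_cm3 Molecular volume of water, cm^3 (default the package
#'   constant).
#' @param max_lag_frames Number of lags used in the Einstein fit
#'   (default 20; short lags carry the densest statistics).
#' @return List: `D_n` (ns^-1), `pf_cm3_s`, `pf_molecules_s`, `r_squared`,
#'   `reliable`.
#' @export
collective_permeability <- function(series,
                                    v_w_cm3 =
                                      channel_constants()$molecular_volume_water,
                                    max_lag_frames = 20) {
  stopifnot(inherits(series, "collective_series"))
  n <- series$n
  nf <- length(n)
  lags <- seq_len(min(max_lag_frames, nf - 1))
  msd_n <- .msd_one(matrix(n, ncol = 1), lags)
  tt <- lags * series$dt
  fit <- stats::lm(msd_n ~ tt)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  d_n <- max(0, slope / 2)                    # ns^-1
  pf_cm3 <- v_w_cm3 * d_n * 1e9               # per ns -> per s
  list(D_n = d_n, pf_cm3_s = pf_cm3,
       pf_molecules_s = pf_cm3 / v_w_cm3,
       r_squared = r2, reliable = r2 >= 0.9)
}
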