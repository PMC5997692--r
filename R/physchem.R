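#' Physical constants used throughout the package
#'
#' Returns the CODATA constants and water properties that every conversion in
#' the package shares. All internal computation is in SI; unit tags are
#' applied only at the user-facing boundary.
#'
#' @return A named list:
#' \describe{
#'   \item{gas_constant}{J mol^-1 K^-1}
#'   \item{avogadro}{mol^-1}
#'   \item{molar_volume_water}{m^3 mol^-1 (18 cm^3/mol)}
#'   \item{molecular_volume_water}{cm^3 per molecule (~2.99e-23)}
#'   \item{vacuum_permittivity}{F m^-1}
#'   \item{elementary_charge}{C}
#'   \item{boltzmann}{J K^-1}
#'   \item{psi_to_bar}{bar per psi (0.0689476)}
#' }
#' @export
#' @examples
#' channel_constants()$molecular_volume_water
channel_constants <- function() {
  n_a <- 6.02214076e23
  v_molar <- 1.8e-5
  list(
    gas_constant           = 8.314462618,
    avogadro               = n_a,
    molar_volume_water     = v_molar,
    molecular_volume_water = v_molar / n_a * 1e6,  # m^3 -> cm^3
    vacuum_permittivity    = 8.8541878128e-12,
    elementary_charge      = 1.602176634e-19,
    boltzmann              = 1.380649e-23,
    psi_to_bar             = 0.0689476
  )
}

#' Dump the package constants to a YAML file for provenance
#'
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_constants <- function(path) {
  yaml::write_yaml(channel_constants(), path)
  invisible(path)
}

.assert_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' Convert osmotic permeability (um/s) to hydraulic permeability (LMH/bar)
#'
#' The osmotic water permeability of a bilayer, expressed as a velocity under
#' an applied osmotic gradient, maps onto the pressure-normalised flux used
#' for synthetic membranes through the van 't Hoff factor `V_w / (R T)`:
#' `Lp = Pf * V_w / (R T)`, re-expressed in L m^-2 h^-1 bar^-1. At the
#' stopped-flow assay temperature of 10 degC (283.15 K) 1 um/s corresponds
#' to 2.75e-3 LMH/bar.
#'
#' @param pf_um_s Osmotic permeability in um s^-1 (vectorised, values >= 0).
#' @param temperature Absolute temperature in K; default 283.15 (the assay
#'   temperature). Must lie in (250, 350).
#' @return Hydraulic permeability in L m^-2 h^-1 bar^-1.
#' @seealso [hydraulic_to_osmotic()]
#' @export
#' @examples
#' osmotic_to_hydraulic(1, temperature = 283.15)  # ~2.75e-3
osmotic_to_hydraulic <- function(pf_um_s, temperature = 283.15) {
  if (!is.numeric(pf_um_s) || any(!is.finite(pf_um_s)) || any(pf_um_s < 0))
    stop("`pf_um_s` must be finite and >= 0", call. = FALSE)
  .assert_scalar(temperature, "temperature", positive = TRUE)
  if (temperature <= 250 || temperature >= 350)
    stop("`temperature` must lie in (250, 350) K", call. = FALSE)
  kc <- channel_constants()
  lp_si <- (pf_um_s * 1e-6) * kc$molar_volume_water /
    (kc$gas_constant * temperature)            # m s^-1 Pa^-1
  lp_si * 1e3 * 3600 * 1e5                     # -> L m^-2 h^-1 bar^-1
}

#' @rdname osmotic_to_hydraulic
#' @param lp_lmh_bar Hydraulic permeability in L m^-2 h^-1 bar^-1.
#' @export
hydraulic_to_osmotic <- function(lp_lmh_bar, temperature = 283.15) {
  if (!is.numeric(lp_lmh_bar) || any(!is.finite(lp_lmh_bar)) ||
      any(lp_lmh_bar < 0))
    stop("`lp_lmh_bar` must be finite and >= 0", call. = FALSE)
  .assert_scalar(temperature, "temperature", positive = TRUE)
  kc <- channel_constants()
  lp_si <- lp_lmh_bar / (1e3 * 3600 * 1e5)
  lp_si * kc$gas_constant * temperature / kc$molar_volume_water * 1e6
}

#' Convert single-channel volumetric flow (cm^3/s) to molecules per second
#'
#' Single-channel permeabilities are reported either as a volumetric flow
#' rate or as water molecules per second; the two differ by the molecular
#' volume of water (3e-14 cm^3/s corresponds to ~1e9 molecules/s).
#'
#' @param pf_vol_cm3_s Volumetric permeability in cm^3 s^-1 (>= 0).
#' @return Molecules per second.
#' @seealso [molecular_to_volumetric()]
#' @export
volumetric_to_molecular <- function(pf_vol_cm3_s) {
  if (!is.numeric(pf_vol_cm3_s) || any(!is.finite(pf_vol_cm3_s)) ||
      any(pf_vol_cm3_s < 0))
    stop("`pf_vol_cm3_s` must be finite and >= 0", call. = FALSE)
  pf_vol_cm3_s / channel_constants()$molecular_volume_water
}

#' @rdname volumetric_to_molecular
#' @param pf_mol_s Permeability in water molecules s^-1 (>= 0).
#' @export
molecular_to_volumetric <- function(pf_mol_s) {
  if (!is.numeric(pf_mol_s) || any(!is.finite(pf_mol_s)) || any(pf_mol_s < 0))
    stop("`pf_mol_s` must be finite and >= 0", call. = FALSE)
  pf_mol_s * channel_constants()$molecular_volume_water
}

#' Debye screening length of an electrolyte solution
#'
#' `lambda_D = sqrt(eps_r eps0 kB T / (2 N_A e^2 I))` with the ionic strength
#' converted from mol/L to mol/m^3. When the Debye length shrinks below the
#' pore diameter, electrostatic solute-membrane interactions are screened and
#' size exclusion dominates rejection.
#'
#' @param ionic_strength Ionic strength in mol/L (> 0, vectorised).
#' @param temperature K.
#' @param rel_permittivity Relative permittivity of the solvent (water: 78.5).
#' @return Debye length in nm.
#' @export
#' @examples
#' debye_length(0.1)    # ~0.96 nm
#' debye_length(0.001)  # ~9.6 nm
debye_length <- function(ionic_strength, temperature = 298.15,
                         rel_permittivity = 78.5) {
  if (!is.numeric(ionic_strength) || any(!is.finite(ionic_strength)) ||
      any(ionic_strength <= 0))
    stop("`ionic_strength` must be finite and > 0", call. = FALSE)
  .assert_scalar(temperature, "temperature", positive = TRUE)
  .assert_scalar(rel_permittivity, "rel_permittivity", positive = TRUE)
  kc <- channel_constants()
  i_si <- ionic_strength * 1e3                 # mol m^-3
  lam <- sqrt(rel_permittivity * kc$vacuum_permittivity * kc$boltzmann *
                temperature /
                (2 * kc$avogadro * kc$elementary_charge^2 * i_si))
  lam * 1e9
}

#' Hydrophilic volume fraction of an amphiphile and the vesicle-forming window
#'
#' Diblock amphiphiles self-assemble into vesicles when the hydrophilic
#' volume fraction lies near 0.35 +/- 0.10; the companion flag reports
#' whether the computed fraction falls inside that window (inclusive at both
#' ends, since the window is stated as a +/- band).
#'
#' @param v_hydrophilic,v_hydrophobic Block volumes in any common unit (> 0).
#' @param window Length-2 inclusive window for the vesicle-forming flag.
#' @return List with `fraction` and logical `vesicle_forming`.
#' @export
hydrophilic_fraction <- function(v_hydrophilic, v_hydrophobic,
                                 window = c(0.25, 0.45)) {
  .assert_scalar(v_hydrophilic, "v_hydrophilic", positive = TRUE)
  .assert_scalar(v_hydrophobic, "v_hydrophobic", positive = TRUE)
  f <- v_hydrophilic / (v_hydrophilic + v_hydrophobic)
  list(fraction = f,
       vesicle_forming = f >= window[1] && f <= window[2])
}

#' Areal packing density of channels and its geometric ceiling
#'
#' `packing_density()` is simply count/area in um^-2;
#' `packing_density_max()` is the close-packing ceiling `1/channel_area`
#' for a channel of given cross-section. A computed density above the
#' ceiling raises a warning (counting and imaging uncertainties can place
#' estimates above it), not an error.
#'
#' @param channel_count Number of channels (>= 0).
#' @param area_um2 Membrane area in um^2 (> 0).
#' @param channel_area_nm2 Channel cross-sectional area in nm^2 (> 0);
#'   optional in `packing_density()` to enable the ceiling check.
#' @return Density (um^-2).
#' @export
#' @examples
#' packing_density_max(1.5)        # ~6.7e5 um^-2 for a 1.5 nm^2 channel
#' packing_density(420, 0.001)     # 4.2e5 um^-2
packing_density <- function(channel_count, area_um2, channel_area_nm2 = NULL) {
  .assert_scalar(channel_count, "channel_count", nonneg = TRUE)
  .assert_scalar(area_um2, "area_um2", positive = TRUE)
  dens <- channel_count / area_um2
  if (!is.null(channel_area_nm2)) {
    dmax <- packing_density_max(channel_area_nm2)
    if (dens > dmax)
      warning(sprintf(
        "density %.3g um^-2 exceeds the geometric ceiling %.3g um^-2",
        dens, dmax), call. = FALSE)
  }
  dens
}

#' @rdname packing_density
#' @export
packing_density_max <- function(channel_area_nm2) {
  .assert_scalar(channel_area_nm2, "channel_area_nm2", positive = TRUE)
  1 / (channel_area_nm2 * 1e-6)                # nm^2 -> um^2
}

# ---- tagged permeability values --------------------------------------------

.perm_units <- c("um_per_s", "LMH_per_bar", "cm3_per_s", "molecules_per_s")

#' A permeability value with an explicit unit tag
#'
#' Two families of units exist: membrane permeabilities (`um_per_s`,
#' `LMH_per_bar`; interconvertible given a temperature) and single-channel
#' permeabilities (`cm3_per_s`, `molecules_per_s`). Conversion across the
#' two families needs membrane geometry and is deliberately not a unit
#' conversion (see [single_channel_permeability()]).
#'
#' @param value Numeric value (>= 0 for physical permeabilities).
#' @param unit One of `"um_per_s"`, `"LMH_per_bar"`, `"cm3_per_s"`,
#'   `"molecules_per_s"`.
#' @param temperature K; required to convert between `um_per_s` and
#'   `LMH_per_bar`.
#' @return Object of class `perm_quantity`.
#' @export
#' @examples
#' p <- perm_quantity(1, "um_per_s", temperature = 283.15)
#' convert_permeability(p, "LMH_per_bar")
perm_quantity <- function(value, unit, temperature = NULL) {
  .assert_scalar(value, "value", nonneg = TRUE)
  unit <- match.arg(unit, .perm_units)
  if (!is.null(temperature)) .assert_scalar(temperature, "temperature",
                                            positive = TRUE)
  structure(list(value = value, unit = unit, temperature = temperature),
            class = "perm_quantity")
}

#' @rdname perm_quantity
#' @param x A `perm_quantity`.
#' @param to Target unit.
#' @export
convert_permeability <- function(x, to) {
  stopifnot(inherits(x, "perm_quantity"))
  to <- match.arg(to, .perm_units)
  from <- x$unit
  if (from == to) return(x)
  fam <- function(u) if (u %in% c("um_per_s", "LMH_per_bar")) "membrane"
                     else "channel"
  if (fam(from) != fam(to))
    stop("conversion between membrane-scale and single-channel units ",
         "requires geometry; see single_channel_permeability()",
         call. = FALSE)
  val <- if (from == "um_per_s") {
    if (is.null(x$temperature))
      stop("temperature required for um_per_s <-> LMH_per_bar", call. = FALSE)
    osmotic_to_hydraulic(x$value, x$temperature)
  } else if (from == "LMH_per_bar") {
    if (is.null(x$temperature))
      stop("temperature required for um_per_s <-> LMH_per_bar", call. = FALSE)
    hydraulic_to_osmotic(x$value, x$temperature)
  } else if (from == "cm3_per_s") {
    volumetric_to_molecular(x$value)
  } else {
    molecular_to_volumetric(x$value)
  }
  perm_quantity(val, to, temperature = x$temperature)
}

#' @export
print.perm_quantity <- function(x, ...) {
  cat(sprintf("<permeability> %.6g %s%s\n", x$value, x$unit,
              if (!is.null(x$temperature))
                sprintf(" (T = %.2f K)", x$temperature) else ""))
  invisible(x)
}
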