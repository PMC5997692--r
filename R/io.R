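# CSV and XYZ readers/writers. CSV with mandatory headers is the universal
# tabular contract; YAML sidecars carry trajectory metadata; JSON carries
# reports.

.trace_schemas <- list(
  scattering = c("time_s", "intensity"),
  fcs        = c("lag_s", "G"),
  frap       = c("time_s", "F_norm"),
  flux       = c("pressure_bar", "flux_LMH"),
  flux_psi   = c("pressure_psi", "flux_LMH"),
  smd        = c("z_angstrom", "force_kcal_mol_A"),
  rejection  = c("solute", "mw_da", "c_feed", "c_permeate", "jv_LMH",
                 "k_mt_LMH")
)

#' Read a trace CSV against a registered schema
#'
#' Validates the header against the named schema, parses numeric columns,
#' and reports malformed rows by line number. Decimal commas are detected
#' and rejected explicitly rather than silently misparsed.
#'
#' @param path CSV file with a mandatory header row.
#' @param schema One of `"scattering"`, `"fcs"`, `"frap"`, `"flux"`,
#'   `"flux_psi"`, `"smd"`, `"rejection"`.
#' @return A data.frame with the schema's columns.
#' @export
read_trace_csv <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- match.arg(schema, names(.trace_schemas))
  cols <- .trace_schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!identical(names(df), cols))
    stop(sprintf(
      "header %s does not match schema '%s' (%s); registered schemas: %s",
      paste(names(df), collapse = ","), schema,
      paste(cols, collapse = ","),
      paste(names(.trace_schemas), collapse = ", ")), call. = FALSE)
  num_cols <- setdiff(cols, "solute")
  for (cn in num_cols) {
    if (any(grepl(",", df[[cn]], fixed = TRUE)))
      stop(sprintf(
        "column `%s` contains commas: decimal-comma locales are not parsed;",
        cn), " convert to decimal points", call. = FALSE)
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & nzchar(df[[cn]]))
    if (length(bad))
      stop(sprintf("column `%s`: malformed values at data line(s) %s", cn,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    df[[cn]] <- v
  }
  df
}

#' Write a data.frame through a registered trace schema
#'
#' @param df Data.frame whose columns include the schema columns.
#' @param path Output CSV path.
#' @param schema Schema name (see [read_trace_csv()]).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(df, path, schema) {
  schema <- match.arg(schema, names(.trace_schemas))
  cols <- .trace_schemas[[schema]]
  if (!all(cols %in% names(df)))
    stop("data.frame lacks schema columns: ",
         paste(setdiff(cols, names(df)), collapse = ", "), call. = FALSE)
  utils::write.csv(df[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an XYZ trajectory with a YAML metadata sidecar
#'
#' XYZ frames are the plain-text convention: an atom-count line, a comment
#' line, then `element x y z` per atom. The sidecar maps atom index ranges
#' to named groups and provides `dt_ns` and optionally `box_nm`:
#' ```
#' dt_ns: 0.02
#' box_nm: [5, 5, 4]
#' groups:
#'   waters: [1, 40]
#' ```
#'
#' @param path XYZ file.
#' @param meta_path YAML sidecar.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path, meta_path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path)) stop("file not found: ", meta_path,
                                    call. = FALSE)
  lines <- readLines(path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$dt_ns) || is.null(meta$groups))
    stop("sidecar must provide `dt_ns` and `groups`", call. = FALSE)
  pos <- 1L; frames <- list(); n_atoms <- NA_integer_; frame <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("malformed atom-count line at frame ", frame,
                       call. = FALSE)
    if (is.na(n_atoms)) n_atoms <- n
    else if (n != n_atoms)
      stop(sprintf("frame %d has %d atoms, expected %d", frame, n, n_atoms),
           call. = FALSE)
    if (pos + 1L + n > length(lines))
      stop("truncated frame ", frame, call. = FALSE)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p) {
      if (length(p) < 4) stop("malformed atom line in frame ", frame,
                              call. = FALSE)
      as.numeric(p[2:4])
    }, numeric(3)))
    if (any(is.na(xyz))) stop("non-numeric coordinates in frame ", frame,
                              call. = FALSE)
    frames[[frame]] <- xyz
    pos <- pos + 2L + n
  }
  if (frame == 0L) stop("no frames in ", path, call. = FALSE)
  coords <- array(0, dim = c(n_atoms, 3, frame))
  for (f in seq_len(frame)) coords[, , f] <- frames[[f]]
  groups <- lapply(meta$groups, function(rg) {
    rg <- as.integer(rg)
    if (length(rg) != 2L || rg[1] > rg[2] || rg[1] < 1 || rg[2] > n_atoms)
      stop("group range out of bounds (atoms 1..", n_atoms, ")",
           call. = FALSE)
    rg[1]:rg[2]
  })
  trajectory(coords, dt = meta$dt_ns, groups = groups,
             box = if (!is.null(meta$box_nm)) as.numeric(meta$box_nm))
}

#' Write a trajectory to XYZ plus a YAML sidecar
#'
#' @param traj A [trajectory()].
#' @param path XYZ output path.
#' @param meta_path YAML sidecar output path.
#' @param element Element symbol written for every atom.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, meta_path,
                                 element = "O") {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[3])) {
    writeLines(c(as.character(d[1]), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", element,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
  }
  groups <- lapply(traj$groups, function(ix) c(min(ix), max(ix)))
  meta <- list(dt_ns = traj$dt, groups = groups)
  if (!is.null(traj$box)) meta$box_nm <- as.numeric(.box_vec(traj))
  yaml::write_yaml(meta, meta_path)
  invisible(path)
}
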