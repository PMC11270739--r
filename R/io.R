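# Readers and writers for the formats the pipeline exchanges:
# multi-model PDB / plain coordinate tables, distance-series TSV
# (round-trip exact to 6 decimals), and YAML/JSON configuration.

# approximate atomic masses (amu) for common elements
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, BR = 79.904, CL = 35.45,
                     F = 18.998, I = 126.904, FE = 55.845, ZN = 65.38,
                     MG = 24.305, NA. = 22.990, K = 39.098, CA = 40.078)

#' Read a coordinate trajectory from PDB or a plain coordinate table
#'
#' Multi-model PDB files (MODEL/ENDMDL records) give one frame per model;
#' atoms are labeled by one-letter residue code plus residue number
#' (e.g. `D147`) for standard amino acids and by residue name (e.g. `LIG`)
#' otherwise, matching the residue identifiers of a [tunnel_network()].
#' Plain tables need columns `frame, atom_id, x, y, z` (whitespace or
#' comma separated); frames are grouped by the frame column and the atom
#' set must be identical in every frame.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"` or `"table"`.
#' @param frame_interval ps per frame stored on the trajectory (default
#'   100).
#' @param ligand ligand residue identifier (default `"LIG"`).
#' @param meta metadata list stored on the trajectory.
#' @return a [coordinate_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "table"),
                            frame_interval = 100, ligand = "LIG",
                            meta = list()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb"
              else "table"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    one <- suppressWarnings(bio3d::aa321(pdb$atom$resid))
    label <- ifelse(is.na(one) | one == "X",
                    pdb$atom$resid,
                    paste0(one, pdb$atom$resno))
    elem <- toupper(sub("^([A-Za-z]{1,2}).*", "\\1", pdb$atom$elety))
    mass <- .element_masses[elem]
    mass[is.na(mass)] <- .element_masses[substr(elem, 1L, 1L)][is.na(mass)]
    atoms <- data.frame(atom = pdb$atom$elety, resid = label,
                        mass = as.numeric(mass), stringsAsFactors = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    nf <- nrow(xyz); na <- ncol(xyz) / 3L
    coords <- array(NA_real_, c(nf, na, 3L))
    for (f in seq_len(nf))
      coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    return(coordinate_trajectory(coords, atoms, frame_interval, ligand,
                                 meta))
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("frame", "atom_id", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("coordinate table needs columns: ", paste(need, collapse = ", "))
  if (any(is.na(tab$frame))) stop("missing frame index in coordinate table")
  frames <- sort(unique(tab$frame))
  ref <- tab$atom_id[tab$frame == frames[1L]]
  coords <- array(NA_real_, c(length(frames), length(ref), 3L))
  for (i in seq_along(frames)) {
    sub <- tab[tab$frame == frames[i], , drop = FALSE]
    if (!identical(as.character(sub$atom_id), as.character(ref)))
      stop("inconsistent atoms across frames; first offending frame: ",
           frames[i])
    coords[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  atoms <- data.frame(atom = as.character(ref), resid = as.character(ref),
                      stringsAsFactors = FALSE)
  coordinate_trajectory(coords, atoms, frame_interval, ligand, meta)
}

#' Write a coordinate trajectory as a multi-model PDB
#'
#' @param traj a [coordinate_trajectory()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- nrow(traj$atoms)
  resno <- match(traj$atoms$resid, unique(traj$atoms$resid))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(na), resno,
      traj$coords[f, , 1], traj$coords[f, , 2], traj$coords[f, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read a distance series as TSV
#'
#' Columns `frame, d_cat, d_bt_<tunnel>..., L_<tunnel>...`; values are
#' written with 6 decimals and round-trip exactly at that precision.
#' Frame interval and metadata travel in `#key=value` header comments.
#'
#' @param ds a `distance_series`.
#' @param path file path.
#' @return `write_distance_series`: invisibly, `path`;
#'   `read_distance_series`: a `distance_series`.
#' @export
write_distance_series <- function(ds, path) {
  ids <- colnames(ds$d_bt)
  tab <- data.frame(frame = seq_len(ds$n_frames),
                    d_cat = sprintf("%.6f", ds$d_cat))
  for (id in ids) tab[[paste0("d_bt_", id)]] <- sprintf("%.6f", ds$d_bt[, id])
  for (id in ids) tab[[paste0("L_", id)]] <- sprintf("%.6f", ds$L[, id])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#frame_interval=%s", ds$frame_interval), con)
  for (k in names(ds$meta))
    writeLines(sprintf("#%s=%s", k, ds$meta[[k]]), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_series
#' @export
read_distance_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(); frame_interval <- 100
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) next
    if (kv[1L] == "frame_interval") frame_interval <- as.numeric(kv[2L])
    else meta[[kv[1L]]] <- kv[2L]
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  bt_cols <- grep("^d_bt_", names(tab), value = TRUE)
  l_cols <- grep("^L_", names(tab), value = TRUE)
  ids <- sub("^d_bt_", "", bt_cols)
  d_bt <- as.matrix(tab[bt_cols]); colnames(d_bt) <- ids
  L <- as.matrix(tab[l_cols]); colnames(L) <- sub("^L_", "", l_cols)
  L <- L[, ids, drop = FALSE]
  distance_series(tab$d_cat, d_bt, L, frame_interval, meta)
}

#' Default analysis configuration
#'
#' All cutoffs and lags at their standard values: region cutoffs
#' `r_cavity = 5`, `r_bulk = 19` Angstrom; transit cutoffs
#' `bt_cutoff_along = 2`, `bt_cutoff_across = 5`, `dist_tolerance = 1`
#' Angstrom; TICA lag 2 ns, MSM lag 20 ns, 1000 microstates,
#' HDBSCAN `min_cluster_size = 2`, automatic metastable-state count.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    cutoffs = list(r_cavity = 5.0, r_bulk = 19.0,
                   bt_cutoff_along = 2.0, bt_cutoff_across = 5.0,
                   dist_tolerance = 1.0),
    tica_lag_ns = 2.0,
    msm_lag_ns = 20.0,
    n_microstates = 1000L,
    n_tica_dims = 3L,
    n_metastable = "auto",
    min_cluster_size = 2L,
    n_representative = 1000L,
    reversible = TRUE
  )
}

#' Read a landmark/cutoff configuration file (YAML or JSON)
#'
#' Recognised keys: `catalytic` (residue list), `tunnels` (map tunnel id
#' to residue list), `cutoffs`, and any [default_config()] entry; absent
#' entries fall back to the defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with `network` (a [tunnel_network()] or `NULL`) and the
#'   merged configuration.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (k in setdiff(names(raw), c("catalytic", "tunnels"))) {
    if (k == "cutoffs") {
      for (c2 in names(raw$cutoffs)) cfg$cutoffs[[c2]] <- raw$cutoffs[[c2]]
    } else cfg[[k]] <- raw[[k]]
  }
  net <- NULL
  if (!is.null(raw$catalytic) && !is.null(raw$tunnels))
    net <- tunnel_network(raw$catalytic, as.list(raw$tunnels))
  list(network = net, config = cfg)
}

transit_params_from_config <- function(cfg) {
  transit_params(cfg$cutoffs$bt_cutoff_along, cfg$cutoffs$bt_cutoff_across,
                 cfg$cutoffs$dist_tolerance)
}
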