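#' Construct a coordinate trajectory
#'
#' Container for per-frame 3D positions of a constant atom set: the ligand
#' atoms plus every landmark-group atom. Coordinates are in Angstrom, the
#' frame interval in picoseconds.
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param atoms data.frame describing the constant atom set, with columns
#'   `resid` (residue identifier used by landmark groups; ligand atoms carry
#'   the ligand id) and optionally `mass` (amu) and `atom` (atom name).
#' @param frame_interval time per saved frame (ps), > 0.
#' @param ligand residue identifier of the ligand (default `"LIG"`).
#' @param meta optional named list of trajectory metadata
#'   (`scheme`, `replicate`, `epoch`, `run`).
#' @return object of class `coordinate_trajectory`.
#' @export
coordinate_trajectory <- function(coords, atoms, frame_interval = 100,
                                  ligand = "LIG", meta = list()) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!is.data.frame(atoms) || is.null(atoms$resid))
    stop("`atoms` must be a data.frame with a `resid` column")
  if (nrow(atoms) != dim(coords)[2])
    stop("atom table (", nrow(atoms), " rows) does not match coordinate ",
         "array (", dim(coords)[2], " atoms)")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  atoms$resid <- as.character(atoms$resid)
  structure(
    list(coords = coords, atoms = atoms,
         frame_interval = frame_interval, ligand = ligand, meta = meta),
    class = "coordinate_trajectory"
  )
}

#' @export
print.coordinate_trajectory <- function(x, ...) {
  cat("Coordinate trajectory:", dim(x$coords)[1], "frames,",
      dim(x$coords)[2], "atoms,", x$frame_interval, "ps/frame\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Centre of mass (or geometric centroid) of an atom group
#'
#' @param frame numeric `n x 3` matrix of positions (Angstrom).
#' @param weights `"geometric"` for the plain coordinate mean, or a numeric
#'   vector of masses (amu), one per row of `frame`.
#' @return numeric length-3 point.
#' @examples
#' group_com(rbind(c(0, 0, 0), c(2, 0, 0)))                  # (1, 0, 0)
#' group_com(rbind(c(0, 0, 0), c(3, 0, 0)), weights = c(1, 2))  # (2, 0, 0)
#' @export
group_com <- function(frame, weights = "geometric") {
  frame <- rbind(frame)
  if (nrow(frame) == 0L) stop("empty landmark group")
  if (identical(weights, "geometric")) {
    colMeans(frame)
  } else {
    w <- as.numeric(weights)
    if (length(w) != nrow(frame))
      stop("weights length (", length(w), ") != group size (", nrow(frame), ")")
    if (any(!is.finite(w)) || sum(w) <= 0) stop("invalid mass weights")
    colSums(frame * w) / sum(w)
  }
}

# indices of atoms belonging to a residue group; errors name missing members
resolve_group <- function(traj, group, label = "group") {
  missing <- setdiff(group, traj$atoms$resid)
  if (length(missing) > 0L)
    stop("missing atom/residue in trajectory for ", label, ": ",
         paste(missing, collapse = ", "))
  idx <- which(traj$atoms$resid %in% group)
  if (length(idx) == 0L) stop("empty landmark group: ", label)
  idx
}

group_weights <- function(traj, idx, weighting) {
  if (weighting == "geometric") return("geometric")
  m <- traj$atoms$mass
  has_mass <- !is.null(m) && all(is.finite(m[idx])) && all(m[idx] > 0)
  if (weighting == "mass" && !has_mass)
    stop("mass weighting requested but atom masses are missing")
  if (has_mass) m[idx] else "geometric"
}

com_series <- function(traj, idx, weighting) {
  w <- group_weights(traj, idx, weighting)
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, 3L)
  for (f in seq_len(nf))
    out[f, ] <- group_com(traj$coords[f, idx, , drop = FALSE][1, , ], w)
  out
}

#' Build per-frame distance series from a trajectory and tunnel network
#'
#' For every frame computes the Euclidean distance between the ligand COM and
#' the catalytic-group COM (`d_cat`), between the ligand COM and each tunnel's
#' bottleneck COM (`d_bt`), and the per-frame tunnel length `L` (catalytic COM
#' to bottleneck COM). These series are the substrate of region
#' classification, transit detection, fingerprinting and MSM featurization.
#'
#' @param traj a [coordinate_trajectory()].
#' @param net a [tunnel_network()].
#' @param weighting `"auto"` (mass-weighted when masses are present,
#'   geometric otherwise), `"mass"`, or `"geometric"`.
#' @param static_lengths if `TRUE`, `L` is held at its value in the first
#'   frame instead of being recomputed per frame.
#' @return object of class `distance_series`: list with `n_frames`, `d_cat`
#'   (numeric), `d_bt` and `L` (matrices `n_frames x n_tunnels`, columns in
#'   canonical tunnel order), `frame_interval` (ps), and `meta`.
#' @export
build_distance_series <- function(traj, net,
                                  weighting = c("auto", "mass", "geometric"),
                                  static_lengths = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(traj, "coordinate_trajectory"),
            inherits(net, "tunnel_network"))
  bad <- which(apply(traj$coords, 1L, function(m) any(!is.finite(m))))
  if (length(bad) > 0L)
    stop("non-finite coordinate at frame ", bad[1])
  lig_idx <- resolve_group(traj, traj$ligand, "ligand")
  cat_idx <- resolve_group(traj, net$catalytic, "catalytic")
  lig <- com_series(traj, lig_idx, weighting)
  ctc <- com_series(traj, cat_idx, weighting)
  d_cat <- sqrt(rowSums((lig - ctc)^2))
  ids <- tunnel_ids(net)
  nf <- n_frames(traj)
  d_bt <- matrix(NA_real_, nf, length(ids), dimnames = list(NULL, ids))
  L <- matrix(NA_real_, nf, length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    bt <- com_series(traj, resolve_group(traj, net$tunnels[[id]], id),
                     weighting)
    d_bt[, id] <- sqrt(rowSums((lig - bt)^2))
    L[, id] <- if (static_lengths) {
      rep(sqrt(sum((ctc[1, ] - bt[1, ])^2)), nf)
    } else {
      sqrt(rowSums((ctc - bt)^2))
    }
  }
  distance_series(d_cat, d_bt, L, frame_interval = traj$frame_interval,
                  meta = traj$meta)
}

#' Assemble a distance series directly from per-frame distances
#'
#' Used when distances are read from a table or generated synthetically
#' rather than computed from coordinates.
#'
#' @param d_cat numeric vector, ligand-COM to catalytic-COM distance (Angstrom).
#' @param d_bt numeric matrix `n_frames x n_tunnels`, ligand-COM to
#'   bottleneck-COM distances; column names are tunnel ids in canonical order.
#' @param L numeric matrix like `d_bt`: per-frame tunnel lengths.
#' @param frame_interval ps per frame.
#' @param meta named list of trajectory metadata.
#' @return object of class `distance_series`.
#' @export
distance_series <- function(d_cat, d_bt, L, frame_interval = 100,
                            meta = list()) {
  d_bt <- as.matrix(d_bt); L <- as.matrix(L)
  n <- length(d_cat)
  if (nrow(d_bt) != n || nrow(L) != n)
    stop("d_cat, d_bt and L must cover the same frames")
  if (is.null(colnames(d_bt)) || !identical(colnames(d_bt), colnames(L)))
    stop("d_bt and L need identical tunnel-id column names")
  if (any(c(d_cat, d_bt, L) < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  structure(
    list(n_frames = n, d_cat = as.numeric(d_cat), d_bt = d_bt, L = L,
         frame_interval = frame_interval, meta = meta),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat("Distance series:", x$n_frames, "frames,",
      ncol(x$d_bt), "tunnel(s) [", paste(colnames(x$d_bt), collapse = ", "),
      "],", x$frame_interval, "ps/frame\n")
  invisible(x)
}

#' Classify ligand location as cavity, tunnel or bulk
#'
#' Partition of frames by the ligand-to-catalytic-machinery distance:
#' cavity for `d_cat <= r_cavity`, tunnel for
#' `r_cavity < d_cat <= r_bulk`, bulk beyond. Boundaries are half-open
#' above, so a frame exactly at `r_cavity` is cavity.
#'
#' @param x a `distance_series` or a numeric vector of `d_cat` values.
#' @param r_cavity cavity radius (Angstrom, default 5).
#' @param r_bulk bulk radius (Angstrom, default 19); must exceed `r_cavity`.
#' @return factor with levels `cavity`, `tunnel`, `bulk`, one per frame.
#' @export
classify_region <- function(x, r_cavity = 5, r_bulk = 19) {
  if (!(is.numeric(r_cavity) && is.numeric(r_bulk) &&
        r_cavity > 0 && r_cavity < r_bulk))
    stop("config error: need 0 < r_cavity < r_bulk")
  d <- if (inherits(x, "distance_series")) x$d_cat else as.numeric(x)
  lab <- ifelse(d <= r_cavity, "cavity", ifelse(d <= r_bulk, "tunnel", "bulk"))
  factor(lab, levels = c("cavity", "tunnel", "bulk"))
}

#' Region occupancy per adaptive-sampling epoch
#'
#' Counts cavity/tunnel/bulk frames per epoch over a collection of distance
#' series, the summary used to track how sampling progressively covers the
#' unbound state.
#'
#' @param series list of `distance_series`, each carrying `meta$epoch`.
#' @param r_cavity,r_bulk region cutoffs (Angstrom).
#' @return data.frame with one row per epoch: counts `n_cavity`, `n_tunnel`,
#'   `n_bulk`, total `n`, and fractions `f_cavity`, `f_tunnel`, `f_bulk`
#'   summing to 1.
#' @export
epoch_region_fractions <- function(series, r_cavity = 5, r_bulk = 19) {
  if (inherits(series, "distance_series")) series <- list(series)
  epochs <- vapply(series, function(s) {
    if (is.null(s$meta$epoch)) stop("missing epoch metadata in series")
    as.character(s$meta$epoch)
  }, character(1))
  tab <- lapply(split(series, epochs), function(grp) {
    regs <- unlist(lapply(grp, classify_region,
                          r_cavity = r_cavity, r_bulk = r_bulk))
    cnt <- table(factor(regs, levels = c("cavity", "tunnel", "bulk")))
    n <- sum(cnt)
    data.frame(n_cavity = cnt[["cavity"]], n_tunnel = cnt[["tunnel"]],
               n_bulk = cnt[["bulk"]], n = n,
               f_cavity = cnt[["cavity"]] / n, f_tunnel = cnt[["tunnel"]] / n,
               f_bulk = cnt[["bulk"]] / n)
  })
  out <- do.call(rbind, tab)
  out <- cbind(epoch = names(tab), out)
  rownames(out) <- NULL
  out[order(suppressWarnings(as.numeric(out$epoch)), out$epoch), ,
      drop = FALSE]
}
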