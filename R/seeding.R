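#' Candidate ligand seed positions on a grid around a protein
#'
#' Builds the axis-aligned bounding box of the protein coordinates, expands
#' it by `padding` on every side, and places an `nx x ny x nz` lattice of
#' candidate points inside it — the bulk-solvent seeding scheme. By default
#' points sit at cell centres of the padded box; `registration = "corner"`
#' places them on the corner lattice spanning the box exactly.
#'
#' @param protein_coords numeric `n x 3` matrix (Angstrom).
#' @param nx,ny,nz lattice counts per axis (default 5 each).
#' @param padding box expansion per side (Angstrom, default 5).
#' @param registration `"center"` (default) or `"corner"`.
#' @return data.frame: `grid_index`, `x`, `y`, `z` (nx*ny*nz rows).
#' @export
grid_seeds <- function(protein_coords, nx = 5L, ny = 5L, nz = 5L,
                       padding = 5.0, registration = c("center", "corner")) {
  registration <- match.arg(registration)
  pc <- as.matrix(protein_coords)
  if (nrow(pc) == 0L) stop("empty protein coordinates")
  if (min(nx, ny, nz) < 1L) stop("lattice counts must be >= 1")
  lo <- apply(pc, 2L, min) - padding
  hi <- apply(pc, 2L, max) + padding
  if (any(hi - lo <= 0)) stop("degenerate bounding box (zero extent)")
  axis_points <- function(a, b, n) {
    if (registration == "center") {
      w <- (b - a) / n
      a + (seq_len(n) - 0.5) * w
    } else {
      if (n == 1L) (a + b) / 2 else seq(a, b, length.out = n)
    }
  }
  g <- expand.grid(x = axis_points(lo[1], hi[1], nx),
                   y = axis_points(lo[2], hi[2], ny),
                   z = axis_points(lo[3], hi[3], nz))
  data.frame(grid_index = seq_len(nrow(g)), g)
}

#' Select seed positions free of protein clashes
#'
#' Drops grid candidates closer than `min_clash_dist` to any protein atom,
#' ranks the survivors by their minimum distance to the protein (nearest
#' non-clashing shell first) and keeps `n_seeds`, breaking exact ties with
#' a seeded random jitter so the selection is deterministic given the seed.
#'
#' @param candidates data.frame from [grid_seeds()] (columns `x`, `y`, `z`).
#' @param protein_coords numeric `n x 3` matrix.
#' @param n_seeds number of seeds to keep (default 30).
#' @param min_clash_dist clash cutoff (Angstrom, default 3.0, about a van
#'   der Waals contact).
#' @param seed RNG seed for tie-breaking (default 1).
#' @return object of class `seed_set`: data.frame `grid_index`, `x`, `y`,
#'   `z`, `min_dist` (distance to nearest protein atom), scheme attribute
#'   `"bulk"`.
#' @export
select_seeds <- function(candidates, protein_coords, n_seeds = 30L,
                         min_clash_dist = 3.0, seed = 1L) {
  pc <- as.matrix(protein_coords)
  pts <- as.matrix(candidates[, c("x", "y", "z")])
  mind <- apply(pts, 1L, function(p)
    sqrt(min(colSums((t(pc) - p)^2))))
  keep <- mind >= min_clash_dist
  if (sum(keep) < n_seeds)
    stop("only ", sum(keep), " clash-free candidates for ", n_seeds,
         " seeds")
  surv <- cbind(candidates[keep, , drop = FALSE], min_dist = mind[keep])
  jitter <- withr::with_seed(seed, stats::runif(nrow(surv), 0, 1e-9))
  surv <- surv[order(surv$min_dist + jitter), , drop = FALSE][
    seq_len(n_seeds), , drop = FALSE]
  rownames(surv) <- NULL
  structure(surv, class = c("seed_set", "data.frame"), scheme = "bulk")
}

#' Write seed positions as PDB HETATM records and TSV
#'
#' @param seeds a [select_seeds()] result.
#' @param pdb_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_seeds <- function(seeds, pdb_path = NULL, tsv_path = NULL) {
  if (!is.null(pdb_path)) {
    lines <- sprintf(
      "HETATM%5d  C   SEE A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(seeds)), seq_len(nrow(seeds)),
      seeds$x, seeds$y, seeds$z)
    writeLines(c(lines, "END"), pdb_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(seeds), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(pdb = pdb_path, tsv = tsv_path))
}
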