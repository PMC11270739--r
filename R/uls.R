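#' Distance fingerprint of a metastable-state ensemble
#'
#' Summarises the per-frame characteristic distances of one metastable
#' state's representative ensemble (ligand-to-catalytic-machinery plus
#' ligand-to-bottleneck for each tunnel) into mean, 25th, 50th and 75th
#' percentile per distance. With four tunnels this is the 20-component
#' vector used to match metastable states across replicates and seeding
#' schemes. Percentiles use linear interpolation between order statistics.
#'
#' @param ens numeric matrix `n_frames x n_distances`; columns in canonical
#'   order (`d_cat`, then tunnels). Column names are kept in the output.
#' @return named numeric vector of length `4 * n_distances`, ordered by
#'   distance then statistic (`mean`, `p25`, `p50`, `p75`).
#' @examples
#' state_fingerprint(cbind(d_cat = c(1, 2, 3, 4)))
#' @export
state_fingerprint <- function(ens) {
  ens <- as.matrix(ens)
  if (nrow(ens) == 0L) stop("empty ensemble")
  cols <- colnames(ens)
  if (is.null(cols)) cols <- paste0("d", seq_len(ncol(ens)))
  out <- numeric(0)
  for (j in seq_len(ncol(ens))) {
    x <- ens[, j]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    v <- c(mean(x), q)
    names(v) <- paste(cols[j], c("mean", "p25", "p50", "p75"), sep = "_")
    out <- c(out, v)
  }
  out
}

#' Reduce fingerprint vectors by principal component analysis
#'
#' Fingerprints are centred and (by default) standardised to unit variance,
#' then projected on the leading principal components. The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making scores reproducible across platforms.
#'
#' @param F numeric matrix `n_states x n_variables` of fingerprints.
#' @param n_components number of components to keep (default 3).
#' @param scale. standardise columns before PCA (default `TRUE`); columns
#'   with zero variance are left unscaled.
#' @return list with `scores` (`n_states x n_components`), `loadings`,
#'   `explained` (fraction of variance per kept component).
#' @export
reduce_fingerprints <- function(F, n_components = 3L, scale. = TRUE) {
  F <- as.matrix(F)
  if (nrow(F) < 2L) stop("need at least 2 states for PCA")
  sds <- apply(F, 2L, stats::sd)
  sc <- if (scale.) ifelse(sds > 0, sds, 1) else FALSE
  p <- stats::prcomp(F, center = TRUE, scale. = sc)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (k < n_components) {  # degenerate rank: pad with zero scores
    pad <- n_components - k
    scores <- cbind(scores, matrix(0, nrow(F), pad))
    colnames(scores) <- paste0("PC", seq_len(n_components))
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = rot,
       explained = ev[seq_len(min(n_components, length(ev)))])
}

#' Cluster reduced fingerprints into unified ligand states
#'
#' Density-based hierarchical clustering (HDBSCAN) of the principal-component
#' scores groups metastable states that share a distance fingerprint across
#' replicates and seeding schemes into unified ligand states (ULSs). States
#' the density clustering leaves unassigned become singleton ULSs, so every
#' metastable state receives a label. Cluster labels are renumbered by
#' decreasing cluster size, ties by first-member order; singletons follow.
#'
#' @param scores numeric matrix `n_states x n_dims` (finite).
#' @param min_cluster_size HDBSCAN minimum cluster size (default 2).
#' @param state_ids optional character ids for the states (rownames of
#'   `scores` by default).
#' @return object of class `uls_assignment`: data.frame with columns
#'   `state`, `uls` (integer label), `singleton` (logical).
#' @export
cluster_uls <- function(scores, min_cluster_size = 2L, state_ids = NULL) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- nrow(scores)
  if (is.null(state_ids))
    state_ids <- if (!is.null(rownames(scores))) rownames(scores)
                 else paste0("state", seq_len(n))
  raw <- hdbscan_cluster(scores, min_cluster_size = min_cluster_size)
  labels <- integer(n)
  clustered <- !is.na(raw)
  if (any(clustered)) {
    tab <- table(raw[clustered])
    first <- tapply(seq_len(n)[clustered], raw[clustered], min)
    ord <- order(-as.integer(tab), as.integer(first))
    remap <- integer(length(tab))
    remap[as.integer(names(tab))[ord]] <- seq_along(ord)
    labels[clustered] <- remap[raw[clustered]]
  }
  next_lab <- max(labels, 0L)
  for (i in which(!clustered)) {
    next_lab <- next_lab + 1L
    labels[i] <- next_lab
  }
  out <- data.frame(state = state_ids, uls = labels,
                    singleton = !clustered, stringsAsFactors = FALSE)
  class(out) <- c("uls_assignment", "data.frame")
  out
}

#' Presence of unified ligand states across replicates
#'
#' Cross-tabulates ULS labels against (scheme, replicate), recording the
#' mean stationary probability of the member metastable states in each
#' cell (or the member count when probabilities are not supplied). `NA`
#' marks absence of a ULS from a replicate.
#'
#' @param assign a [cluster_uls()] assignment.
#' @param metadata data.frame with one row per state: `state`, `scheme`,
#'   `replicate`, and optionally `probability` in `[0, 1]`.
#' @return matrix ULS x replicate (columns named `scheme.replicate`), cells
#'   the mean probability (or count), `NA` where absent.
#' @export
presence_matrix <- function(assign, metadata) {
  stopifnot(all(c("state", "scheme", "replicate") %in% names(metadata)))
  m <- merge(as.data.frame(assign), metadata, by = "state")
  has_p <- "probability" %in% names(m)
  if (has_p && any(m$probability < 0 | m$probability > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  col <- interaction(m$scheme, m$replicate, drop = TRUE, lex.order = TRUE)
  uls_lv <- sort(unique(m$uls))
  out <- matrix(NA_real_, length(uls_lv), nlevels(col),
                dimnames = list(paste0("ULS", uls_lv), levels(col)))
  for (g in split(m, list(m$uls, col), drop = TRUE)) {
    if (nrow(g) == 0L) next
    val <- if (has_p) mean(g$probability) else nrow(g)
    out[paste0("ULS", g$uls[1L]),
        as.character(interaction(g$scheme[1L], g$replicate[1L],
                                 lex.order = TRUE))] <- val
  }
  out
}
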