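# Synthetic inputs with planted ground truth: toy tunnel networks, ligand
# walks executing a planned sequence of bulk<->interior transits, Markov
# chains with known kinetics, and metastable ensembles with planted
# fingerprint profiles. Every generator is deterministic given its seed and
# returns the exact expected result alongside the data.

#' Build a toy tunnel network with explicit landmark coordinates
#'
#' Places the catalytic-machinery COM at the origin and the bottleneck COM
#' of each tunnel at `length * direction`. Each landmark group is realised
#' as atoms arranged symmetrically about its COM, so geometric centroids
#' reproduce the specification exactly; tunnel lengths computed from the
#' emitted coordinates equal the requested lengths to machine precision.
#'
#' @param tunnels named list; each element `list(direction = unit-ish 3
#'   vector, length = Angstrom)`. Directions are normalised; duplicate
#'   directions are an error.
#' @return list of class `toy_network`: `network` (a [tunnel_network()]),
#'   `landmark_atoms` (data.frame `resid, x, y, z`), `directions`
#'   (`n_tunnels x 3`, unit rows), `lengths` (named).
#' @export
make_toy_network <- function(tunnels) {
  if (length(tunnels) < 1L) stop("need at least one tunnel")
  ids <- names(tunnels)
  U <- t(vapply(tunnels, function(t) {
    u <- as.numeric(t$direction)
    u / sqrt(sum(u^2))
  }, numeric(3)))
  if (nrow(U) > 1L) {
    dots <- tcrossprod(U)
    diag(dots) <- 0
    if (any(dots > 1 - 1e-9)) stop("duplicate tunnel directions")
  }
  lens <- vapply(tunnels, function(t) as.numeric(t$length), numeric(1))
  # three catalytic atoms whose offsets sum to zero -> COM exactly at origin
  tri <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
               c(-0.5, -sqrt(3) / 2, 0)) * 0.8
  atoms <- data.frame(resid = paste0("CAT", 1:3),
                      x = tri[, 1], y = tri[, 2], z = tri[, 3])
  groups <- list()
  for (i in seq_along(ids)) {
    ctr <- lens[i] * U[i, ]
    perp <- if (abs(U[i, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * U[i, ]) * U[i, ]
    perp <- 0.8 * perp / sqrt(sum(perp^2))
    bt <- rbind(ctr + perp, ctr - perp)
    rid <- paste0(ids[i], "_BT", 1:2)
    atoms <- rbind(atoms, data.frame(resid = rid,
                                     x = bt[, 1], y = bt[, 2], z = bt[, 3]))
    groups[[ids[i]]] <- rid
  }
  structure(
    list(network = tunnel_network(paste0("CAT", 1:3), groups),
         landmark_atoms = atoms,
         directions = U,
         lengths = stats::setNames(lens, ids)),
    class = "toy_network"
  )
}

#' Plan a sequence of tunnel transits for a synthetic ligand walk
#'
#' @param tunnel character vector: tunnel used by each planted crossing.
#' @param direction `"out_in"` or `"in_out"` per crossing; consecutive
#'   crossings must alternate consistently (you cannot enter twice without
#'   leaving).
#' @param dwell frames spent settled on the origin side before each
#'   crossing (>= 1).
#' @param band_frames frames spent in the bottleneck band during each
#'   crossing; 0 plants a direct crossing.
#' @return data.frame of class `event_plan`.
#' @export
event_plan <- function(tunnel, direction, dwell = 5L, band_frames = 2L) {
  n <- length(tunnel)
  out <- data.frame(tunnel = tunnel, direction = direction,
                    dwell = rep_len(as.integer(dwell), n),
                    band_frames = rep_len(as.integer(band_frames), n),
                    stringsAsFactors = FALSE)
  if (n > 0L) {
    if (any(out$dwell < 1L)) stop("dwell frames must be >= 1")
    if (any(out$band_frames < 0L)) stop("band_frames must be >= 0")
    if (!all(out$direction %in% c("out_in", "in_out")))
      stop("direction must be out_in or in_out")
    side <- ifelse(out$direction == "out_in", "out", "in")
    dest <- ifelse(out$direction == "out_in", "in", "out")
    if (n > 1L && any(side[-1L] != dest[-n]))
      stop("infeasible plan at step ",
           which(side[-1L] != dest[-n])[1L] + 1L,
           ": crossings do not alternate")
  }
  class(out) <- c("event_plan", "data.frame")
  out
}

# spherical interpolation at constant radius (safe path through the bulk)
slerp <- function(a, b, n) {
  ra <- sqrt(sum(a^2)); rb <- sqrt(sum(b^2))
  ua <- a / ra; ub <- b / rb
  ang <- acos(max(-1, min(1, sum(ua * ub))))
  t <- seq_len(n) / (n + 1)
  if (ang < 1e-8) {
    out <- outer(1 - t, a) + outer(t, b)
  } else {
    out <- (outer(sin((1 - t) * ang), ua) + outer(sin(t * ang), ub)) /
      sin(ang)
    out <- out * (ra + t * (rb - ra))
  }
  out
}

#' Simulate a ligand walk executing a planted transit plan
#'
#' Generates a ligand COM path that carries out each planned crossing along
#' its tunnel axis: settled frames in the bulk (beyond every tunnel length
#' plus the along-cutoff and a safety margin), optional frames at the
#' bottleneck, settled frames deep inside, with Gaussian positional jitter
#' throughout. Paths between anchors stay at a safe radius (spherical
#' interpolation outside, straight lines inside), so no unplanned crossing
#' occurs. Returns the trajectory together with the exact expected event
#' list.
#'
#' @param toy a [make_toy_network()] object.
#' @param plan an [event_plan()]; zero rows give a bulk hover.
#' @param noise_sd positional jitter sd (Angstrom, default 0.3); must stay
#'   below `bt_cutoff_across / 3` for clean planting.
#' @param seed RNG seed.
#' @param params [transit_params()] whose cutoffs the plant respects.
#' @param frame_interval ps per frame (default 100).
#' @param tail_frames settled frames appended after the last crossing
#'   (default 5).
#' @param move_frames frames for same-side relocations between anchors
#'   (default 3).
#' @param hard if `TRUE`, drop the safety margins around the decision
#'   boundaries so the tolerance rules get exercised.
#' @param meta metadata list stored on the trajectory.
#' @return list: `trajectory` (a [coordinate_trajectory()]), `truth`
#'   (data.frame of expected events in [detect_transitions()] format).
#' @export
simulate_ligand_walk <- function(toy, plan, noise_sd = 0.3, seed = 1L,
                                 params = transit_params(),
                                 frame_interval = 100, tail_frames = 5L,
                                 move_frames = 3L, hard = FALSE,
                                 meta = list()) {
  stopifnot(inherits(toy, "toy_network"))
  if (noise_sd >= params$bt_cutoff_across / 3)
    warning("noise_sd >= bt_cutoff_across / 3; planting may not be clean")
  margin <- if (hard) 0 else max(1, 6 * noise_sd)
  lens <- toy$lengths
  ids <- names(lens)
  along <- params$bt_cutoff_along
  r_out <- max(lens) + along + margin + 2
  r_in <- min(lens) - along - margin - 1
  if (r_in <= 0.5)
    stop("infeasible plan: tunnels too short for an interior dwell at ",
         "this noise level")
  r_in <- min(r_in, 0.4 * min(lens))
  anchor <- function(side, tun) {
    u <- toy$directions[match(tun, ids), ]
    if (side == "out") r_out * u else r_in * u
  }
  pos <- list(); truth <- list()
  side <- if (nrow(plan) > 0L && plan$direction[1L] == "in_out") "in"
          else "out"
  cur <- anchor(side, if (nrow(plan) > 0L) plan$tunnel[1L] else ids[1L])
  add <- function(p) pos[[length(pos) + 1L]] <<- p
  add(cur)
  for (s in seq_len(nrow(plan))) {
    tun <- plan$tunnel[s]
    origin <- if (plan$direction[s] == "out_in") "out" else "in"
    if (origin != side)
      stop("infeasible plan at step ", s, ": ligand is on the ", side,
           " side")
    a <- anchor(side, tun)
    if (sqrt(sum((cur - a)^2)) > 1e-9) {
      if (side == "out") apply(slerp(cur, a, move_frames), 1L, add)
      else {
        t <- seq_len(move_frames) / (move_frames + 1)
        apply(outer(1 - t, cur) + outer(t, a), 1L, add)
      }
    }
    for (f in seq_len(plan$dwell[s] - 1L)) add(a)
    start_frame <- length(pos)           # last settled origin-side frame
    u <- toy$directions[match(tun, ids), ]
    nb <- plan$band_frames[s]
    for (f in seq_len(nb)) add(lens[[tun]] * u)
    dest <- if (origin == "out") "in" else "out"
    cur <- anchor(dest, tun)
    add(cur)
    truth[[s]] <- data.frame(
      start_frame = start_frame + nb,    # filled with machine convention
      end_frame = start_frame + nb + 1L,
      direction = plan$direction[s],
      mediation = if (nb > 0L) "via_bottleneck" else "direct",
      category = tun, stringsAsFactors = FALSE)
    truth[[s]]$start_frame <- start_frame
    side <- dest
  }
  for (f in seq_len(tail_frames)) add(cur)
  P <- do.call(rbind, pos)
  nf <- nrow(P)
  P <- P + withr::with_seed(seed,
    matrix(stats::rnorm(nf * 3L, 0, noise_sd), nf, 3L))
  lm <- toy$landmark_atoms
  atoms <- rbind(lm, data.frame(resid = "LIG", x = 0, y = 0, z = 0))
  coords <- array(NA_real_, c(nf, nrow(atoms), 3L))
  for (j in seq_len(nrow(lm)))
    coords[, j, ] <- matrix(c(lm$x[j], lm$y[j], lm$z[j]), nf, 3L,
                            byrow = TRUE)
  coords[, nrow(atoms), ] <- P
  traj <- coordinate_trajectory(coords, atoms, frame_interval,
                                ligand = "LIG", meta = meta)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(start_frame = integer(), end_frame = integer(),
               direction = character(), mediation = character(),
               category = character(), stringsAsFactors = FALSE)
  # event frames: start = last origin-side frame before the band/jump,
  # end = first destination-side frame
  list(trajectory = traj, truth = truth)
}

#' Sample a discrete Markov chain and map it to noisy coordinates
#'
#' Validation oracle for the MSM stage: a chain drawn from a known
#' row-stochastic transition matrix, embedded as Gaussian blobs around
#' state centres, together with the chain itself and the exact
#' first-passage times implied by the generator matrix.
#'
#' @param P_true row-stochastic, irreducible transition matrix.
#' @param centers numeric `k x d` matrix of state centres.
#' @param n_steps chain length.
#' @param frame_interval time per step (default 1).
#' @param noise_sd jitter sd around centres (default 0.1).
#' @param seed RNG seed.
#' @return list: `dtraj` (integer chain), `X` (`n_steps x d` coordinates),
#'   `P_true`, `mfpt_true(source, sink)` (function: exact MFPT in steps
#'   times `frame_interval`).
#' @export
simulate_markov_chain <- function(P_true, centers, n_steps,
                                  frame_interval = 1, noise_sd = 0.1,
                                  seed = 1L) {
  P_true <- as.matrix(P_true)
  k <- nrow(P_true)
  if (any(P_true < 0) || any(abs(rowSums(P_true) - 1) > 1e-10))
    stop("P_true must be row-stochastic")
  g <- igraph::graph_from_adjacency_matrix((P_true > 0) * 1,
                                           mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("P_true must be irreducible")
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == k)
  sim <- withr::with_seed(seed, {
    d <- integer(n_steps)
    d[1L] <- sample.int(k, 1L)
    for (t in 2L:n_steps)
      d[t] <- sample.int(k, 1L, prob = P_true[d[t - 1L], ])
    X <- centers[d, , drop = FALSE] +
      matrix(stats::rnorm(n_steps * ncol(centers), 0, noise_sd),
             n_steps, ncol(centers))
    list(d = d, X = X)
  })
  list(dtraj = sim$d, X = sim$X, P_true = P_true,
       mfpt_true = function(source, sink)
         mfpt(P_true, source, sink, lag_time = frame_interval))
}

#' Generate metastable-state ensembles with planted fingerprint profiles
#'
#' For each replicate and each profile present in it, draws an ensemble of
#' Gaussian-jittered distance vectors around the profile means, emulating
#' the representative-structure ensembles whose fingerprints the ULS stage
#' unifies. The planted profile is recorded per ensemble, and per-replicate
#' state probabilities (normalised within each replicate) are attached.
#'
#' @param profiles numeric `k x n_distances` matrix of profile mean
#'   distances (rownames become profile ids).
#' @param noise_sd within-profile jitter sd (Angstrom).
#' @param n_reps number of replicates (default 3).
#' @param n_frames representative frames per ensemble (default 200).
#' @param seed RNG seed.
#' @param presence logical `k x n_reps` matrix; `FALSE` omits a profile
#'   from that replicate (default: all present).
#' @param scheme scheme label stored in the metadata (default `"synth"`).
#' @return list: `ensembles` (list of `list(state, scheme, replicate,
#'   profile, data, probability)`), `metadata` (data.frame), `planted`
#'   (profile id per state).
#' @export
generate_metastable_ensembles <- function(profiles, noise_sd = 0.2,
                                          n_reps = 3L, n_frames = 200L,
                                          seed = 1L, presence = NULL,
                                          scheme = "synth") {
  profiles <- as.matrix(profiles)
  k <- nrow(profiles)
  if (k < 1L) stop("need at least one profile")
  if (anyDuplicated(profiles)) stop("profiles must be distinct")
  pid <- rownames(profiles)
  if (is.null(pid)) pid <- paste0("profile", seq_len(k))
  if (is.null(presence)) presence <- matrix(TRUE, k, n_reps)
  stopifnot(dim(presence) == c(k, n_reps))
  m <- ncol(profiles)
  ens <- list(); meta <- list()
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      present <- which(presence[, r])
      w <- stats::runif(length(present), 0.5, 1.5)
      prob <- w / sum(w)
      for (j in seq_along(present)) {
        i <- present[j]
        dat <- matrix(profiles[i, ], n_frames, m, byrow = TRUE) +
          matrix(stats::rnorm(n_frames * m, 0, noise_sd), n_frames, m)
        dat[dat < 0] <- 0
        colnames(dat) <- colnames(profiles)
        sid <- sprintf("%s_rep%d_state%d", scheme, r, j)
        ens[[length(ens) + 1L]] <- list(
          state = sid, scheme = scheme, replicate = r,
          profile = pid[i], data = dat, probability = prob[j])
        meta[[length(meta) + 1L]] <- data.frame(
          state = sid, scheme = scheme, replicate = r,
          probability = prob[j], profile = pid[i],
          stringsAsFactors = FALSE)
      }
    }
  })
  meta <- do.call(rbind, meta)
  list(ensembles = ens, metadata = meta, planted = meta$profile)
}
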