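# Shared fixtures and independent oracles for the test suite.

# three orthogonal-ish tunnels of distinct lengths
toy3 <- function() {
  make_toy_network(list(
    p1a = list(direction = c(1, 0, 0), length = 14),
    p2  = list(direction = c(0, 1, 0), length = 12),
    p3  = list(direction = c(0, 0, 1), length = 16)
  ))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# independent brute-force transition enumerator: scans all pairs of
# consecutive general-state frames and categorises each boundary crossing
# from first principles, without the incremental state machine.
oracle_transitions <- function(ds, params = transit_params()) {
  pos <- assign_position(ds, params)
  gen <- which(pos$kind %in% c("in_", "out_"))
  out <- list()
  if (length(gen) < 2L) {
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      direction = character(), mediation = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  for (j in 2:length(gen)) {
    a <- gen[j - 1L]; b <- gen[j]
    if (pos$kind[a] == pos$kind[b]) next
    direction <- if (pos$kind[a] == "in_") "in_out" else "out_in"
    band <- if (b > a + 1L) pos[(a + 1L):(b - 1L), , drop = FALSE]
            else pos[0L, ]
    if (nrow(band) == 0L) {
      ta <- pos$tunnel[a]; tb <- pos$tunnel[b]
      if (ta == tb) categ <- ta
      else if (ds$d_bt[b, ta] - ds$d_bt[b, tb] <= params$dist_tolerance)
        categ <- ta
      else if (ds$d_bt[a, tb] - ds$d_bt[a, ta] <= params$dist_tolerance)
        categ <- tb
      else categ <- "mixed"
      med <- "direct"
    } else {
      last <- band[nrow(band), ]
      categ <- if (last$kind == "bt_unknown") "unknown" else last$tunnel
      med <- "via_bottleneck"
    }
    out[[length(out) + 1L]] <- data.frame(
      start_frame = a, end_frame = b, direction = direction,
      mediation = med, category = categ, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    data.frame(start_frame = integer(), end_frame = integer(),
               direction = character(), mediation = character(),
               category = character(), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

# random distance series exercising all position kinds (3 tunnels with
# constant lengths; ligand distance random-walks across all bands)
random_distance_series <- function(n = 60L) {
  ids <- c("p1a", "p2", "p3")
  lens <- c(p1a = 14, p2 = 12, p3 = 16)
  d_cat <- pmax(0.1, cumsum(c(runif(1, 0, 25), rnorm(n - 1L, 0, 4))))
  d_cat <- ((d_cat) %% 25) + 0.1
  d_bt <- matrix(runif(n * 3L, 0, 8), n, 3L, dimnames = list(NULL, ids))
  L <- matrix(rep(lens, each = n), n, 3L, dimnames = list(NULL, ids))
  distance_series(d_cat, d_bt, L, frame_interval = 100)
}

# Monte-Carlo first-passage oracle: mean steps (times lag_time) for walkers
# started in `source` (stationary-weighted) to first hit `sink`.
mc_first_passage <- function(P, source, sink, n_walkers = 1e4,
                             lag_time = 1, max_steps = 1e5, seed = 1L) {
  k <- nrow(P)
  e <- eigen(t(P)); i <- which.max(Re(e$values))
  pi <- abs(Re(e$vectors[, i])); pi <- pi / sum(pi)
  w <- pi[source] / sum(pi[source])
  withr::with_seed(seed, {
    state <- sample(source, n_walkers, replace = TRUE, prob = w)
    steps <- rep(NA_real_, n_walkers)
    alive <- !(state %in% sink)
    steps[!alive] <- 0
    t <- 0L
    while (any(alive) && t < max_steps) {
      t <- t + 1L
      idx <- which(alive)
      cur <- state[idx]
      nxt <- cur
      for (s in unique(cur)) {
        sel <- which(cur == s)
        nxt[sel] <- sample.int(k, length(sel), replace = TRUE,
                               prob = P[s, ])
      }
      state[idx] <- nxt
      hit <- idx[state[idx] %in% sink]
      steps[hit] <- t
      alive[hit] <- FALSE
    }
    list(mean = mean(steps, na.rm = TRUE) * lag_time,
         se = stats::sd(steps, na.rm = TRUE) * lag_time /
           sqrt(sum(!is.na(steps))))
  })
}

# random irreducible row-stochastic matrix with a sticky diagonal
random_transition_matrix <- function(k, self = 0.6) {
  M <- matrix(runif(k * k, 0.05, 1), k, k)
  diag(M) <- diag(M) + self * k
  M / rowSums(M)
}
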