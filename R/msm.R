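#' Time-lagged independent component analysis (TICA)
#'
#' Linear projection maximising autocorrelation at a lag: solves the
#' generalized eigenproblem of the symmetrized time-lagged covariance
#' against the instantaneous covariance and returns the slowest collective
#' coordinates. A small ridge is added to the instantaneous covariance for
#' conditioning. Components are ordered by decreasing eigenvalue; the sign
#' of each is fixed so its largest-magnitude loading is positive.
#'
#' @param X numeric matrix `n_frames x n_features`, or a list of such
#'   matrices (one per trajectory; lagged pairs never span a boundary).
#' @param lag lag in frames (>= 1, < n_frames of at least one trajectory).
#' @param n_dims number of independent components to keep (default 3,
#'   capped at `n_features`).
#' @param ridge ridge added to the diagonal of the instantaneous
#'   covariance (default 1e-6).
#' @return list of class `tica`: `y` (projected coordinates, all
#'   trajectories stacked, `n_frames x n_dims`), `eigenvalues`,
#'   `components` (loadings), `lag`.
#' @export
tica <- function(X, lag, n_dims = 3L, ridge = 1e-6) {
  if (!is.list(X)) X <- list(X)
  X <- lapply(X, as.matrix)
  m <- ncol(X[[1L]])
  if (lag < 1L) stop("lag must be >= 1")
  usable <- vapply(X, nrow, integer(1)) > lag
  if (!any(usable)) stop("need 1 <= lag < n_frames")
  n_dims <- min(n_dims, m)
  mu <- colSums(do.call(rbind, lapply(X, function(x)
    colSums(x)))) / sum(vapply(X, nrow, integer(1)))
  C0 <- Ct <- matrix(0, m, m)
  np <- 0L
  for (x in X[usable]) {
    Xc <- sweep(x, 2L, mu)
    n <- nrow(Xc)
    A <- Xc[seq_len(n - lag), , drop = FALSE]
    B <- Xc[(lag + 1L):n, , drop = FALSE]
    C0 <- C0 + (crossprod(A) + crossprod(B)) / 2
    Ct <- Ct + crossprod(A, B)
    np <- np + (n - lag)
  }
  C0 <- C0 / np
  Ct <- Ct / np
  Ct <- (Ct + t(Ct)) / 2
  C0r <- C0 + diag(ridge, m)
  ch <- tryCatch(chol(C0r), error = function(e)
    stop("instantaneous covariance is singular; increase `ridge`"))
  Li <- backsolve(ch, diag(m))           # C0r^{-1/2} (upper-tri inverse)
  M <- t(Li) %*% Ct %*% Li
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  keep <- seq_len(n_dims)
  comp <- Li %*% eg$vectors[, keep, drop = FALSE]
  for (j in seq_len(n_dims)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  y <- do.call(rbind, lapply(X, function(x) sweep(x, 2L, mu) %*% comp))
  structure(list(y = y, eigenvalues = eg$values[keep],
                 components = comp, lag = lag),
            class = "tica")
}

#' Cluster reduced coordinates into microstates
#'
#' k-means discretisation of the (TICA) coordinates into microstates.
#' A fixed seed gives bit-identical assignments.
#'
#' @param coords numeric matrix `n_frames x n_dims`.
#' @param k number of microstates.
#' @param seed RNG seed (default 1).
#' @param nstart,iter.max passed to [stats::kmeans()].
#' @return list: `assignments` (integer per frame, 1..k), `centers`.
#' @export
cluster_microstates <- function(coords, k, seed = 1L, nstart = 5L,
                                iter.max = 100L) {
  coords <- as.matrix(coords)
  n_distinct <- nrow(unique(coords))
  if (k > n_distinct)
    stop("k (", k, ") exceeds distinct points (", n_distinct, ")")
  km <- withr::with_seed(seed,
    stats::kmeans(coords, centers = k, nstart = nstart,
                  iter.max = iter.max))
  list(assignments = as.integer(km$cluster), centers = km$centers)
}

#' Transition count matrix at a lag
#'
#' Counts microstate transitions over a sliding window of `lag` frames.
#' Trajectories are never concatenated: no pair spans a trajectory boundary.
#'
#' @param dtrajs integer vector (one trajectory) or list of integer vectors
#'   (discrete trajectories, states 1..k or any positive integers).
#' @param lag lag in frames (>= 1).
#' @param n_states number of states (defaults to the largest label seen).
#' @return integer matrix `n_states x n_states`; entry (i, j) counts pairs
#'   `state(t) = i, state(t + lag) = j`.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (lag < 1L) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  C <- matrix(0L, n_states, n_states)
  any_pairs <- FALSE
  for (d in dtrajs) {
    d <- as.integer(d)
    if (length(d) <= lag) next
    any_pairs <- TRUE
    from <- d[seq_len(length(d) - lag)]
    to <- d[(lag + 1L):length(d)]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  if (!any_pairs) stop("no transition pairs: lag >= every trajectory length")
  dimnames(C) <- NULL
  C
}

# largest strongly connected component of the count graph
largest_connected_set <- function(C) {
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tapply(rowSums(C) + colSums(C), comp$membership, sum)
  keep <- which(comp$membership ==
                  as.integer(names(sizes)[which.max(sizes)]))
  sort(keep)
}

#' Estimate a transition matrix from counts
#'
#' Row-normalises the (optionally symmetrized) count matrix restricted to
#' its largest strongly connected state set. Reversible estimation
#' symmetrizes counts as `(C + t(C)) / 2`, which yields a transition matrix
#' in exact detailed balance with stationary distribution proportional to
#' the symmetrized row sums; non-reversible estimation is the plain
#' maximum-likelihood row normalisation with the stationary distribution
#' taken as the leading left eigenvector.
#'
#' @param C count matrix.
#' @param reversible logical (default `TRUE`).
#' @return list of class `msm_estimate`: `P` (row-stochastic), `pi`
#'   (stationary distribution), `active` (indices of retained states in the
#'   original labeling), `n_dropped_counts` (counts outside the connected
#'   set).
#' @export
transition_matrix <- function(C, reversible = TRUE) {
  C <- as.matrix(C)
  active <- largest_connected_set(C)
  if (length(active) == 0L) stop("empty connected set")
  Ca <- C[active, active, drop = FALSE]
  dropped <- sum(C) - sum(Ca)
  if (reversible) {
    S <- (Ca + t(Ca)) / 2
    rs <- rowSums(S)
    if (any(rs == 0)) stop("state with no counts in connected set")
    P <- S / rs
    pi <- rs / sum(rs)
  } else {
    rs <- rowSums(Ca)
    if (any(rs == 0)) stop("state with no outgoing counts in connected set")
    P <- Ca / rs
    e <- eigen(t(P))
    i <- which.max(Re(e$values))
    v <- Re(e$vectors[, i])
    pi <- abs(v) / sum(abs(v))
  }
  structure(list(P = P, pi = as.numeric(pi), active = active,
                 n_dropped_counts = dropped),
            class = "msm_estimate")
}

#' @export
print.msm_estimate <- function(x, ...) {
  cat("MSM estimate:", nrow(x$P), "states,",
      x$n_dropped_counts, "counts outside the connected set\n")
  invisible(x)
}

#' Implied timescales across lags
#'
#' `t_i(tau) = -tau / log(lambda_i(tau))` for the non-unit eigenvalues of
#' the transition matrix estimated at each lag. Lag-independence of the
#' implied timescales indicates Markovianity at that resolution. Complex
#' eigenvalues are reported by modulus with a warning.
#'
#' @param dtrajs discrete trajectories (vector or list).
#' @param lags integer vector of lags in frames (>= 2 values).
#' @param n_timescales how many timescales to report (default 3).
#' @param frame_interval time per frame (default 1; output in the same
#'   unit times frames).
#' @param reversible passed to [transition_matrix()].
#' @return data.frame: `lag`, `lag_time`, `t1`, `t2`, ... (same time unit
#'   as `frame_interval`); `NA` where an eigenvalue is (numerically) 1
#'   or the model has too few states.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 3L,
                               frame_interval = 1, reversible = TRUE) {
  if (length(lags) < 2L) stop("need at least 2 lags")
  rows <- lapply(sort(lags), function(tau) {
    est <- transition_matrix(count_matrix(dtrajs, tau), reversible)
    ev <- eigen(est$P)$values
    if (any(abs(Im(ev)) > 1e-12))
      warning("complex eigenvalues at lag ", tau, "; using moduli")
    mod <- sort(Mod(ev), decreasing = TRUE)
    mod <- mod[-1L]                     # drop the unit eigenvalue
    ts <- rep(NA_real_, n_timescales)
    for (i in seq_len(min(n_timescales, length(mod)))) {
      if (mod[i] > 0 && mod[i] < 1 - 1e-12)
        ts[i] <- -tau * frame_interval / log(mod[i])
    }
    c(lag = tau, lag_time = tau * frame_interval,
      stats::setNames(ts, paste0("t", seq_len(n_timescales))))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Lump microstates into metastable macrostates
#'
#' Spectral lumping: k-means on the leading right eigenvectors of the
#' transition matrix (each eigenvector scaled by its eigenvalue, rows
#' weighted by the stationary distribution), a compact stand-in for
#' membership-based spectral methods. Deterministic given the seed.
#'
#' @param P row-stochastic transition matrix.
#' @param n_states number of macrostates (2..k).
#' @param pi stationary distribution (recomputed if `NULL`).
#' @param seed RNG seed for the k-means step.
#' @return integer vector: macrostate (1..n_states) of each microstate.
#' @export
lump_metastable <- function(P, n_states, pi = NULL, seed = 1L) {
  k <- nrow(P)
  if (n_states < 1L || n_states > k) stop("need 1 <= n_states <= k")
  if (n_states == k) return(seq_len(k))
  if (n_states == 1L) return(rep(1L, k))
  e <- eigen(P)
  ord <- order(Mod(e$values), decreasing = TRUE)
  ev <- Re(e$vectors[, ord[seq_len(n_states)], drop = FALSE])
  lam <- Re(e$values[ord[seq_len(n_states)]])
  gap_idx <- n_states
  if (Mod(e$values[ord[min(n_states + 1L, k)]]) >
      Mod(e$values[ord[n_states]]) - 1e-12 && n_states < k)
    warning("no spectral gap after ", n_states, " eigenvalues; ",
            "lumping may be ill-defined")
  if (is.null(pi)) {
    el <- eigen(t(P))
    i <- which.max(Re(el$values))
    v <- Re(el$vectors[, i]); pi <- abs(v) / sum(abs(v))
  }
  feat <- sweep(ev, 2L, lam, `*`) * sqrt(pi)
  km <- withr::with_seed(seed,
    stats::kmeans(feat, centers = n_states, nstart = 20L, iter.max = 100L))
  as.integer(km$cluster)
}

#' Suggest the number of metastable states from the spectral gap
#'
#' Picks `m` maximising the relative gap between consecutive eigenvalue
#' moduli of the transition matrix, within `[2, max_states]`. Heuristic.
#'
#' @param P transition matrix.
#' @param max_states largest number of macrostates considered (default 8).
#' @return integer.
#' @export
n_metastable_auto <- function(P, max_states = 8L) {
  ev <- sort(Mod(eigen(P, only.values = TRUE)$values), decreasing = TRUE)
  upper <- min(max_states, length(ev) - 1L)
  if (upper < 2L) return(2L)
  gaps <- ev[2:upper] - ev[3:(upper + 1L)]
  as.integer(which.max(gaps) + 1L)
}

#' Chapman-Kolmogorov test on macrostates
#'
#' Compares macrostate self-transition probabilities predicted by powering
#' the lag-`tau` model, `(P(tau))^k`, against models re-estimated at `k tau`,
#' for each factor `k`. A bootstrap over trajectories provides a confidence
#' band for the re-estimated probabilities.
#'
#' @param dtrajs discrete trajectories.
#' @param lag base lag (frames).
#' @param factors integer multiples of the lag to test (default 2:4).
#' @param n_macrostates number of metastable states for the lumping.
#' @param n_boot bootstrap resamples of whole trajectories (default 100).
#' @param conf confidence level of the band (default 0.95).
#' @param seed RNG seed.
#' @return data.frame: `factor`, `macrostate`, `predicted`, `estimated`,
#'   `deviation`, `lower`, `upper`, `within_band`.
#' @export
ck_test <- function(dtrajs, lag, factors = c(2L, 3L, 4L), n_macrostates = 2L,
                    n_boot = 100L, conf = 0.95, seed = 1L) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  est <- transition_matrix(count_matrix(dtrajs, lag))
  lump <- lump_metastable(est$P, n_macrostates, est$pi, seed = seed)
  # map microstate labels to macrostates; states outside the active set -> NA
  micro2macro <- rep(NA_integer_, max(unlist(dtrajs)))
  micro2macro[est$active] <- lump
  mtrajs <- lapply(dtrajs, function(d) micro2macro[d])
  macro_P <- function(trajs, tau) {
    C <- matrix(0, n_macrostates, n_macrostates)
    for (d in trajs) {
      if (length(d) <= tau) next
      from <- d[seq_len(length(d) - tau)]
      to <- d[(tau + 1L):length(d)]
      ok <- !is.na(from) & !is.na(to)
      if (!any(ok)) next
      C <- C + unclass(table(factor(from[ok], levels = seq_len(n_macrostates)),
                             factor(to[ok], levels = seq_len(n_macrostates))))
    }
    rs <- rowSums(C)
    if (any(rs == 0)) return(NULL)
    C / rs
  }
  P1 <- macro_P(mtrajs, lag)
  if (is.null(P1)) stop("insufficient pairs at the base lag")
  alpha <- (1 - conf) / 2
  rows <- list()
  boot_idx <- withr::with_seed(seed, replicate(n_boot,
    sample.int(length(mtrajs), replace = TRUE), simplify = FALSE))
  for (k in factors) {
    tauk <- as.integer(k * lag)
    Pk_est <- macro_P(mtrajs, tauk)
    if (is.null(Pk_est)) {
      warning("factor ", k, " skipped: insufficient pairs at lag ", tauk)
      next
    }
    Pk_pred <- matrix_power(P1, k)
    boot <- vapply(boot_idx, function(ix) {
      Pb <- macro_P(mtrajs[ix], tauk)
      if (is.null(Pb)) rep(NA_real_, n_macrostates) else diag(Pb)
    }, numeric(n_macrostates))
    boot <- matrix(boot, nrow = n_macrostates)
    for (s in seq_len(n_macrostates)) {
      bi <- boot[s, ]; bi <- bi[is.finite(bi)]
      lo <- if (length(bi)) stats::quantile(bi, alpha, names = FALSE) else NA
      hi <- if (length(bi)) stats::quantile(bi, 1 - alpha, names = FALSE)
            else NA
      rows[[length(rows) + 1L]] <- data.frame(
        factor = k, macrostate = s,
        predicted = Pk_pred[s, s], estimated = Pk_est[s, s],
        deviation = abs(Pk_pred[s, s] - Pk_est[s, s]),
        lower = lo, upper = hi,
        within_band = !is.na(lo) && Pk_pred[s, s] >= lo &&
          Pk_pred[s, s] <= hi)
    }
  }
  do.call(rbind, rows)
}

matrix_power <- function(P, k) {
  out <- diag(nrow(P))
  for (i in seq_len(k)) out <- out %*% P
  out
}

#' Mean first-passage time between state sets
#'
#' Solves the linear system `m_i = tau + sum_j P_ij m_j` with `m_i = 0` on
#' the sink set and returns the stationary-weighted average of `m` over the
#' source set (weights restricted to the source and renormalised).
#'
#' @param P row-stochastic transition matrix.
#' @param source,sink disjoint non-empty integer sets of state indices.
#' @param lag_time time per lag step `tau` (default 1).
#' @param pi stationary distribution (recomputed if `NULL`).
#' @return scalar mean first-passage time (units of `lag_time`).
#' @export
mfpt <- function(P, source, sink, lag_time = 1, pi = NULL) {
  k <- nrow(P)
  source <- as.integer(source); sink <- as.integer(sink)
  if (length(source) == 0L || length(sink) == 0L)
    stop("source and sink must be non-empty")
  if (length(intersect(source, sink)) > 0L)
    stop("source and sink must be disjoint")
  notsink <- setdiff(seq_len(k), sink)
  A <- diag(length(notsink)) - P[notsink, notsink, drop = FALSE]
  m <- tryCatch(solve(A, rep(lag_time, length(notsink))),
                error = function(e)
                  stop("absorbing failure: sink unreachable from source"))
  if (any(!is.finite(m)) || any(m < 0))
    stop("absorbing failure: sink unreachable from source")
  mf <- numeric(k); mf[notsink] <- m
  if (is.null(pi)) {
    e <- eigen(t(P)); i <- which.max(Re(e$values))
    v <- Re(e$vectors[, i]); pi <- abs(v) / sum(abs(v))
  }
  w <- pi[source] / sum(pi[source])
  sum(w * mf[source])
}

#' Association/dissociation rates and their ratio from MFPTs
#'
#' `k_on = 1 / mfpt_on`, `k_off = 1 / mfpt_off`; the equilibrium
#' dissociation constant estimate is the dimensionless ratio
#' `k_d = k_off / k_on = mfpt_on / mfpt_off`. Unit conversion to molar
#' quantities (a volume/concentration factor) is left to the caller.
#'
#' @param mfpt_on mean first-passage time bulk -> bound (association).
#' @param mfpt_off mean first-passage time bound -> bulk (dissociation).
#' @return list of class `kinetic_estimates`: `mfpt_on`, `mfpt_off`,
#'   `k_on`, `k_off`, `k_d`.
#' @export
rates_and_kd <- function(mfpt_on, mfpt_off) {
  if (!is.finite(mfpt_on) || !is.finite(mfpt_off) ||
      mfpt_on <= 0 || mfpt_off <= 0)
    stop("MFPTs must be positive and finite")
  structure(list(mfpt_on = mfpt_on, mfpt_off = mfpt_off,
                 k_on = 1 / mfpt_on, k_off = 1 / mfpt_off,
                 k_d = mfpt_on / mfpt_off),
            class = "kinetic_estimates")
}

#' @export
print.kinetic_estimates <- function(x, ...) {
  cat(sprintf("MFPT on %.4g, off %.4g; k_on %.4g, k_off %.4g, k_d %.4g\n",
              x$mfpt_on, x$mfpt_off, x$k_on, x$k_off, x$k_d))
  invisible(x)
}

#' Automatic source/sink selection from state fingerprints
#'
#' Sink = metastable states whose median ligand-to-catalytic-machinery
#' distance lies in the cavity (below `r_cavity`); source = states
#' predominantly in the bulk (median beyond `r_bulk`). Falls back to the
#' states with the smallest / largest median when no state qualifies.
#'
#' @param medians numeric vector: median `d_cat` per metastable state.
#' @param r_cavity,r_bulk region cutoffs (Angstrom).
#' @return list with integer `source` and `sink` index sets.
#' @export
select_source_sink <- function(medians, r_cavity = 5, r_bulk = 19) {
  sink <- which(medians <= r_cavity)
  source <- which(medians > r_bulk)
  if (length(sink) == 0L) sink <- which.min(medians)
  if (length(source) == 0L) source <- which.max(medians)
  if (length(intersect(source, sink)) > 0L)
    stop("source and sink overlap; adjust cutoffs")
  list(source = source, sink = sink)
}
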