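# Hierarchical density-based clustering (HDBSCAN*) on a small point set.
#
# Pipeline: core distances -> mutual-reachability graph -> minimum spanning
# tree (Prim) -> single-linkage hierarchy -> condensed tree at
# min_cluster_size -> excess-of-mass cluster selection. The whole-data root
# cluster is selectable ("single cluster allowed"); points attached directly
# to a selected root are labeled only if they persist to the maximal density
# level, so an isolated outlier next to one tight group stays noise.
#
# Complexity is O(n^2 log n); intended for the few dozen to few hundred
# metastable states a unification run compares, not for raw frames.

#' HDBSCAN clustering
#'
#' @param X numeric matrix, rows are points.
#' @param min_cluster_size smallest group treated as a cluster (default 2).
#' @param min_samples neighborhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @param allow_single_cluster may the root (all-data) cluster be selected
#'   (default `TRUE`)?
#' @return integer vector of cluster labels (1, 2, ...), `NA` for noise.
#' @export
hdbscan_cluster <- function(X, min_cluster_size = 2L,
                            min_samples = min_cluster_size,
                            allow_single_cluster = TRUE) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("scores must be finite")
  n <- nrow(X)
  if (n < min_cluster_size || n < 2L) return(rep(NA_integer_, n))

  D <- as.matrix(stats::dist(X))
  # core distance: k-th nearest including the point itself at rank 1
  k <- min(min_samples, n)
  core <- apply(D, 1L, function(r) sort(r, partial = k)[k])
  MR <- pmax(D, outer(core, core, pmax))

  mst <- prim_mst(MR)
  hc <- single_linkage(mst, n)
  ct <- condense_tree(hc, n, min_cluster_size)
  select_and_label(ct, n, allow_single_cluster)
}

# Prim's MST on a dense weight matrix; returns edges (from,to,weight)
prim_mst <- function(W) {
  n <- nrow(W)
  in_tree <- logical(n); in_tree[1L] <- TRUE
  best <- W[1L, ]; best_from <- rep(1L, n)
  edges <- matrix(NA_real_, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges[e, ] <- c(best_from[v], v, best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & W[v, ] < best
    best[upd] <- W[v, upd]; best_from[upd] <- v
  }
  edges
}

# single-linkage dendrogram from MST edges.
# Nodes 1..n are points; internal nodes n+1..2n-1 carry (left,right,height,size).
single_linkage <- function(edges, n) {
  ord <- order(edges[, 3L])
  parent_of <- seq_len(2L * n - 1L)   # union-find with path halving
  node_of <- seq_len(2L * n - 1L)     # current dendrogram node of each root
  find <- function(i) {
    while (parent_of[i] != i) {
      parent_of[i] <<- parent_of[parent_of[i]]
      i <- parent_of[i]
    }
    i
  }
  left <- right <- integer(n - 1L); height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  for (e in seq_len(n - 1L)) {
    i <- edges[ord[e], 1L]; j <- edges[ord[e], 2L]
    ri <- find(i); rj <- find(j)
    node <- n + e
    left[e] <- node_of[ri]; right[e] <- node_of[rj]
    height[e] <- edges[ord[e], 3L]
    size[node] <- size[left[e]] + size[right[e]]
    parent_of[rj] <- ri
    node_of[ri] <- node
  }
  list(left = left, right = right, height = height, size = size, n = n)
}

# condensed tree: walk from the root; a split where both sides reach
# min_cluster_size creates two child clusters, otherwise the undersized
# side's points fall out of the current cluster at this density level.
condense_tree <- function(hc, n, mcs) {
  lam <- function(d) 1 / max(d, .Machine$double.xmin)
  parent <- integer(0); child <- integer(0)     # child > 0: cluster id
  lambda <- numeric(0); child_size <- integer(0) # child < 0: -point index
  next_cluster <- 1L
  add <- function(p, c, l, s) {
    parent[length(parent) + 1L] <<- p
    child[length(child) + 1L] <<- c
    lambda[length(lambda) + 1L] <<- l
    child_size[length(child_size) + 1L] <<- s
  }
  leaves_under <- function(node) {
    if (node <= n) return(node)
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out[length(out) + 1L] <- v
      else {
        e <- v - n
        stack <- c(stack, hc$left[e], hc$right[e])
      }
    }
    out
  }
  root_node <- 2L * n - 1L
  stack <- list(list(node = root_node, cluster = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    e <- top$node - n
    l <- lam(hc$height[e])
    kids <- c(hc$left[e], hc$right[e])
    sz <- hc$size[kids]
    big <- sz >= mcs
    if (all(big)) {
      for (kid in kids) {
        next_cluster <- next_cluster + 1L
        add(top$cluster, next_cluster, l, hc$size[kid])
        if (kid > n)
          stack[[length(stack) + 1L]] <- list(node = kid,
                                              cluster = next_cluster)
        else  # a bare point can only be a cluster if mcs == 1
          add(next_cluster, -kid, l, 1L)
      }
    } else {
      for (w in 1:2) {
        kid <- kids[w]
        if (big[w]) {
          if (kid > n)
            stack[[length(stack) + 1L]] <- list(node = kid,
                                                cluster = top$cluster)
          else add(top$cluster, -kid, l, 1L)
        } else {
          for (p in leaves_under(kid)) add(top$cluster, -p, l, 1L)
        }
      }
    }
  }
  list(parent = parent, child = child, lambda = lambda,
       child_size = child_size, n_clusters = next_cluster)
}

# excess-of-mass selection and point labeling
select_and_label <- function(ct, n, allow_single_cluster) {
  nc <- ct$n_clusters
  birth <- rep(0, nc)
  is_cl <- ct$child > 0
  birth[ct$child[is_cl]] <- ct$lambda[is_cl]
  stability <- numeric(nc)
  for (i in seq_along(ct$parent)) {
    p <- ct$parent[i]
    stability[p] <- stability[p] +
      (ct$lambda[i] - birth[p]) * ct$child_size[i]
  }
  kids_of <- split(ct$child[is_cl], ct$parent[is_cl])
  value <- numeric(nc); selected <- logical(nc)
  for (c in rev(seq_len(nc))) {        # children always have larger ids
    kids <- kids_of[[as.character(c)]]
    subtotal <- if (is.null(kids)) 0 else sum(value[kids])
    if (is.null(kids) || stability[c] > subtotal) {
      selected[c] <- TRUE
      value[c] <- stability[c]
      if (!is.null(kids)) {            # deselect the whole subtree
        stack <- kids
        while (length(stack)) {
          v <- stack[length(stack)]; stack <- stack[-length(stack)]
          selected[v] <- FALSE
          more <- kids_of[[as.character(v)]]
          if (!is.null(more)) stack <- c(stack, more)
        }
      }
    } else {
      value[c] <- subtotal
    }
  }
  if (!allow_single_cluster) selected[1L] <- FALSE

  # nearest selected ancestor of each cluster
  parent_cl <- rep(NA_integer_, nc)
  parent_cl[ct$child[is_cl]] <- ct$parent[is_cl]
  sel_anc <- function(c) {
    while (!is.na(c)) {
      if (selected[c]) return(c)
      c <- parent_cl[c]
    }
    NA_integer_
  }
  labels <- rep(NA_integer_, n)
  pt <- !is_cl
  root_max_lambda <- if (any(ct$parent == 1L))
    max(ct$lambda[ct$parent == 1L]) else Inf
  for (i in which(pt)) {
    p <- -ct$child[i]
    anc <- sel_anc(ct$parent[i])
    if (is.na(anc)) next
    if (anc == 1L && ct$parent[i] == 1L &&
        ct$lambda[i] < root_max_lambda) next  # root core only
    labels[p] <- anc
  }
  # renumber compactly in order of first appearance
  seen <- unique(labels[!is.na(labels)])
  match(labels, seen)
}
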