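#' Parameters of the bottleneck-transit tracker
#'
#' @param bt_cutoff_along half-width (Angstrom) of the band around the tunnel
#'   length within which the ligand is considered to be at the bottleneck;
#'   default 2.0.
#' @param bt_cutoff_across maximum lateral ligand-to-bottleneck distance
#'   (Angstrom) for the bottleneck to count as identified; beyond it a band
#'   frame is an unknown bottleneck; default 5.0.
#' @param dist_tolerance tolerance (Angstrom) used to reconcile a closest-
#'   tunnel mismatch between the two end points of a direct crossing;
#'   default 1.0.
#' @return object of class `transit_params`.
#' @export
transit_params <- function(bt_cutoff_along = 2.0, bt_cutoff_across = 5.0,
                           dist_tolerance = 1.0) {
  p <- list(bt_cutoff_along = bt_cutoff_along,
            bt_cutoff_across = bt_cutoff_across,
            dist_tolerance = dist_tolerance)
  if (any(vapply(p, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all transit parameters must be positive")
  structure(p, class = "transit_params")
}

#' Assign a per-frame ligand position state relative to the tunnel network
#'
#' For each frame the closest bottleneck `T*` (smallest `d_bt`; ties broken
#' by canonical tunnel order) fixes the reference tunnel length `L`.
#' With `d = d_cat`:
#' \itemize{
#'   \item `out_` (bulk) when `d > L + bt_cutoff_along`;
#'   \item `in_` (inside) when `d < L - bt_cutoff_along`;
#'   \item otherwise the ligand sits in the bottleneck band:
#'     `bt_` when `d_bt[T*] <= bt_cutoff_across`, `bt_unknown` beyond.
#' }
#' Band boundaries are inclusive (`|d - L| == bt_cutoff_along` is band).
#'
#' @param ds a `distance_series`.
#' @param params a [transit_params()].
#' @return data.frame with one row per frame: `frame`, `kind`
#'   (`out_`, `in_`, `bt_`, `bt_unknown`), `tunnel` (closest bottleneck id).
#' @export
assign_position <- function(ds, params = transit_params()) {
  stopifnot(inherits(ds, "distance_series"))
  if (ncol(ds$d_bt) == 0L) stop("empty tunnel set")
  ids <- colnames(ds$d_bt)
  closest <- apply(ds$d_bt, 1L, which.min)   # first index wins ties
  n <- ds$n_frames
  Lstar <- ds$L[cbind(seq_len(n), closest)]
  bstar <- ds$d_bt[cbind(seq_len(n), closest)]
  d <- ds$d_cat
  kind <- rep("bt_", n)
  kind[d > Lstar + params$bt_cutoff_along] <- "out_"
  kind[d < Lstar - params$bt_cutoff_along] <- "in_"
  band <- kind == "bt_"
  kind[band & bstar > params$bt_cutoff_across] <- "bt_unknown"
  data.frame(frame = seq_len(n), kind = kind, tunnel = ids[closest],
             stringsAsFactors = FALSE)
}

# tolerance-based reconciliation of a closest-tunnel mismatch between the two
# end-point frames of a direct crossing. d_bt_a / d_bt_b are the full
# per-tunnel distance rows at the origin (a) and destination (b) frames.
# The destination side is offered the swap first; if neither side can be
# relabeled within the tolerance, the crossing is "mixed".
resolve_direct_category <- function(t_a, t_b, d_bt_a, d_bt_b, tol) {
  if (identical(t_a, t_b)) return(t_a)
  if (d_bt_b[t_a] - d_bt_b[t_b] <= tol) return(t_a)  # relabel destination
  if (d_bt_a[t_b] - d_bt_a[t_a] <= tol) return(t_b)  # relabel origin
  "mixed"
}

#' Detect completed bulk-interior transitions
#'
#' Walks the per-frame position states of one trajectory with a small state
#' machine and emits every completed crossing between the bulk (`out_`) and
#' the protein interior (`in_`):
#' \itemize{
#'   \item a direct `in_ <-> out_` flip between consecutive general-state
#'     frames yields a *direct* event whose category is the common closest
#'     tunnel of the two end points, reconciled within `dist_tolerance` when
#'     the sides disagree, else `mixed`;
#'   \item a crossing that visits the bottleneck band yields a
#'     *via_bottleneck* event categorised by the band state of the last band
#'     frame before the exit (`unknown` if that frame was `bt_unknown`);
#'   \item a band excursion that returns to the side it came from yields no
#'     event.
#' }
#' Leading band frames before the first `in_`/`out_` frame are ignored.
#'
#' @param ds a `distance_series`.
#' @param params a [transit_params()].
#' @param positions optional precomputed [assign_position()] table.
#' @return data.frame of events: `start_frame` (last frame on the origin
#'   side), `end_frame` (first frame on the destination side), `direction`
#'   (`in_out` or `out_in`), `mediation` (`direct` or `via_bottleneck`),
#'   `category` (tunnel id, `mixed`, or `unknown`). Zero rows when no
#'   transition completed.
#' @export
detect_transitions <- function(ds, params = transit_params(),
                               positions = NULL) {
  stopifnot(inherits(ds, "distance_series"))
  if (is.null(positions)) positions <- assign_position(ds, params)
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      direction = character(), mediation = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (nrow(positions) == 0L) return(empty)

  events <- list()
  general <- NA_character_      # "in_" / "out_" of the current origin side
  general_frame <- NA_integer_  # last frame seen on that side
  temp_bt <- NULL               # band memory: tunnel id or "unknown"

  emit <- function(start, end, direction, mediation, category) {
    events[[length(events) + 1L]] <<- data.frame(
      start_frame = start, end_frame = end, direction = direction,
      mediation = mediation, category = category, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(positions))) {
    kind <- positions$kind[i]
    if (kind %in% c("bt_", "bt_unknown")) {
      if (!is.na(general))   # leading band frames carry no memory
        temp_bt <- if (kind == "bt_") positions$tunnel[i] else "unknown"
      next
    }
    # kind is a general state (in_ / out_)
    if (is.na(general)) {
      general <- kind; general_frame <- i
      temp_bt <- NULL
      next
    }
    if (kind == general) {            # same side: refresh, drop band memory
      general <- kind; general_frame <- i
      temp_bt <- NULL
      next
    }
    # opposite side: a transition completed
    direction <- if (general == "in_") "in_out" else "out_in"
    if (is.null(temp_bt)) {
      category <- resolve_direct_category(
        positions$tunnel[general_frame], positions$tunnel[i],
        ds$d_bt[general_frame, ], ds$d_bt[i, ], params$dist_tolerance)
      emit(general_frame, i, direction, "direct", category)
    } else {
      emit(general_frame, i, direction, "via_bottleneck", temp_bt)
    }
    general <- kind; general_frame <- i
    temp_bt <- NULL
  }
  if (length(events) == 0L) empty else do.call(rbind, events)
}

#' Tunnel utilization summary across trajectories, replicates and schemes
#'
#' Counts completed transitions per category (each tunnel id, `mixed`,
#' `unknown`) for every trajectory, sums them per replicate, and summarises
#' each seeding scheme as mean +/- sample standard deviation over its
#' replicate totals, together with relative utilization fractions.
#'
#' @param events data.frame of transition events carrying metadata columns
#'   `scheme`, `replicate`, `trajectory` in addition to the
#'   [detect_transitions()] columns. Zero rows allowed.
#' @param categories character vector fixing category order; defaults to the
#'   categories present (tunnels first, then `mixed`, `unknown`).
#' @return list of class `utilization_table`:
#'   `per_trajectory`, `per_replicate` (counts), `per_scheme`
#'   (`mean`/`sd`/fraction per category), each a data.frame.
#' @export
count_utilization <- function(events, categories = NULL) {
  needed <- c("scheme", "replicate", "trajectory", "category")
  if (nrow(events) > 0L && !all(needed %in% names(events)))
    stop("events must carry columns: ", paste(needed, collapse = ", "))
  if (is.null(categories)) {
    cats <- unique(events$category)
    categories <- c(sort(setdiff(cats, c("mixed", "unknown"))),
                    intersect(c("mixed", "unknown"), cats))
  }
  if (length(categories) == 0L) categories <- "none"
  count_block <- function(df, keys) {
    grp <- interaction(df[keys], drop = TRUE, lex.order = TRUE)
    rows <- lapply(split(df, grp), function(d) {
      cnt <- table(factor(d$category, levels = categories))
      cbind(d[1L, keys, drop = FALSE],
            as.data.frame.matrix(t(as.matrix(cnt))),
            total = sum(cnt))
    })
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  }
  if (nrow(events) == 0L) {
    per_traj <- per_rep <- NULL
    per_scheme <- data.frame()
  } else {
    per_traj <- count_block(events, c("scheme", "replicate", "trajectory"))
    per_rep <- count_block(events, c("scheme", "replicate"))
    rows <- lapply(split(per_rep, per_rep$scheme), function(d) {
      m <- as.matrix(d[, categories, drop = FALSE])
      mu <- colMeans(m)
      sdv <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) else rep(NA_real_,
                                                                ncol(m))
      tot <- sum(m)
      data.frame(scheme = d$scheme[1L], category = categories,
                 mean = as.numeric(mu), sd = as.numeric(sdv),
                 count = as.numeric(colSums(m)),
                 fraction = if (tot > 0) as.numeric(colSums(m)) / tot else 0,
                 stringsAsFactors = FALSE)
    })
    per_scheme <- do.call(rbind, rows); rownames(per_scheme) <- NULL
  }
  structure(list(per_trajectory = per_traj, per_replicate = per_rep,
                 per_scheme = per_scheme, categories = categories),
            class = "utilization_table")
}

#' @export
print.utilization_table <- function(x, ...) {
  cat("Tunnel utilization (categories:",
      paste(x$categories, collapse = ", "), ")\n")
  if (!is.null(x$per_scheme) && nrow(x$per_scheme) > 0L)
    print(x$per_scheme)
  else cat("  no events\n")
  invisible(x)
}
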