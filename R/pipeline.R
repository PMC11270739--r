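#' Build a Markov state model from distance series
#'
#' Featurizes each trajectory as `(d_cat, d_bt[tunnels])`, reduces with
#' TICA, discretises into microstates with seeded k-means, estimates the
#' transition matrix at the MSM lag, lumps microstates into metastable
#' macrostates spectrally, and extracts per-macrostate representative
#' distance ensembles, source/sink sets and first-passage kinetics.
#'
#' Lag times given in nanoseconds are converted to frames through the
#' frame interval of the first series; microstate and representative
#' counts are capped by the data actually available.
#'
#' @param series list of `distance_series` (one MSM over all of them).
#' @param config configuration list, see [default_config()].
#' @param seed RNG seed for the clustering steps.
#' @return list of class `msm_result`: `tica`, `dtrajs`, `estimate`
#'   (`P`, `pi`, `active`), `lumping`, `n_metastable`, `macro_pi`,
#'   `ensembles` (per-macrostate distance matrices), `fingerprints`,
#'   `source`, `sink`, `kinetics` ([rates_and_kd()] output, times in ns),
#'   `lag_frames`, `frame_interval`.
#' @export
build_msm <- function(series, config = default_config(), seed = 1L) {
  if (inherits(series, "distance_series")) series <- list(series)
  fi <- series[[1L]]$frame_interval            # ps per frame
  feats <- lapply(series, function(s) cbind(d_cat = s$d_cat, s$d_bt))
  ns_to_frames <- function(ns) max(1L, as.integer(round(ns * 1000 / fi)))
  tica_lag <- ns_to_frames(config$tica_lag_ns)
  msm_lag <- ns_to_frames(config$msm_lag_ns)
  tic <- tica(feats, lag = tica_lag, n_dims = config$n_tica_dims)
  total <- nrow(tic$y)
  k <- min(config$n_microstates, max(2L, total %/% 5L),
           nrow(unique(round(tic$y, 8))))
  cl <- cluster_microstates(tic$y, k, seed = seed)
  lens <- vapply(feats, nrow, integer(1))
  dtrajs <- split(cl$assignments, rep(seq_along(lens), lens))
  C <- count_matrix(dtrajs, msm_lag, n_states = k)
  est <- transition_matrix(C, reversible = config$reversible)
  n_meta <- config$n_metastable
  if (identical(n_meta, "auto")) n_meta <- n_metastable_auto(est$P)
  n_meta <- min(as.integer(n_meta), nrow(est$P))
  lump <- lump_metastable(est$P, n_meta, est$pi, seed = seed)
  micro2macro <- rep(NA_integer_, k)
  micro2macro[est$active] <- lump
  frame_macro <- micro2macro[cl$assignments]
  macro_pi <- vapply(seq_len(n_meta), function(s)
    sum(est$pi[lump == s]), numeric(1))
  all_feat <- do.call(rbind, feats)
  ens <- lapply(seq_len(n_meta), function(s) {
    idx <- which(frame_macro == s)
    if (length(idx) > config$n_representative)
      idx <- withr::with_seed(seed + s,
        sample(idx, config$n_representative))
    all_feat[idx, , drop = FALSE]
  })
  fp <- t(vapply(ens, state_fingerprint,
                 state_fingerprint(ens[[1L]])))
  medians <- vapply(ens, function(e) stats::median(e[, "d_cat"]),
                    numeric(1))
  ss <- select_source_sink(medians, config$cutoffs$r_cavity,
                           config$cutoffs$r_bulk)
  kin <- tryCatch({
    lag_ns <- msm_lag * fi / 1000
    macro_of_micro <- lump
    src_micro <- which(macro_of_micro %in% ss$source)
    snk_micro <- which(macro_of_micro %in% ss$sink)
    m_on <- mfpt(est$P, src_micro, snk_micro, lag_time = lag_ns, est$pi)
    m_off <- mfpt(est$P, snk_micro, src_micro, lag_time = lag_ns, est$pi)
    rates_and_kd(m_on, m_off)
  }, error = function(e) {
    warning("kinetics unavailable: ", conditionMessage(e))
    NULL
  })
  structure(
    list(tica = tic, dtrajs = dtrajs, estimate = est, lumping = lump,
         n_metastable = n_meta, macro_pi = macro_pi, ensembles = ens,
         fingerprints = fp, state_medians = medians,
         source = ss$source, sink = ss$sink, kinetics = kin,
         lag_frames = msm_lag, frame_interval = fi),
    class = "msm_result"
  )
}

#' @export
print.msm_result <- function(x, ...) {
  cat("MSM:", nrow(x$estimate$P), "microstates,", x$n_metastable,
      "metastable states, lag", x$lag_frames, "frames\n")
  if (!is.null(x$kinetics)) print(x$kinetics)
  invisible(x)
}

#' Run the full analysis pipeline on a set of distance series
#'
#' Composes the stages end to end: region classification and per-epoch
#' occupancy, transit detection and tunnel-utilization summary, one MSM
#' per (scheme, replicate) with first-passage kinetics, metastable-state
#' fingerprints unified across replicates into ULSs with their presence
#' matrix, and a single JSON-serialisable summary. Deterministic given the
#' seed.
#'
#' @param series list of `distance_series`; each must carry `meta$scheme`,
#'   `meta$replicate`, `meta$run` (and ideally `meta$epoch`).
#' @param config configuration list, see [default_config()].
#' @param seed RNG seed.
#' @param json_path optional path: write the summary as JSON.
#' @return list of class `pipeline_result`: `region_fractions`, `events`,
#'   `utilization`, `msm` (per replicate), `uls`, `presence`, `kinetics`
#'   (per replicate + mean), `config`.
#' @export
run_pipeline <- function(series, config = default_config(), seed = 1L,
                         json_path = NULL) {
  if (length(series) == 0L) stop("empty manifest: no distance series")
  for (i in seq_along(series)) {
    m <- series[[i]]$meta
    if (is.null(m$scheme)) series[[i]]$meta$scheme <- "default"
    if (is.null(m$replicate)) series[[i]]$meta$replicate <- 1L
    if (is.null(m$run)) series[[i]]$meta$run <- i
    if (is.null(m$epoch)) series[[i]]$meta$epoch <- 1L
  }
  cut <- config$cutoffs
  tp <- transit_params_from_config(config)

  frac <- epoch_region_fractions(series, cut$r_cavity, cut$r_bulk)

  events <- do.call(rbind, lapply(series, function(s) {
    ev <- detect_transitions(s, tp)
    if (nrow(ev) == 0L) return(NULL)
    cbind(scheme = s$meta$scheme, replicate = s$meta$replicate,
          trajectory = s$meta$run, ev, stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(scheme = character(), replicate = integer(),
                         trajectory = integer(), start_frame = integer(),
                         end_frame = integer(), direction = character(),
                         mediation = character(), category = character())
  util <- count_utilization(events)

  key <- vapply(series, function(s)
    paste(s$meta$scheme, s$meta$replicate, sep = "|"), character(1))
  groups <- split(series, key)
  msms <- lapply(groups, build_msm, config = config, seed = seed)

  state_meta <- list(); fps <- list()
  for (g in names(msms)) {
    mm <- msms[[g]]
    sr <- strsplit(g, "|", fixed = TRUE)[[1L]]
    for (s in seq_len(mm$n_metastable)) {
      sid <- sprintf("%s_rep%s_ms%d", sr[1L], sr[2L], s)
      state_meta[[sid]] <- data.frame(
        state = sid, scheme = sr[1L], replicate = sr[2L],
        probability = mm$macro_pi[s], stringsAsFactors = FALSE)
      fps[[sid]] <- mm$fingerprints[s, ]
    }
  }
  state_meta <- do.call(rbind, state_meta)
  Fm <- do.call(rbind, fps)
  uls <- NULL; pres <- NULL
  if (nrow(Fm) >= 2L) {
    red <- reduce_fingerprints(Fm, n_components = min(3L, ncol(Fm)))
    uls <- cluster_uls(red$scores, config$min_cluster_size,
                       state_ids = rownames(Fm))
    pres <- presence_matrix(uls, state_meta)
  }

  kin <- lapply(msms, function(m) m$kinetics)
  kd <- vapply(kin, function(k2) if (is.null(k2)) NA_real_ else k2$k_d,
               numeric(1))

  out <- structure(
    list(region_fractions = frac, events = events, utilization = util,
         msm = msms, uls = uls, presence = pres,
         kinetics = list(per_replicate = kin,
                         k_d = kd, k_d_mean = mean(kd, na.rm = TRUE)),
         config = config, seed = seed),
    class = "pipeline_result"
  )
  if (!is.null(json_path))
    jsonlite::write_json(pipeline_summary(out), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  out
}

#' JSON-serialisable summary of a pipeline run
#'
#' @param x a [run_pipeline()] result.
#' @return plain list (config echo, region fractions, utilization,
#'   per-replicate MSM/kinetics summaries, ULS assignment and presence).
#' @export
pipeline_summary <- function(x) {
  msum <- lapply(x$msm, function(m) list(
    n_microstates = nrow(m$estimate$P),
    n_metastable = m$n_metastable,
    macro_pi = as.numeric(m$macro_pi),
    source = m$source, sink = m$sink,
    mfpt_on_ns = if (!is.null(m$kinetics)) m$kinetics$mfpt_on else NULL,
    mfpt_off_ns = if (!is.null(m$kinetics)) m$kinetics$mfpt_off else NULL,
    k_d = if (!is.null(m$kinetics)) m$kinetics$k_d else NULL))
  list(
    config = x$config,
    seed = x$seed,
    region_fractions = x$region_fractions,
    utilization = list(per_replicate = x$utilization$per_replicate,
                       per_scheme = x$utilization$per_scheme),
    n_events = nrow(x$events),
    msm = msum,
    uls = if (!is.null(x$uls)) as.data.frame(x$uls) else NULL,
    presence = if (!is.null(x$presence)) {
      p <- as.data.frame(x$presence)
      cbind(uls = rownames(x$presence), p)
    } else NULL,
    k_d_per_replicate = as.list(x$kinetics$k_d),
    k_d_mean = x$kinetics$k_d_mean
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(x$msm), "replicate MSM(s),",
      nrow(x$events), "transition events,",
      if (!is.null(x$uls)) max(x$uls$uls) else 0, "ULS(s)\n")
  invisible(x)
}
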