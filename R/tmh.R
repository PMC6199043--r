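## tmh: propensity track -> topology, plus the four benchmark metrics.
##
## Segmentation follows the dynamic-threshold idea: threshold the smoothed
## track at T0 = 0.4 (inclusive), then raise the threshold in 0.05 steps
## looking for an interior valley at which a merged segment separates into
## two valid helices. The original split rules are unpublished; the
## explicit surrogate used here accepts the first level at which the
## segment separates into >= 2 pieces, each at least min_tmh_length long,
## with the segment's interior minimum lying at least split_valley_depth
## below that level.

#' Segmenter configuration
#'
#' @param initial_threshold starting propensity cutoff T0 (default 0.4).
#' @param step threshold increment for the dynamic search (default 0.05).
#' @param max_threshold upper bound of the search (default 0.95).
#' @param min_tmh_length minimum helix length kept (default 5).
#' @param median_window odd width of the median smoother (default 5).
#' @param split_valley_depth required depth of the interior valley below
#'   the splitting level (default 0.1).
#' @return a `segmenter_config` list.
#' @export
segmenter_config <- function(initial_threshold = 0.4, step = 0.05,
                             max_threshold = 0.95, min_tmh_length = 5L,
                             median_window = 5L,
                             split_valley_depth = 0.1) {
  if (!(initial_threshold > 0 && initial_threshold < max_threshold &&
        max_threshold <= 1 && step > 0 && median_window %% 2L == 1L &&
        min_tmh_length >= 1L && split_valley_depth >= 0))
    tk_stop("invalid segmenter configuration", "tmhkit_config_error")
  structure(list(initial_threshold = initial_threshold, step = step,
                 max_threshold = max_threshold,
                 min_tmh_length = as.integer(min_tmh_length),
                 median_window = as.integer(median_window),
                 split_valley_depth = split_valley_depth),
            class = "segmenter_config")
}

#' Median-filter a propensity track
#'
#' Value `i` is the median of the track over the window
#' `[i-(w-1)/2, i+(w-1)/2]` intersected with `[1, L]`; the window shrinks
#' at the termini rather than fabricating values. Idempotent on constant
#' tracks.
#'
#' @param track a [propensity_track()] (or bare numeric vector).
#' @param window odd window width (default 5).
#' @return object of the same type as `track`.
#' @export
median_filter <- function(track, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L)
    tk_stop("median filter window must be odd", "tmhkit_config_error")
  v <- if (inherits(track, "propensity_track")) track$values else track
  L <- length(v)
  h <- (window - 1L) %/% 2L
  out <- vapply(seq_len(L), function(i)
    stats::median(v[max(1L, i - h):min(L, i + h)]), numeric(1))
  if (inherits(track, "propensity_track"))
    propensity_track(track$record_id, out)
  else out
}

#' Threshold a track into maximal runs
#'
#' Returns the maximal runs of consecutive positions whose value is
#' greater than or equal to `T` (inclusive comparison).
#'
#' @param track a [propensity_track()] or numeric vector.
#' @param T threshold in (0,1).
#' @return data.frame with columns `start`, `end` (possibly zero rows).
#' @export
threshold_segments <- function(track, T) {
  stopifnot(T > 0, T < 1)
  v <- if (inherits(track, "propensity_track")) track$values else track
  r <- rle(v >= T)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Dynamic-threshold split of one candidate segment
#'
#' Raises the threshold from `T0 + step` up to `max_threshold`; at each
#' level re-thresholds the track restricted to the segment's span and
#' accepts the first level at which the segment separates into at least
#' two pieces, each at least `min_tmh_length` residues, while the
#' segment's interior minimum lies below `level - split_valley_depth`.
#' Accepted pieces are split recursively; if no level qualifies the
#' segment is returned unchanged. Pieces keep the coordinates of the
#' restricted re-thresholding, so valley residues are excluded.
#'
#' @param segment one-row data.frame (or list) with `start` and `end`.
#' @param track a [propensity_track()] or numeric vector.
#' @param config a [segmenter_config()].
#' @return data.frame of segments with columns `start`, `end`.
#' @export
dynamic_split <- function(segment, track, config = segmenter_config()) {
  v <- if (inherits(track, "propensity_track")) track$values else track
  span <- segment$start:segment$end
  sub <- v[span]
  levels <- seq(config$initial_threshold + config$step,
                config$max_threshold, by = config$step)
  for (lev in levels) {
    pieces <- threshold_segments(sub, lev)
    if (nrow(pieces) >= 2L &&
        all(pieces$end - pieces$start + 1L >= config$min_tmh_length) &&
        min(sub) < lev - config$split_valley_depth) {
      pieces$start <- pieces$start + segment$start - 1L
      pieces$end <- pieces$end + segment$start - 1L
      out <- lapply(seq_len(nrow(pieces)), function(p)
        dynamic_split(pieces[p, ], v, config))
      return(do.call(rbind, out))
    }
  }
  data.frame(start = segment$start, end = segment$end)
}

#' Segment a smoothed propensity track into a topology
#'
#' Thresholds at `initial_threshold`, applies [dynamic_split()] to each
#' candidate segment, and drops pieces shorter than `min_tmh_length`.
#' The input is expected to be median-filter smoothed already (see
#' [predict_topology()] for the full pipeline).
#'
#' @param track a [propensity_track()].
#' @param config a [segmenter_config()].
#' @return a [topology()].
#' @export
segment_track <- function(track, config = segmenter_config()) {
  stopifnot(inherits(track, "propensity_track"))
  initial <- threshold_segments(track, config$initial_threshold)
  segs <- if (nrow(initial))
    do.call(rbind, lapply(seq_len(nrow(initial)), function(s)
      dynamic_split(initial[s, ], track, config)))
  else initial
  if (nrow(segs))
    segs <- segs[segs$end - segs$start + 1L >= config$min_tmh_length, ,
                 drop = FALSE]
  topology(track$record_id, segs$start, segs$end)
}

#' Full propensity-to-topology pipeline
#'
#' Median-filter smoothing followed by dynamic-threshold segmentation.
#'
#' @param track a raw [propensity_track()].
#' @param config a [segmenter_config()].
#' @return list with `topology` and the `smoothed` track.
#' @export
predict_topology <- function(track, config = segmenter_config()) {
  sm <- median_filter(track, config$median_window)
  list(topology = segment_track(sm, config), smoothed = sm)
}

## ---- evaluation ----------------------------------------------------------

## Greedy one-to-one matching in sequence order. An observed and a
## predicted helix match if they overlap by at least
## min(5, ceiling(len_observed / 2)) residues.
match_segments <- function(pred, obs) {
  used <- rep(FALSE, nrow(pred))
  matches <- NULL
  for (o in seq_len(nrow(obs))) {
    need <- min(5L, ceiling((obs$end[o] - obs$start[o] + 1L) / 2))
    for (p in seq_len(nrow(pred))) {
      if (nrow(pred) == 0L) break
      if (used[p]) next
      ov <- min(obs$end[o], pred$end[p]) - max(obs$start[o], pred$start[p]) + 1L
      if (ov >= need) {
        used[p] <- TRUE
        matches <- rbind(matches, data.frame(obs = o, pred = p))
        break
      }
    }
  }
  list(matches = matches, used_pred = used)
}

#' Evaluate a predicted topology against the observed one
#'
#' Computes the four segment-level benchmark statistics: `a_tmh`, the
#' fraction of observed helices matched by a prediction; `a_p`, 1 if every
#' observed helix is matched and there is no unmatched prediction (else 0);
#' and the N-/C-scores, the absolute deviation in residues of predicted
#' segment starts/ends from the observed ones over matched pairs.
#'
#' @param predicted,observed [topology()] objects for the same record.
#' @return a `tmh_eval` list with fields `a_tmh`, `a_p`, `n_scores`,
#'   `c_scores` (vectors over matched pairs), `n_obs`, `n_pred`,
#'   `n_matched`.
#' @export
evaluate_topology <- function(predicted, observed) {
  if (!identical(predicted$record_id, observed$record_id))
    tk_stop("topologies refer to different records", "tmhkit_input_error")
  pred <- predicted$segments; obs <- observed$segments
  mm <- match_segments(pred, obs)
  n_matched <- if (is.null(mm$matches)) 0L else nrow(mm$matches)
  n_scores <- c_scores <- numeric(0)
  if (n_matched) {
    n_scores <- abs(pred$start[mm$matches$pred] - obs$start[mm$matches$obs])
    c_scores <- abs(pred$end[mm$matches$pred] - obs$end[mm$matches$obs])
  }
  a_tmh <- if (nrow(obs)) n_matched / nrow(obs) else 1
  a_p <- as.numeric(n_matched == nrow(obs) && all(mm$used_pred))
  structure(list(a_tmh = a_tmh, a_p = a_p,
                 n_scores = n_scores, c_scores = c_scores,
                 n_obs = nrow(obs), n_pred = nrow(pred),
                 n_matched = n_matched),
            class = "tmh_eval")
}

#' Pool topology evaluations over a protein set
#'
#' @param predicted,observed lists of [topology()] objects, index-aligned.
#' @return list with `a_tmh` (pooled over helices), `a_p` (fraction of
#'   fully correct proteins), `n_score_mean`, `n_score_sd`, `c_score_mean`,
#'   `c_score_sd`.
#' @export
evaluate_topology_set <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  evals <- Map(evaluate_topology, predicted, observed)
  n_obs <- sum(vapply(evals, `[[`, 0L, "n_obs"))
  n_matched <- sum(vapply(evals, `[[`, 0L, "n_matched"))
  nsc <- unlist(lapply(evals, `[[`, "n_scores"))
  csc <- unlist(lapply(evals, `[[`, "c_scores"))
  list(a_tmh = if (n_obs) n_matched / n_obs else 1,
       a_p = mean(vapply(evals, `[[`, 0, "a_p")),
       n_score_mean = if (length(nsc)) mean(nsc) else NA_real_,
       n_score_sd = if (length(nsc) > 1) stats::sd(nsc) else NA_real_,
       c_score_mean = if (length(csc)) mean(csc) else NA_real_,
       c_score_sd = if (length(csc) > 1) stats::sd(csc) else NA_real_,
       n_proteins = length(evals))
}
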