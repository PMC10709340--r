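## Feeding-context association via tail-slap proximity.
##
## Herring-feeding killer whales debilitate prey with audible tail slaps,
## so a transition within five minutes of a high-quality tail slap on the
## same tag is taken as produced in a feeding context.

#' Label transition events as feeding / non-feeding
#'
#' An event is feeding iff the nearest same-tag tail slap is within
#' `window_s` seconds, symmetrically (before or after the slap). Tags
#' without slaps get all-non-feeding. Only high-quality slaps are used
#' when a `quality` column is present.
#'
#' @param events Data.frame with `tag_id` and `time_s` (transition events
#'   are timestamped by the start of their first call).
#' @param tail_slaps Data.frame with `tag_id`, `time_s` and optionally
#'   `quality`.
#' @param window_s Half-window (s), default 300 (five minutes).
#' @return `events` with logical `feeding` and `nearest_slap_dt_s`.
#' @export
label_feeding <- function(events, tail_slaps, window_s = 300) {
  if ("quality" %in% names(tail_slaps))
    tail_slaps <- tail_slaps[tail_slaps$quality == "high", , drop = FALSE]
  slap_by_tag <- split(tail_slaps$time_s, tail_slaps$tag_id)
  dt <- vapply(seq_len(nrow(events)), function(i) {
    st <- slap_by_tag[[events$tag_id[i]]]
    if (is.null(st) || !length(st)) return(Inf)
    min(abs(events$time_s[i] - st))
  }, numeric(1))
  events$nearest_slap_dt_s <- dt
  events$feeding <- dt <= window_s
  events
}

#' Per-cluster feeding-context summary
#'
#' @param labeled_events Output of [label_feeding()], carrying a
#'   `cluster_label` column (see [assign_clusters()]).
#' @param clusters Optional `combination_clusters`; clusters with no
#'   events are reported as absent (NA proportion).
#' @return List of class `context_summary`: `per_cluster` (data.frame
#'   label, n_feeding, n_total, proportion_feeding), `overall_n`,
#'   `overall_feeding`, `proportion_feeding_overall`,
#'   `proportion_outside_feeding_overall` (the complement, over all
#'   events — both denominators conventions are reported).
#' @export
context_summary <- function(labeled_events, clusters = NULL) {
  labs <- if (!is.null(clusters) && length(clusters))
    vapply(clusters, `[[`, character(1), "label") else
    sort(unique(stats::na.omit(labeled_events$cluster_label)))
  per <- do.call(rbind, lapply(labs, function(lb) {
    ev <- labeled_events[labeled_events$cluster_label %in% lb, , drop = FALSE]
    data.frame(label = lb, n_feeding = sum(ev$feeding), n_total = nrow(ev),
               proportion_feeding = if (nrow(ev)) mean(ev$feeding) else
                 NA_real_, stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(label = character(0), n_feeding = integer(0),
                      n_total = integer(0), proportion_feeding = numeric(0))
  n_all <- nrow(labeled_events)
  n_feed <- sum(labeled_events$feeding)
  structure(list(per_cluster = per, overall_n = n_all,
                 overall_feeding = n_feed,
                 proportion_feeding_overall = if (n_all) n_feed / n_all else
                   NA_real_,
                 proportion_outside_feeding_overall =
                   if (n_all) 1 - n_feed / n_all else NA_real_),
            class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  cat(sprintf("Feeding context over %d transitions: %.1f%% within window, %.1f%% outside\n",
              x$overall_n, 100 * x$proportion_feeding_overall,
              100 * x$proportion_outside_feeding_overall))
  for (i in seq_len(nrow(x$per_cluster)))
    cat(sprintf("  cluster %s: %.1f%% feeding (n = %d/%d)\n",
                x$per_cluster$label[i],
                100 * x$per_cluster$proportion_feeding[i],
                x$per_cluster$n_feeding[i], x$per_cluster$n_total[i]))
  invisible(x)
}
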