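## Combination-cluster extraction and sequence validation.
##
## Categories linked by significantly over-expected mixed-category
## transitions form a directed graph; its weakly connected components
## (with at least two categories) are the call-combination clusters.
## Same-category repetitions are reported as a separate share and never
## contribute cluster edges.

#' Extract call-combination clusters
#'
#' Builds a directed graph whose edges are the significant over-expected
#' mixed-category cells observed more than `min_count` times (self-loops,
#' i.e. repetitions, excluded) and returns its weakly connected
#' components with >= 2 categories. Clusters are ordered by descending
#' total transition count, ties broken by the lexicographically smallest
#' member, and labeled A, B, C, ...
#'
#' @param cells A `posthoc_cells` data.frame.
#' @param min_count Strict lower bound on edge counts (default 10).
#' @return List of class `combination_clusters`; each element has
#'   `cluster_id`, `label`, `categories`, `edges` (from_cat, to_cat,
#'   count), `n_transitions`.
#' @export
extract_clusters <- function(cells, min_count = 10) {
  edges <- cells[cells$significant_over & cells$from_cat != cells$to_cat &
                   cells$observed > min_count,
                 c("from_cat", "to_cat", "observed"), drop = FALSE]
  names(edges)[3] <- "count"
  rownames(edges) <- NULL
  if (!nrow(edges)) return(structure(list(), class = "combination_clusters"))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  clusters <- lapply(seq_len(comp$no), function(k) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2) return(NULL)
    sub <- edges[edges$from_cat %in% members & edges$to_cat %in% members, ,
                 drop = FALSE]
    rownames(sub) <- NULL
    list(categories = sort(members), edges = sub,
         n_transitions = sum(sub$count))
  })
  clusters <- Filter(Negate(is.null), clusters)
  if (!length(clusters)) return(structure(list(),
                                          class = "combination_clusters"))
  ord <- order(-vapply(clusters, `[[`, numeric(1), "n_transitions"),
               vapply(clusters, function(cl) cl$categories[1], character(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$cluster_id <- i
    clusters[[i]]$label <- LETTERS[i]
  }
  structure(clusters, class = "combination_clusters")
}

## Lookup table "from->to" -> cluster label for edge membership tests.
cluster_edge_map <- function(clusters) {
  if (!length(clusters)) return(character(0))
  unlist(lapply(clusters, function(cl)
    stats::setNames(rep(cl$label, nrow(cl$edges)),
                    paste(cl$edges$from_cat, cl$edges$to_cat, sep = "\r"))))
}

#' Validate multi-call sequences
#'
#' A multi-category sequence is accepted only when every first-order
#' transition in it is both within the BCI and significantly
#' over-expected. Assembly is greedy-maximal left to right within each
#' tag: an embedded longer run is reported once, never as all its
#' sub-runs. A run is assigned a cluster label only when every one of
#' its mixed-category edges is an edge of that single cluster;
#' repetition-only runs and runs touching non-cluster or multi-cluster
#' edges carry NA.
#'
#' @param calls Retained, categorized calls (per tag, sorted).
#' @param bci_s Gap threshold (s).
#' @param cells A `posthoc_cells` data.frame (the significant pairs).
#' @param clusters Optional `combination_clusters` for labeling.
#' @param exclude_variable Drop VARIABLE calls first.
#' @return Data.frame of class `validated_sequences`: tag_id, start_s,
#'   length, categories (ordered, "+"-separated), call_ids
#'   ("+"-separated), cluster_label.
#' @export
validate_sequences <- function(calls, bci_s, cells, clusters = NULL,
                               exclude_variable = TRUE) {
  sig <- cells[cells$significant_over, , drop = FALSE]
  sig_key <- paste(sig$from_cat, sig$to_cat, sep = "\r")
  emap <- cluster_edge_map(clusters)
  gaps <- compute_gaps(calls, exclude_variable = exclude_variable)
  rows <- list()
  for (tg in split(gaps, gaps$tag_id)) {
    ok <- tg$gap_s <= bci_s &
      paste(tg$from_cat, tg$to_cat, sep = "\r") %in% sig_key
    i <- 1L
    while (i <= nrow(tg)) {
      if (!ok[i]) { i <- i + 1L; next }
      j <- i
      while (j < nrow(tg) && ok[j + 1L] &&
             tg$to_call_id[j] == tg$from_call_id[j + 1L]) j <- j + 1L
      run <- tg[i:j, , drop = FALSE]
      cats <- c(run$from_cat, run$to_cat[nrow(run)])
      ids <- c(run$from_call_id, run$to_call_id[nrow(run)])
      mixed <- run$from_cat != run$to_cat
      lab <- NA_character_
      if (any(mixed)) {
        ## assigned only when every mixed edge of the run is an edge of
        ## one and the same cluster
        labs <- unique(unname(
          emap[paste(run$from_cat[mixed], run$to_cat[mixed], sep = "\r")]))
        if (length(labs) == 1L && !is.na(labs)) lab <- labs
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = run$tag_id[1], start_s = run$time_s[1],
        length = length(cats),
        categories = paste(cats, collapse = "+"),
        call_ids = paste(ids, collapse = "+"),
        cluster_label = lab, stringsAsFactors = FALSE)
      i <- j + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag_id = character(0), start_s = numeric(0),
               length = integer(0), categories = character(0),
               call_ids = character(0), cluster_label = character(0))
  rownames(out) <- NULL
  class(out) <- c("validated_sequences", "data.frame")
  out
}

#' Assign transition events to clusters
#'
#' @param events Event data.frame from a `transition_table`.
#' @param clusters `combination_clusters`.
#' @return `events` with a `cluster_label` column (NA where the ordered
#'   pair is not a cluster edge).
#' @export
assign_clusters <- function(events, clusters) {
  emap <- cluster_edge_map(clusters)
  key <- paste(events$from_cat, events$to_cat, sep = "\r")
  events$cluster_label <- unname(emap[key])
  events
}

#' Repetition and combination shares
#'
#' Splits the gated transitions into same-category repetitions and
#' cluster-edge transitions (shares need not sum to 1; transitions that
#' are neither are the remainder).
#'
#' @param table A `transition_table`.
#' @param clusters `combination_clusters`.
#' @return List of class `share_summary`: n_total, n_repetition,
#'   repetition_share, n_cluster, cluster_share, per_cluster (data.frame
#'   label, n_transitions).
#' @export
summarize_shares <- function(table, clusters) {
  events <- table$events
  n <- nrow(events)
  if (n == 0) abort("no transitions: shares undefined",
                    "orcaseq_undefined_share")
  ev <- assign_clusters(events, clusters)
  n_rep <- sum(ev$from_cat == ev$to_cat)
  n_clu <- sum(!is.na(ev$cluster_label))
  per <- if (length(clusters)) {
    data.frame(label = vapply(clusters, `[[`, character(1), "label"),
               n_transitions = vapply(clusters, function(cl)
                 sum(ev$cluster_label %in% cl$label), integer(1)),
               stringsAsFactors = FALSE)
  } else data.frame(label = character(0), n_transitions = integer(0))
  structure(list(n_total = n, n_repetition = n_rep,
                 repetition_share = n_rep / n,
                 n_cluster = n_clu, cluster_share = n_clu / n,
                 per_cluster = per),
            class = "share_summary")
}

#' @export
print.combination_clusters <- function(x, ...) {
  cat(sprintf("%d call-combination cluster(s)\n", length(x)))
  for (cl in x)
    cat(sprintf("  %s: {%s}  n = %d transitions over %d edges\n",
                cl$label, paste(cl$categories, collapse = ", "),
                cl$n_transitions, nrow(cl$edges)))
  invisible(x)
}

#' @export
print.share_summary <- function(x, ...) {
  cat(sprintf("Transitions: %d\n", x$n_total))
  cat(sprintf("  repetitions      : %d (%.1f%%)\n", x$n_repetition,
              100 * x$repetition_share))
  cat(sprintf("  cluster combinations: %d (%.1f%%)\n", x$n_cluster,
              100 * x$cluster_share))
  for (i in seq_len(nrow(x$per_cluster)))
    cat(sprintf("    cluster %s: n = %d\n", x$per_cluster$label[i],
                x$per_cluster$n_transitions[i]))
  invisible(x)
}
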