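## End-to-end pipeline: quality gate -> gaps -> bout model -> transitions
## -> Monte-Carlo chi-squared -> post-hoc residuals -> clusters ->
## validated sequences -> shares -> feeding context.

#' Pipeline configuration
#'
#' Collects the thresholds of the analysis in one validated object. All
#' constants default to the standard protocol: 10 dB SNR gate, 30 s gap
#' cap for the bout fit, 2000 Monte-Carlo replicates, alpha 0.05,
#' min_count 10, five-minute feeding window.
#'
#' @param annotations_path,tail_slaps_path Input CSVs (either may be NULL
#'   when data.frames are passed to [run_pipeline()] directly).
#' @param out_dir Output directory for stage artifacts (NULL = don't
#'   write).
#' @param snr_threshold_db,max_gap_s,n_sim,alpha,min_count,window_s
#'   Stage constants; see the stage functions.
#' @param bci_override_s Optional fixed BCI (s); skips the bout fit.
#' @param exclude_variable Drop VARIABLE calls before sequence stages.
#' @param seed RNG seed (Monte-Carlo p only).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(annotations_path = NULL, tail_slaps_path = NULL,
                            out_dir = NULL, snr_threshold_db = 10,
                            max_gap_s = 30, n_sim = 2000, alpha = 0.05,
                            min_count = 10, window_s = 300,
                            bci_override_s = NULL, exclude_variable = TRUE,
                            seed = 1L) {
  for (v in c(snr_threshold_db = snr_threshold_db, max_gap_s = max_gap_s,
              n_sim = n_sim, min_count = min_count, window_s = window_s))
    if (!is.numeric(v) || v <= 0)
      abort("thresholds must be positive", "orcaseq_bad_parameter")
  if (!is_prob(alpha) || alpha <= 0 || alpha >= 1)
    abort("alpha must lie in (0, 1)", "orcaseq_bad_parameter")
  if (!is.null(bci_override_s) && bci_override_s <= 0)
    abort("bci_override_s must be positive", "orcaseq_bad_parameter")
  structure(list(annotations_path = annotations_path,
                 tail_slaps_path = tail_slaps_path, out_dir = out_dir,
                 snr_threshold_db = snr_threshold_db, max_gap_s = max_gap_s,
                 n_sim = n_sim, alpha = alpha, min_count = min_count,
                 window_s = window_s, bci_override_s = bci_override_s,
                 exclude_variable = exclude_variable,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full call-combination pipeline
#'
#' Executes every stage in order and returns the bundle of intermediate
#' and final results. With `config$out_dir` set, stage artifacts (gate
#' audit, gap series, bout-model JSON, transition counts, test results,
#' clusters, sequences, context summary, run manifest) are written as
#' CSV/JSON. Fully reproducible under a fixed seed; the seed only
#' affects the Monte-Carlo p-value.
#'
#' @param config A [pipeline_config()].
#' @param calls Optional annotation data.frame (otherwise read from
#'   `config$annotations_path`).
#' @param tail_slaps Optional tail-slap data.frame.
#' @return List of class `pipeline_result`: `gate`, `gaps`, `bout_model`,
#'   `bci_s`, `transitions`, `chisq`, `posthoc`, `clusters`, `sequences`,
#'   `shares`, `events_labeled`, `context`, `funnel`, `config`.
#' @export
run_pipeline <- function(config, calls = NULL, tail_slaps = NULL) {
  if (is.null(calls)) {
    if (is.null(config$annotations_path))
      abort("no calls given and no annotations_path configured",
            "orcaseq_bad_parameter")
    calls <- read_annotations(config$annotations_path)
  }
  if (is.null(tail_slaps)) {
    tail_slaps <- if (!is.null(config$tail_slaps_path))
      read_tail_slaps(config$tail_slaps_path) else
      data.frame(tag_id = character(0), time_s = numeric(0),
                 quality = character(0))
  }
  funnel <- c(calls_in = nrow(calls))

  gate <- quality_gate(calls, snr_threshold_db = config$snr_threshold_db)
  retained <- gate$retained
  funnel["after_quality_gate"] <- nrow(retained)
  funnel["after_variable_removed"] <- if (config$exclude_variable)
    sum(retained$category != VARIABLE_LABEL) else nrow(retained)

  gaps <- compute_gaps(retained, exclude_variable = config$exclude_variable)
  funnel["gaps"] <- nrow(gaps)

  if (is.null(config$bci_override_s)) {
    bout <- fit_bout_model(gaps, max_gap_s = config$max_gap_s)
    bci <- bout$bci_s
    if (is.na(bci))
      abort("bout fit degenerate and no BCI override given",
            "orcaseq_fit_error")
  } else {
    bout <- NULL
    bci <- config$bci_override_s
  }

  tt <- build_transitions(retained, bci_s = bci,
                          exclude_variable = config$exclude_variable)
  funnel["transitions_within_bci"] <- tt$n_total
  chisq <- chi_square_mc(tt, n_sim = config$n_sim, seed = config$seed)
  posthoc <- posthoc_residuals(tt, alpha = config$alpha)
  clusters <- extract_clusters(posthoc, min_count = config$min_count)
  sequences <- validate_sequences(retained, bci, posthoc, clusters,
                                  exclude_variable = config$exclude_variable)
  shares <- summarize_shares(tt, clusters)
  ev <- assign_clusters(tt$events, clusters)
  ev <- label_feeding(ev, tail_slaps, window_s = config$window_s)
  context <- context_summary(ev, clusters)

  res <- structure(list(gate = gate, gaps = gaps, bout_model = bout,
                        bci_s = bci, transitions = tt, chisq = chisq,
                        posthoc = posthoc, clusters = clusters,
                        sequences = sequences, shares = shares,
                        events_labeled = ev, context = context,
                        funnel = funnel, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$gate$audit, file.path(dir, "gate_audit.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$gaps), file.path(dir, "gaps.csv"),
                   row.names = FALSE)
  if (!is.null(res$bout_model)) {
    bm <- res$bout_model
    jsonlite::write_json(
      list(p = bm$p, lambda_fast = bm$lambda_fast,
           lambda_slow = bm$lambda_slow, loglik = bm$loglik,
           n_gaps_used = bm$n_gaps_used, max_gap_s = bm$max_gap_s,
           bci_s = bm$bci_s, degenerate = bm$degenerate),
      file.path(dir, "bout_model.json"), auto_unbox = TRUE, digits = NA)
  }
  write_transition_counts(res$transitions,
                          file.path(dir, "transition_counts.csv"))
  utils::write.csv(res$events_labeled, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$posthoc),
                   file.path(dir, "posthoc_cells.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(statistic = res$chisq$statistic, n_sim = res$chisq$n_sim,
         p_mc = res$chisq$p_mc, seed = res$chisq$seed),
    file.path(dir, "chisq.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(unclass(res$clusters), function(cl)
      list(label = cl$label, categories = cl$categories,
           n_transitions = cl$n_transitions, edges = cl$edges)),
    file.path(dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(res$sequences),
                   file.path(dir, "sequences.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_total = res$shares$n_total,
         n_repetition = res$shares$n_repetition,
         repetition_share = res$shares$repetition_share,
         n_cluster = res$shares$n_cluster,
         cluster_share = res$shares$cluster_share,
         per_cluster = res$shares$per_cluster,
         context = list(
           per_cluster = res$context$per_cluster,
           proportion_outside_feeding_overall =
             res$context$proportion_outside_feeding_overall)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "orcaseq",
         version = as.character(utils::packageVersion("orcaseq")),
         seed = res$config$seed, bci_s = res$bci_s,
         funnel = as.list(res$funnel),
         config = res$config[!vapply(res$config, is.null, logical(1))]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Call-combination pipeline\n")
  cat(sprintf("  funnel: %s\n",
              paste(sprintf("%s=%d", names(x$funnel), x$funnel),
                    collapse = " -> ")))
  cat(sprintf("  BCI: %.3f s%s\n", x$bci_s,
              if (is.null(x$bout_model)) " (override)" else " (fitted)"))
  print(x$chisq)
  print(x$clusters)
  print(x$shares)
  print(x$context)
  invisible(x)
}
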