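## First-order Markov transition analysis.
##
## Consecutive retained calls of the same tag whose silent gap does not
## exceed the bout criterion interval form a transition event. The
## observed ordered-pair count matrix is tested against the independence
## null (margins fixed) with a Pearson chi-squared statistic whose p-value
## comes from Monte-Carlo resampling of fixed-margin tables (Patefield
## algorithm via r2dtable), followed by per-cell post-hoc tests on
## adjusted standardized residuals with Bonferroni correction.

#' Build the BCI-gated transition table
#'
#' @param calls Data.frame of retained, categorized calls (per tag,
#'   sorted); VARIABLE calls are removed first when `exclude_variable`.
#' @param bci_s Gap threshold (s); only pairs with gap <= bci_s count.
#' @param exclude_variable Drop VARIABLE calls before pairing.
#' @return Object of class `transition_table`: `categories` (sorted label
#'   vector), `counts` (square matrix), `events` (data.frame tag_id,
#'   from_call_id, to_call_id, from_cat, to_cat, gap_s, time_s),
#'   `n_total`.
#' @export
build_transitions <- function(calls, bci_s, exclude_variable = TRUE) {
  if (!is.numeric(bci_s) || bci_s <= 0)
    abort("bci_s must be positive", "orcaseq_bad_parameter")
  gaps <- compute_gaps(calls, exclude_variable = exclude_variable)
  events <- gaps[gaps$gap_s <= bci_s,
                 c("tag_id", "from_call_id", "to_call_id",
                   "from_cat", "to_cat", "gap_s", "time_s"),
                 drop = FALSE]
  rownames(events) <- NULL
  cats <- sort(unique(c(events$from_cat, events$to_cat)))
  counts <- matrix(0L, length(cats), length(cats),
                   dimnames = list(from = cats, to = cats))
  if (nrow(events)) {
    tab <- table(factor(events$from_cat, levels = cats),
                 factor(events$to_cat, levels = cats))
    counts[] <- as.integer(tab)
  }
  structure(list(categories = cats, counts = counts, events = events,
                 n_total = nrow(events)),
            class = "transition_table")
}

#' Expected counts under the independence null
#'
#' `E_ij = row_i total * col_j total / n_total`, i.e. independence of the
#' preceding and following category with the observed margins.
#'
#' @param table A `transition_table` or a count matrix.
#' @return Matrix of expected counts, same shape as the observed counts.
#' @export
expected_counts <- function(table) {
  counts <- if (inherits(table, "transition_table")) table$counts else table
  n <- sum(counts)
  if (n <= 0) abort("empty table", "orcaseq_bad_parameter")
  outer(rowSums(counts), colSums(counts)) / n
}

## Pearson statistic over cells with positive expectation.
pearson_stat <- function(O, E) {
  ok <- E > 0
  sum((O[ok] - E[ok])^2 / E[ok])
}

#' Monte-Carlo Pearson chi-squared test
#'
#' Computes the Pearson statistic over cells with positive expectation
#' and estimates the p-value by sampling `n_sim` tables uniformly among
#' tables with both margins fixed at the observed margins (Patefield
#' sampling). The add-one convention
#' `p = (1 + #\{chi2_sim >= chi2_obs\}) / (n_sim + 1)` keeps p strictly
#' positive.
#'
#' @param table A `transition_table` or count matrix.
#' @param n_sim Number of Monte-Carlo replicates (default 2000).
#' @param seed Integer RNG seed.
#' @return Object of class `chisq_mc_result`: statistic, n_sim, p_mc,
#'   seed, df_nominal.
#' @export
chi_square_mc <- function(table, n_sim = 2000, seed = 1L) {
  counts <- if (inherits(table, "transition_table")) table$counts else table
  counts <- as.matrix(counts)
  if (sum(counts) <= 0) abort("empty table", "orcaseq_bad_parameter")
  r <- rowSums(counts); cs <- colSums(counts)
  keep_r <- r > 0; keep_c <- cs > 0
  if (sum(keep_r) < 2 || sum(keep_c) < 2)
    abort("degenerate margins: need >= 2 positive rows and columns",
          "orcaseq_test_undefined")
  O <- counts[keep_r, keep_c, drop = FALSE]
  E <- outer(r[keep_r], cs[keep_c]) / sum(counts)
  stat <- pearson_stat(O, E)
  sims <- with_seed(seed, stats::r2dtable(n_sim, r[keep_r], cs[keep_c]))
  sim_stats <- vapply(sims, pearson_stat, numeric(1), E = E)
  p <- (1 + sum(sim_stats >= stat - 1e-9)) / (n_sim + 1)
  structure(list(statistic = stat, n_sim = n_sim, p_mc = p,
                 seed = as.integer(seed),
                 df_nominal = (sum(keep_r) - 1) * (sum(keep_c) - 1)),
            class = "chisq_mc_result")
}

#' Post-hoc per-cell residual tests
#'
#' For each cell with positive expectation the adjusted standardized
#' residual
#' `z_ij = (O_ij - E_ij) / sqrt(E_ij (1 - r_i/n) (1 - c_j/n))`
#' is referred to the standard normal (two-sided), with Bonferroni
#' correction over the whole `C^2`-cell family. A cell is flagged
#' `significant_over` when its adjusted p falls below `alpha` and the
#' residual is positive (over-expected), the direction that feeds
#' combination-cluster extraction.
#'
#' @param table A `transition_table` or count matrix.
#' @param alpha Family-wise significance level (default 0.05).
#' @param family_size Bonferroni family size; default `C^2`, the full
#'   cell count of the square table.
#' @return Data.frame of class `posthoc_cells`: from_cat, to_cat,
#'   observed, expected, residual, p_raw, p_adj, direction,
#'   significant_over. Cells with `E = 0` are excluded and listed in the
#'   `excluded` attribute.
#' @export
posthoc_residuals <- function(table, alpha = 0.05, family_size = NULL) {
  counts <- if (inherits(table, "transition_table")) table$counts else
    as.matrix(table)
  n <- sum(counts)
  if (n <= 0) abort("empty table", "orcaseq_bad_parameter")
  E <- expected_counts(counts)
  r <- rowSums(counts); cs <- colSums(counts)
  C <- nrow(counts)
  if (is.null(family_size)) family_size <- C * C
  idx <- which(E > 0, arr.ind = TRUE)
  denom <- sqrt(E[idx] * (1 - r[idx[, 1]] / n) * (1 - cs[idx[, 2]] / n))
  z <- (counts[idx] - E[idx]) / ifelse(denom > 0, denom, NA_real_)
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(1, p_raw * family_size)
  out <- data.frame(
    from_cat = rownames(counts)[idx[, 1]],
    to_cat = colnames(counts)[idx[, 2]],
    observed = as.integer(counts[idx]), expected = E[idx],
    residual = z, p_raw = p_raw, p_adj = p_adj,
    direction = ifelse(z >= 0, "over", "under"),
    significant_over = !is.na(p_adj) & p_adj < alpha & z > 0,
    stringsAsFactors = FALSE)
  out <- out[order(out$from_cat, out$to_cat), ]
  rownames(out) <- NULL
  excl <- which(E == 0, arr.ind = TRUE)
  attr(out, "excluded") <- data.frame(
    from_cat = rownames(counts)[excl[, 1]],
    to_cat = colnames(counts)[excl[, 2]], stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "family_size") <- family_size
  class(out) <- c("posthoc_cells", "data.frame")
  out
}

#' Drop low-count cells
#'
#' Retains cells observed strictly more than `min_count` times (O > 10,
#' not >=, at the default), the convention used when reporting
#' transitions robust to small samples.
#'
#' @param cells A `posthoc_cells` data.frame (or any frame with an
#'   `observed` column).
#' @param min_count Strict lower bound on the observed count.
#' @return The retained rows.
#' @export
filter_min_count <- function(cells, min_count = 10) {
  out <- cells[cells$observed > min_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.chisq_mc_result <- function(x, ...) {
  cat(sprintf("Pearson chi-squared (Monte-Carlo, %d fixed-margin replicates)\n",
              x$n_sim))
  cat(sprintf("  chi2 = %.1f, simulated p = %.4g (seed %d)\n",
              x$statistic, x$p_mc, x$seed))
  invisible(x)
}
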