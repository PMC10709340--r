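# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A call table from onset/offset vectors (single tag unless tag_id given).
make_calls <- function(starts, ends, categories, tag_id = "t1",
                       quality = "high", snr_db = 20) {
  data.frame(tag_id = tag_id,
             call_id = sprintf("%s_c%03d", tag_id, seq_along(starts)),
             start_s = starts, end_s = ends, category = categories,
             quality = quality, snr_db = snr_db, stringsAsFactors = FALSE)
}

# A call stream from categories and silent gaps (length n-1), fixed call
# duration.
make_stream <- function(categories, gaps, duration = 1, tag_id = "t1") {
  n <- length(categories)
  starts <- numeric(n)
  starts[1] <- 1
  for (i in seq_len(n - 1))
    starts[i + 1] <- starts[i] + duration + gaps[i]
  make_calls(starts, starts + duration, categories, tag_id = tag_id)
}

# Fabricated post-hoc cell table marking given ordered pairs significant.
make_sig_cells <- function(pairs, observed = 20) {
  if (!length(pairs))
    return(data.frame(from_cat = character(0), to_cat = character(0),
                      observed = integer(0), expected = numeric(0),
                      residual = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), direction = character(0),
                      significant_over = logical(0)))
  data.frame(from_cat = vapply(pairs, `[[`, character(1), 1),
             to_cat = vapply(pairs, `[[`, character(1), 2),
             observed = observed, expected = 1, residual = 10,
             p_raw = 1e-10, p_adj = 1e-6, direction = "over",
             significant_over = TRUE, stringsAsFactors = FALSE)
}

# Truth-derived bout criterion for the default timing world.
TRUTH_TIMING <- list(p = 0.7, lf = 2, ls = 0.05)
TRUTH_BCI <- log(0.7 * 2 / (0.3 * 0.05)) / (2 - 0.05)
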