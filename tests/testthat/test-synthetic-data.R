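# Synthetic call-stream generator: gap mixture, planted grammars,
# determinism, tail-slap association.

test_that("timing_spec enforces its invariants", {
  expect_error(timing_spec(p_fast = 1.0), class = "orcaseq_bad_parameter")
  expect_error(timing_spec(p_fast = 0), class = "orcaseq_bad_parameter")
  expect_error(timing_spec(lambda_fast = 0.05, lambda_slow = 2),
               class = "orcaseq_bad_parameter")
  expect_s3_class(timing_spec(), "timing_spec")
})

test_that("generate_gaps matches the mixture's closed-form moments", {
  # near-single-component limit: mean ~ 1/lambda_fast
  tm1 <- timing_spec(p_fast = 1 - 1e-12, lambda_fast = 2, lambda_slow = 0.05)
  g1 <- generate_gaps(tm1, 5000, seed = 11)
  expect_equal(mean(g1), 0.5, tolerance = 0.05)

  # two-component mixture mean: 0.7/2 + 0.3/0.05 = 6.35 s
  tm <- timing_spec()
  g <- generate_gaps(tm, 5000, seed = 12)
  # mixture sd ~ 14.2 s -> 4 standard errors ~ 0.8 s
  expect_lt(abs(mean(g) - 6.35), 0.8)
  comp <- attr(g, "component")
  expect_setequal(unique(comp), c("fast", "slow"))
  expect_equal(mean(comp == "fast"), 0.7, tolerance = 0.05)
})

test_that("generate_gaps is seed-deterministic and validates n", {
  tm <- timing_spec()
  expect_identical(generate_gaps(tm, 100, seed = 3),
                   generate_gaps(tm, 100, seed = 3))
  expect_error(generate_gaps(tm, 0), class = "orcaseq_bad_parameter")
})

test_that("empirical gap distribution matches the mixture density (KS)", {
  tm <- timing_spec()
  mix_cdf <- function(q) 0.7 * stats::pexp(q, 2) + 0.3 * stats::pexp(q, 0.05)
  pvals <- vapply(1:10, function(s) {
    g <- as.numeric(generate_gaps(tm, 10000, seed = 100 + s))
    suppressWarnings(stats::ks.test(g, mix_cdf)$p.value)
  }, numeric(1))
  # allow the nominal false-positive rate at alpha = 0.01
  expect_gte(sum(pvals > 0.01), 8)
})

test_that("grammar_spec validates motifs against category and order sets", {
  expect_error(grammar_spec(character(0)), class = "orcaseq_bad_parameter")
  expect_error(grammar_spec(c("A", "B"),
                            motifs = list(list(calls = c("A", "Z"),
                                               weight = 1))),
               class = "orcaseq_bad_parameter")
  expect_error(grammar_spec(c("A", "B"),
                            motifs = list(list(calls = c("A", "B"),
                                               weight = 1)),
                            start_set = "B"),
               class = "orcaseq_bad_parameter")
  expect_error(grammar_spec(c("A", "B", "C", "D"),
                            motifs = list(list(calls = c("A", "B", "C", "D"),
                                               weight = 1))),
               class = "orcaseq_bad_parameter")
  expect_error(grammar_spec(c("A", VARIABLE_LABEL)),
               class = "orcaseq_bad_parameter")
})

test_that("degenerate single-motif grammar emits the motif verbatim", {
  g <- grammar_spec(c("A", "B"),
                    motifs = list(list(calls = c("A", "B"), weight = 1)),
                    repetition_prob = 0, variable_call_prob = 0)
  tag <- generate_tag(g, timing_spec(), 4, seed = 1)
  expect_identical(tag$calls$category, c("A", "B", "A", "B"))
  expect_true(all(tag$truth$unit_kind == "motif"))
  expect_true(all(diff(tag$calls$start_s) > 0))
  expect_true(all(tag$calls$end_s >= tag$calls$start_s))
})

test_that("fixed seed gives byte-identical annotation tables", {
  g <- default_grammar()
  tm <- timing_spec()
  t1 <- generate_tag(g, tm, 200, seed = 9)
  t2 <- generate_tag(g, tm, 200, seed = 9)
  expect_identical(t1$calls, t2$calls)
  expect_identical(t1$truth, t2$truth)
  t3 <- generate_tag(g, tm, 200, seed = 10)
  expect_false(identical(t1$calls$start_s, t3$calls$start_s))
})

test_that("planted motif instances respect start/terminal rules", {
  g <- default_grammar()
  for (s in 1:5) {
    tag <- generate_tag(g, timing_spec(), 500, seed = 40 + s)
    tr <- tag$truth
    calls <- tag$calls
    for (u in unique(tr$unit_id[tr$unit_kind == "motif"])) {
      labs <- calls$category[tr$unit_id == u]
      expect_true(labs[1] %in% g$start_set)
      expect_true(labs[length(labs)] %in% g$terminal_set)
      # three-call instances of the big cluster always close with I69
      if (length(labs) == 3 && labs[1] %in% c("I38.1", "I38.2"))
        expect_identical(labs[3], "I69")
    }
  }
})

test_that("truth lives in the sidecar, not the annotation table", {
  tag <- generate_tag(default_grammar(), timing_spec(), 100, seed = 2)
  expect_named(tag$calls, c("tag_id", "call_id", "start_s", "end_s",
                            "category", "quality", "snr_db"))
  expect_true(all(c("unit_kind", "motif_index", "gap_component") %in%
                    names(tag$truth)))
})

test_that("forced association places a slap within 300 s of every instance", {
  g <- default_grammar()
  cl_c <- default_planted_clusters()$C
  tag <- generate_tag(g, timing_spec(), 600, slap_cluster = cl_c,
                      association_prob = 1, seed = 77)
  tr <- tag$truth
  motif_units <- unique(tr$unit_id[tr$unit_kind == "motif"])
  calls <- tag$calls
  n_c_units <- 0
  for (u in motif_units) {
    labs <- calls$category[tr$unit_id == u]
    if (!all(labs %in% cl_c)) next
    n_c_units <- n_c_units + 1
    inst_start <- min(calls$start_s[tr$unit_id == u])
    expect_lte(min(abs(tag$tail_slaps$time_s - inst_start)), 300)
  }
  expect_gt(n_c_units, 0)
  # association 0 -> no slaps at all
  tag0 <- generate_tag(g, timing_spec(), 300, slap_cluster = cl_c,
                       association_prob = 0, seed = 78)
  expect_identical(nrow(tag0$tail_slaps), 0L)
})

test_that("synthesize_waveform honours bounds and the empty tag", {
  tag <- generate_tag(default_grammar(), timing_spec(), 3, seed = 1)
  expect_error(synthesize_waveform(tag, sample_rate = 16000),
               class = "orcaseq_bad_parameter")
  empty <- tag
  empty$calls <- empty$calls[0, ]
  w <- synthesize_waveform(empty, sample_rate = 24000, duration_s = 0.5,
                           seed = 1)
  expect_length(w$wave, 12000)
  expect_equal(stats::sd(w$wave), 1, tolerance = 0.05)
})
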