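# Transition table construction, expected counts, Monte-Carlo
# chi-squared, post-hoc residuals.

test_that("build_transitions gates pairs at the BCI, per tag", {
  # stream A,(0.5 s),A,(2.0 s),B,(1.0 s),B with bci 1.72 -> A->A and B->B
  calls <- make_stream(c("A", "A", "B", "B"), gaps = c(0.5, 2.0, 1.0))
  tt <- build_transitions(calls, bci_s = 1.72)
  expect_identical(tt$n_total, 2L)
  expect_identical(tt$counts["A", "A"], 1L)
  expect_identical(tt$counts["B", "B"], 1L)
  expect_identical(sum(tt$counts), 2L)
  expect_true(all(tt$events$gap_s <= 1.72))

  # no gap under the threshold -> empty table
  wide <- make_stream(c("A", "B"), gaps = 5)
  expect_identical(build_transitions(wide, bci_s = 1.72)$n_total, 0L)

  expect_error(build_transitions(calls, bci_s = 0),
               class = "orcaseq_bad_parameter")

  # row and column label sets are identical (square table)
  expect_identical(rownames(tt$counts), colnames(tt$counts))
})

test_that("expected counts follow the independence margins", {
  m <- matrix(c(10, 0, 0, 10), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  expect_equal(unname(expected_counts(m)), matrix(5, 2, 2))

  # conservation and brute-force margin-product oracle on random tables
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(9, 5), 3, 3)
    E <- expected_counts(m)
    expect_equal(sum(E), sum(m), tolerance = 1e-12)
    for (r in 1:3) for (cc in 1:3)
      expect_equal(E[r, cc], sum(m[r, ]) * sum(m[, cc]) / sum(m),
                   tolerance = 1e-12)
  }
})

test_that("chi-squared statistic matches hand and brute-force oracles", {
  m <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(chi_square_mc(m, n_sim = 50, seed = 1)$statistic, 20)

  flat <- matrix(4, 2, 2)
  res <- chi_square_mc(flat, n_sim = 200, seed = 1)
  expect_equal(res$statistic, 0)
  expect_gt(res$p_mc, 0.9)

  # brute-force double loop on random tables
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rpois(20, 4) + 1, 4, 5)
    stat <- chi_square_mc(m, n_sim = 10, seed = 1)$statistic
    n <- sum(m); acc <- 0
    for (r in 1:4) for (cc in 1:5) {
      e <- sum(m[r, ]) * sum(m[, cc]) / n
      acc <- acc + (m[r, cc] - e)^2 / e
    }
    expect_equal(stat, acc, tolerance = 1e-9)
  }
})

test_that("Monte-Carlo p is reproducible, positive, and margin-faithful", {
  m <- matrix(c(12, 3, 2, 9, 1, 4), 2, 3)
  r1 <- chi_square_mc(m, n_sim = 500, seed = 99)
  r2 <- chi_square_mc(m, n_sim = 500, seed = 99)
  expect_identical(r1$p_mc, r2$p_mc)
  expect_gt(r1$p_mc, 0)

  # the null tables used are fixed-margin Patefield samples: regenerate
  # the identical stream and check every table's margins
  sims <- orcaseq:::with_seed(99, stats::r2dtable(500, rowSums(m),
                                                  colSums(m)))
  for (s in sims[1:50]) {
    expect_identical(rowSums(s), rowSums(m))
    expect_identical(colSums(s), colSums(m))
  }

  expect_error(chi_square_mc(matrix(c(5, 5, 0, 0), 2, 2)),
               class = "orcaseq_test_undefined")
})

test_that("Monte-Carlo p agrees with exact enumeration on small 2x2 tables", {
  exact_p <- function(m) {
    r <- rowSums(m); cc <- colSums(m); n <- sum(m)
    stat_of <- function(k) {
      tab <- matrix(c(k, r[1] - k, cc[1] - k, n - r[1] - cc[1] + k), 2, 2)
      E <- outer(r, cc) / n
      sum((tab - E)^2 / E)
    }
    obs <- stat_of(m[1, 1])
    ks <- max(0, r[1] + cc[1] - n):min(r[1], cc[1])
    probs <- stats::dhyper(ks, cc[1], n - cc[1], r[1])
    min(1, sum(probs[vapply(ks, stat_of, numeric(1)) >= obs - 1e-9]))
  }
  tables <- list(matrix(c(6, 2, 3, 7), 2, 2),
                 matrix(c(5, 5, 5, 5), 2, 2),
                 matrix(c(9, 1, 2, 8), 2, 2),
                 matrix(c(3, 4, 6, 2), 2, 2))
  for (m in tables) {
    pe <- exact_p(m)
    pm <- chi_square_mc(m, n_sim = 2000, seed = 4)$p_mc
    # binomial 99% CI around the exact p (plus add-one offset)
    tol <- 2.58 * sqrt(pe * (1 - pe) / 2000) + 2 / 2000
    expect_lt(abs(pm - pe), tol + 1e-12)
  }
})

test_that("post-hoc residuals match the adjusted-residual formula", {
  flat <- matrix(4, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  cells <- posthoc_residuals(flat)
  expect_true(all(cells$residual == 0))
  expect_false(any(cells$significant_over))

  m <- matrix(c(30, 0, 0, 30), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  cells <- posthoc_residuals(m)
  # independent evaluation: z = (O-E)/sqrt(E(1-r/n)(1-c/n)) for O=30
  n <- 60; E <- 15
  z_ref <- (30 - E) / sqrt(E * (1 - 30 / n) * (1 - 30 / n))
  diag_cells <- cells[cells$from_cat == cells$to_cat, ]
  expect_equal(diag_cells$residual, rep(z_ref, 2), tolerance = 1e-12)
  p_ref <- min(1, 2 * stats::pnorm(-abs(z_ref)) * 4)   # Bonferroni C^2 = 4
  expect_equal(diag_cells$p_adj, rep(p_ref, 2), tolerance = 1e-12)
  expect_true(all(diag_cells$significant_over))
  off <- cells[cells$from_cat != cells$to_cat, ]
  expect_true(all(off$direction == "under"))
  expect_false(any(off$significant_over))
})

test_that("cells with zero expectation are excluded and logged", {
  m <- matrix(c(5, 3, 0, 4, 2, 0), 3, 2,
              dimnames = list(c("A", "B", "C"), c("A", "B")))
  cells <- posthoc_residuals(m)
  expect_false(any(cells$from_cat == "C"))
  excl <- attr(cells, "excluded")
  expect_true(all(excl$from_cat == "C"))
  expect_identical(attr(cells, "family_size"), 9L)   # 3^2 cells
})

test_that("filter_min_count uses a strict inequality", {
  cells <- data.frame(observed = c(9, 10, 11, 50))
  kept <- filter_min_count(cells)
  expect_identical(kept$observed, c(11, 50))
  expect_identical(nrow(filter_min_count(cells[0, , drop = FALSE])), 0L)
})
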