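test_that("mk_table tabulates events by stratum, per length and pooled", {
  indels <- tibble::tibble(
    event = c("deletion", "deletion", "insertion", "deletion", "insertion"),
    fixation = c("fixed", "fixed", "fixed", "polymorphic", "polymorphic"),
    length = c(1L, 2L, 1L, 1L, 1L)
  )
  tab <- mk_table(indels, split_by = "fixation")
  expect_equal(tab$class, c("fixed", "polymorphic"))
  expect_equal(tab$deletions, c(2, 1))
  expect_equal(tab$insertions, c(1, 1))
  expect_equal(tab$rdi, c(2, 1))

  by_len <- mk_table(indels, split_by = "fixation", by_length = TRUE)
  expect_equal(by_len$deletions[by_len$length == "2" &
                                  by_len$class == "fixed"], 1)
  pooled <- by_len[by_len$length == "pooled", ]
  expect_equal(pooled$deletions, tab$deletions)

  empty <- mk_table(indels[0, ], split_by = "fixation")
  expect_equal(nrow(empty), 0)
})

test_that("pre-tabulated counts reproduce the published survey tables", {
  tab <- indel_survey_counts("fixation") |>
    mk_table(split_by = "class", by_length = TRUE, count = "count")
  pooled <- tab[tab$length == "pooled", ]
  expect_equal(pooled$deletions[pooled$class == "fixed"], 145303)
  expect_equal(pooled$insertions[pooled$class == "polymorphic"], 322570)

  shared <- indel_survey_counts("sharing") |>
    mk_table(split_by = "class", count = "count")
  expect_equal(shared$deletions, c(205075, 604423))
})

test_that("uncovered indels are excluded from sharing tables", {
  indels <- tibble::tibble(
    event = c("deletion", "insertion", "deletion"),
    sharing = c("archaic_shared", "modern_specific", "uncovered")
  )
  tab <- mk_table(indels, split_by = "sharing")
  expect_equal(sum(tab$deletions) + sum(tab$insertions), 2)
})

test_that("rdi matches published ratios and rejects empty denominators", {
  expect_equal(round(rdi(145303, 100217), 3), 1.450)
  expect_equal(rdi(5, 5), 1)
  expect_error(rdi(3, 0), "undefined")
  expect_error(rdi(-1, 2), "non-negative")
})

test_that("a symmetric table gives OR 1 and p 1", {
  ft <- fisher_exact_2x2(10, 10, 10, 10)
  expect_equal(ft$odds_ratio, 1)
  expect_equal(ft$p_value, 1)
  expect_equal(ft$log10_p, 0)
})

test_that("the exact p matches direct hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 1, 2, 8)$p_value,
               oracle_fisher_p(5, 1, 2, 8), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    cells <- as.vector(rmultinom(1, n, runif(4, 0.05, 1)))
    ft <- suppressWarnings(fisher_exact_2x2(cells[1], cells[2], cells[3],
                                            cells[4]))
    margins_ok <- all(c(cells[1] + cells[3], cells[2] + cells[4],
                        cells[1] + cells[2], cells[3] + cells[4]) > 0)
    if (!margins_ok) next
    expect_equal(ft$p_value,
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    # cross-check against the reference implementation
    ref <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))
    expect_equal(ft$p_value, ref$p.value, tolerance = 1e-7)
    if (all(cells > 0)) {
      # fisher.test's ML optimizer is itself approximate
      expect_equal(ft$or_conditional_mle, unname(ref$estimate),
                   tolerance = 1e-2)
    }
  }
})

test_that("log10_p stays finite where the p-value underflows", {
  ft <- fisher_exact_2x2(205075, 155818, 604423, 266969)
  expect_equal(ft$p_value, 0)            # below double precision
  expect_true(is.finite(ft$log10_p))
  expect_lt(ft$log10_p, log10(2.2e-16))
  expect_equal(round(ft$odds_ratio, 2), 0.58)
})

test_that("zero margins fall back to p = 1 with a warning", {
  expect_warning(ft <- fisher_exact_2x2(0, 0, 5, 5), "degenerate")
  expect_equal(ft$p_value, 1)
})

test_that("mk_test wraps tables and tests with tidy/glance methods", {
  fit <- indel_survey_counts("fixation") |>
    mk_test(split_by = "class", by_length = TRUE, count = "count")
  td <- tidy(fit)
  expect_equal(nrow(td), 6)   # five lengths plus pooled
  expect_true(all(td$log10_p < log10(2.2e-16)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(round(gl$rdi_1, 3), 1.450)
})

test_that("neutral simulated tables keep the test near its nominal level", {
  set.seed(99)
  rejects <- vapply(1:300, function(i) {
    tab <- simulate_mk_counts(rho = 2, sel_diff = 1, n_fixed = 800,
                              n_poly = 800)
    fisher_exact_2x2(tab)$p_value < 0.05
  }, logical(1))
  # loose bound for a quick unit check; the calibration suite runs 2,000
  expect_lt(mean(rejects), 0.09)
})
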