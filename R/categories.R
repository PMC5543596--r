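#' Per-category binomial contrast with family-wise error control
#'
#' Compares the number of indels of two classes annotated to genes of each
#' functional category (e.g., a Gene Ontology term) against the global
#' class proportion: for category *i* with counts `count_a`, `count_b`,
#' a two-sided exact binomial test of `count_a` out of
#' `count_a + count_b` against `p0 = total_a / (total_a + total_b)`.
#' Contrasting the two indel classes directly cancels per-category
#' differences in gene length and mutation rate. The family-wise error
#' rate over the tested categories is controlled by Bonferroni correction.
#' Categories with no annotated indels are excluded.
#'
#' @param cats Tibble with columns `category`, `count_a`, `count_b` (one
#'   row per category).
#' @param total_a,total_b Global class totals; default to the column sums.
#' @param fwer_alpha Family-wise error rate threshold for the `enriched`
#'   flag.
#' @return Tibble with per-category proportions, the enrichment direction
#'   (`"a"` when class A is over-represented), raw and Bonferroni-adjusted
#'   p-values, and an `enriched` flag at `fwer_alpha`.
#' @export
category_contrast <- function(cats, total_a = NULL, total_b = NULL,
                              fwer_alpha = 0.05) {
  cats <- as_tibble(cats)
  if (!all(c("category", "count_a", "count_b") %in% names(cats))) {
    abort("`cats` needs columns category, count_a, count_b")
  }
  if (is.null(total_a)) total_a <- sum(cats$count_a)
  if (is.null(total_b)) total_b <- sum(cats$count_b)
  if (total_a + total_b <= 0) abort("global totals must be positive")
  if (any(cats$count_a > total_a) || any(cats$count_b > total_b)) {
    abort("category counts cannot exceed the global totals")
  }
  p0 <- total_a / (total_a + total_b)

  cats <- filter(cats, .data$count_a + .data$count_b > 0)
  m <- nrow(cats)
  res <- purrr::pmap(
    list(cats$count_a, cats$count_b),
    function(ca, cb) {
      bt <- binom.test(ca, ca + cb, p = p0, alternative = "two.sided")
      tibble(proportion_a = ca / (ca + cb), p_value = bt$p.value)
    }
  ) %>% bind_rows()

  bind_cols(cats, res) %>%
    mutate(
      expected_proportion_a = p0,
      direction = if_else(.data$proportion_a > p0, "a", "b"),
      p_fwer = pmin(1, .data$p_value * m),
      enriched = .data$p_fwer <= fwer_alpha
    ) %>%
    arrange(.data$p_fwer)
}
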