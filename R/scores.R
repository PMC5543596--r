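#' Filter indels by phred-scaled deleteriousness score
#'
#' Joins a per-variant C-score table (CADD-style) onto the indel table and
#' keeps variants scoring at or above the cutoff; a score of 20
#' corresponds to the top 1% most disruptive variants genome-wide.
#' Indels without a score are dropped (their count is reported in a
#' warning); duplicate score rows for one variant keep the highest score.
#'
#' @param indels Indel tibble with `chrom`, `pos` and, when present in
#'   `scores` too, `ancestral`/`derived` allele columns used for the join.
#' @param scores Tibble with `chrom`, `pos`, optional allele columns, and
#'   `score`.
#' @param cutoff Minimum score retained (inclusive).
#' @return Scored subset of `indels`, sorted by descending score.
#' @export
score_filter <- function(indels, scores, cutoff = 20) {
  scores <- as_tibble(scores)
  if (!"score" %in% names(scores)) abort("`scores` needs a `score` column")
  keys <- intersect(intersect(names(indels), names(scores)),
                    c("chrom", "pos", "ancestral", "derived"))
  if (!all(c("chrom", "pos") %in% keys)) {
    abort("`scores` must be joinable on at least chrom and pos")
  }
  if (nrow(scores) == 0) {
    warn("empty score table; no indels retained")
    return(indels[0, , drop = FALSE] %>% mutate(score = numeric()))
  }
  dup <- scores %>%
    count(across(all_of(keys))) %>%
    filter(n > 1L)
  if (nrow(dup) > 0) {
    warn(sprintf("%d variant(s) had duplicate score rows; highest kept",
                 nrow(dup)))
  }
  scores <- scores %>%
    group_by(across(all_of(keys))) %>%
    summarise(score = max(.data$score), .groups = "drop")

  joined <- inner_join(indels, scores, by = keys)
  n_lost <- nrow(indels) - nrow(joined)
  if (n_lost > 0) {
    warn(sprintf("%d indel(s) had no score and were dropped", n_lost))
  }
  joined %>%
    filter(.data$score >= cutoff) %>%
    arrange(dplyr::desc(.data$score))
}

#' Per-site Hudson FST between two populations
#'
#' Hudson's estimator from allele frequencies and sample sizes:
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'   {p_1(1-p_2) + p_2(1-p_1)}}
#' with `n` counted in chromosomes. Values are clipped to `[0, 1]` for
#' ranking; sites monomorphic for the same allele in both populations have
#' an undefined estimator and return `NA`.
#'
#' @param p1,p2 Derived allele frequencies in the two populations
#'   (vectorized).
#' @param n1,n2 Chromosome counts (>= 2).
#' @return Numeric vector of per-site FST estimates.
#' @export
#' @examples
#' fst_hudson(0.1, 100, 0.4, 100)
fst_hudson <- function(p1, n1, p2, n2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1, na.rm = TRUE)) {
    abort("frequencies must lie in [0, 1]")
  }
  if (any(c(n1, n2) < 2)) abort("chromosome counts must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- ifelse(den > 0, num / den, NA_real_)
  pmin(pmax(out, 0), 1)
}
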