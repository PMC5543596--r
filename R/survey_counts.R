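#' Published genome-wide indel counts for the human lineage
#'
#' Count tables from a published genome-wide survey of 1-5 bp human-lineage
#' indels polarized with seven primate outgroups and stratified with the
#' Altai Neandertal genome. These serve as reference inputs for the
#' contingency statistics ([mk_table()], [rdi()], [fisher_exact_2x2()])
#' without redistributing the underlying cohort data.
#'
#' * `"fixation"`: fixed vs polymorphic deletions/insertions by event
#'   length (1-5 bp).
#' * `"sharing"`: archaic-shared vs modern-human-specific deletions and
#'   insertions (pooled lengths).
#'
#' @param table Which count table to return.
#' @return Tibble with columns `length` (fixation table only), `class`,
#'   `event`, `count`.
#' @export
#' @examples
#' indel_survey_counts("fixation") |>
#'   mk_table(split_by = "class", count = "count")
indel_survey_counts <- function(table = c("fixation", "sharing")) {
  table <- match.arg(table)
  if (table == "fixation") {
    tibble(
      length = rep(rep(as.character(1:5), each = 2), 2),
      class = rep(c("fixed", "polymorphic"), each = 10),
      event = rep(c("deletion", "insertion"), 10),
      count = c(
        86791, 66333, 26860, 13589, 14802, 8022, 12161, 9406, 4689, 2867,
        344533, 226712, 121548, 38545, 82114, 21147, 84393, 27180,
        31607, 8986
      )
    )
  } else {
    tibble(
      class = rep(c("archaic_shared", "modern_specific"), each = 2),
      event = rep(c("deletion", "insertion"), 2),
      count = c(205075, 155818, 604423, 266969)
    )
  }
}
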