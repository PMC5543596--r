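#' Default species panel for the eight-way primate alignment
#'
#' The analysis anchors on the human reference and requires seven primate
#' outgroups (chimpanzee, bonobo, gorilla, orangutan, gibbon, rhesus macaque,
#' marmoset). The first element is always the human (reference) label; the
#' remaining seven are the outgroups whose unanimous agreement defines the
#' ancestral allele.
#'
#' @return Named character vector of 8 assembly labels; the first element is
#'   named `"human"`, the rest `"outgroup"`.
#' @export
#' @examples
#' default_species()
default_species <- function() {
  c(
    human = "hg19",
    outgroup = "panTro4",
    outgroup = "panpan1.1",
    outgroup = "gorGor3",
    outgroup = "ponAbe2",
    outgroup = "nomLeu1",
    outgroup = "rheMac3",
    outgroup = "calJac3"
  )
}

#' Default population to super-population map
#'
#' Maps cohort population labels to the continental super-populations used by
#' the introgression rule (derived allele absent in all African populations,
#' present in Europeans or East Asians). The synthetic cohort uses one
#' population per super-population; real panels can supply their own map.
#'
#' @return Tibble with columns `population` and `superpop`.
#' @export
default_superpops <- function() {
  tibble::tibble(
    population = c("YRI", "LWK", "GWD", "MSL", "ESN",
                   "CEU", "GBR", "FIN", "IBS", "TSI",
                   "CHB", "CHS", "CDX", "JPT", "KHV"),
    superpop = c(rep("AFR", 5), rep("EUR", 5), rep("EAS", 5))
  )
}

# shared validation: species vector must be length 8, human first
check_species <- function(species) {
  if (length(species) != 8L || is.null(names(species)) ||
      names(species)[1] != "human") {
    abort("`species` must be a named vector of 8 labels with the human label first (see default_species()).")
  }
  invisible(species)
}
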