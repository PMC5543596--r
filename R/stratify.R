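#' Polarize cohort indels against the outgroup consensus
#'
#' Assigns ancestral and derived states to panel variants by matching the
#' VCF alleles against the seven-outgroup consensus allele at each site: the
#' allele identical to the outgroup state is ancestral and the other allele
#' derived, so the event type (insertion vs deletion) follows from the sign
#' of the length difference of the derived allele. Sites absent from the
#' alignment, sites where the outgroups disagree among themselves, and sites
#' where neither VCF allele matches the outgroup state are routed to a
#' rejection table.
#'
#' Derived allele frequencies are computed per population from called
#' genotypes; when the ancestral allele is the VCF ALT the frequency is
#' flipped, so re-polarizing a REF/ALT-swapped VCF yields identical records.
#'
#' @param panel A `genotype_panel` from [load_cohort_indels()].
#' @param outgroups Tibble of the outgroup consensus per aligned site:
#'   columns `chrom`, `pos`, `allele` (VCF-style, sharing the anchor base),
#'   plus optional logical `disagree` marking sites where the seven
#'   outgroups were not unanimous.
#' @return List with `calls` (tibble: chrom, pos, length, event, ancestral,
#'   derived, origin, fixation, one `daf_<population>` column per
#'   population) and `rejected` (tibble: chrom, pos, reason).
#' @export
polarize_cohort <- function(panel, outgroups) {
  stopifnot(inherits(panel, "genotype_panel"))
  outgroups <- as_tibble(outgroups)
  if (!"disagree" %in% names(outgroups)) outgroups$disagree <- FALSE

  v <- panel$variants %>%
    mutate(.row = row_number()) %>%
    left_join(outgroups, by = c("chrom", "pos"))

  aligned <- !is.na(v$allele)
  disagree <- aligned & v$disagree
  anc_is_ref <- aligned & !disagree & v$allele == v$ref
  anc_is_alt <- aligned & !disagree & v$allele == v$alt
  unpolar <- aligned & !disagree & !anc_is_ref & !anc_is_alt

  rejected <- bind_rows(
    tibble(chrom = v$chrom[!aligned], pos = v$pos[!aligned],
           reason = "not_aligned"),
    tibble(chrom = v$chrom[disagree], pos = v$pos[disagree],
           reason = "outgroup_disagreement"),
    tibble(chrom = v$chrom[unpolar], pos = v$pos[unpolar],
           reason = "unpolarizable")
  )

  keep <- anc_is_ref | anc_is_alt
  if (!any(keep)) {
    return(list(calls = empty_cohort_calls(panel), rejected = rejected))
  }

  vv <- v[keep, ]
  derived <- ifelse(anc_is_ref[keep], vv$alt, vv$ref)
  ancestral <- ifelse(anc_is_ref[keep], vv$ref, vv$alt)
  af <- panel_alt_freq(panel)[vv$.row, , drop = FALSE]
  flip <- !anc_is_ref[keep]
  af[flip, ] <- 1 - af[flip, ]

  calls <- tibble(
    chrom = vv$chrom,
    pos = vv$pos,
    length = abs(nchar(derived) - nchar(ancestral)),
    event = ifelse(nchar(derived) > nchar(ancestral), "insertion",
                   "deletion"),
    ancestral = ancestral,
    derived = derived,
    origin = "cohort_vcf",
    fixation = "polymorphic"
  )
  daf <- as_tibble(af)
  names(daf) <- paste0("daf_", names(daf))
  list(calls = bind_cols(calls, daf), rejected = rejected)
}

empty_cohort_calls <- function(panel) {
  daf <- setNames(
    rep(list(numeric()), length(unique(panel$pops$population))),
    paste0("daf_", unique(panel$pops$population))
  )
  bind_cols(
    tibble(chrom = character(), pos = integer(), length = integer(),
           event = character(), ancestral = character(),
           derived = character(), origin = character(),
           fixation = character()),
    as_tibble(daf)
  )
}

#' Merge reference-scan and cohort calls and assign fixation status
#'
#' A human-lineage difference visible in the reference scan is fixed only if
#' the position is not segregating in the cohort; where a cohort record
#' exists at the same site with the same alleles, the cohort record (with
#' its frequencies) wins and the indel is polymorphic. Cohort-only calls are
#' polymorphic unless their derived allele frequency is 1 in every
#' population, in which case they are fixed. Sites where the two sources
#' give incompatible alleles are dropped from the merged table and logged.
#'
#' @param reference_calls Tibble of reference-scan calls ([scan_alignment()]).
#' @param cohort_calls Tibble of polarized cohort calls
#'   ([polarize_cohort()]).
#' @return List with `indels` (unified tibble with a `fixation` column and
#'   the cohort `daf_*` columns, NA for reference-only calls) and `dropped`
#'   (tibble of colliding sites with reason `conflicting_alleles`).
#' @export
merge_and_fix_status <- function(reference_calls, cohort_calls) {
  daf_cols <- grep("^daf_", names(cohort_calls), value = TRUE)
  key <- c("chrom", "pos", "ancestral", "derived")

  ref <- reference_calls %>%
    mutate(fixation = "fixed")

  # same site, same alleles -> cohort wins; same site, different alleles ->
  # both dropped
  same_site <- inner_join(
    ref %>% select("chrom", "pos", ref_anc = "ancestral",
                   ref_der = "derived"),
    cohort_calls %>% select("chrom", "pos", coh_anc = "ancestral",
                            coh_der = "derived"),
    by = c("chrom", "pos")
  )
  conflicts <- same_site %>%
    filter(.data$ref_anc != .data$coh_anc | .data$ref_der != .data$coh_der) %>%
    distinct(.data$chrom, .data$pos)

  ref_kept <- ref %>%
    anti_join(cohort_calls, by = c("chrom", "pos")) %>%
    anti_join(conflicts, by = c("chrom", "pos"))
  coh_kept <- cohort_calls %>%
    anti_join(conflicts, by = c("chrom", "pos"))

  if (nrow(coh_kept) > 0 && length(daf_cols) > 0) {
    daf_mat <- as.matrix(coh_kept[daf_cols])
    all_fixed <- apply(daf_mat, 1L, function(x) all(!is.na(x) & x == 1))
    coh_kept$fixation <- ifelse(all_fixed, "fixed", "polymorphic")
  }

  indels <- bind_rows(ref_kept, coh_kept) %>%
    arrange(.data$chrom, .data$pos)
  dropped <- conflicts %>% mutate(reason = "conflicting_alleles")
  list(indels = indels, dropped = dropped)
}

#' Label indels by archaic sharing
#'
#' An indel is `archaic_shared` when the archaic genotype carries at least
#' one copy of the derived allele at the site (a heterozygous archaic counts
#' as shared), `modern_specific` when the site is covered in the archaic
#' track but carries no derived allele, and `uncovered` when the site is
#' outside archaic coverage. Uncovered sites carry no information about
#' sharing and are excluded from shared-vs-specific contrasts downstream.
#'
#' @param indels Unified indel tibble (see [merge_and_fix_status()]).
#' @param archaic Archaic track tibble from [load_archaic_track()].
#' @return `indels` with a `sharing` column added.
#' @export
annotate_archaic <- function(indels, archaic) {
  j <- indels %>%
    left_join(
      archaic %>% select("chrom", "pos", arch_ref = "ref",
                         arch_alt = "alt", arch_dosage = "dosage"),
      by = c("chrom", "pos")
    )
  covered <- !is.na(j$arch_dosage)
  derived_dosage <- rep(NA_integer_, nrow(j))
  m_alt <- covered & !is.na(j$arch_alt) &
    j$derived == j$arch_alt & j$ancestral == j$arch_ref
  m_ref <- covered & j$derived == j$arch_ref &
    (is.na(j$arch_alt) | j$ancestral == j$arch_alt)
  derived_dosage[covered] <- 0L  # covered but allele not seen in archaic
  derived_dosage[m_alt] <- j$arch_dosage[m_alt]
  derived_dosage[m_ref] <- 2L - j$arch_dosage[m_ref]

  indels$sharing <- dplyr::case_when(
    !covered ~ "uncovered",
    derived_dosage >= 1L ~ "archaic_shared",
    TRUE ~ "modern_specific"
  )
  indels
}

#' Flag putatively introgressed indels
#'
#' Applies the admixture filter: a polymorphic, archaic-shared indel is
#' putatively introgressed when its derived allele is absent (frequency
#' exactly 0) in every African population of the panel and present
#' (frequency > 0) in the European or the East-Asian super-population. The
#' archaic carrier requirement is already encoded in `sharing ==
#' "archaic_shared"`. Admixed super-populations (AMR, SAS) are ignored by
#' the rule but keep their frequency columns.
#'
#' @param indels Indel tibble with `fixation`, `sharing` and `daf_*` columns.
#' @param superpops Population to super-population map (tibble with columns
#'   `population`, `superpop`); see [default_superpops()].
#' @return `indels` with a logical `introgressed` column added.
#' @export
detect_introgressed <- function(indels, superpops = default_superpops()) {
  daf_cols <- grep("^daf_", names(indels), value = TRUE)
  pops <- sub("^daf_", "", daf_cols)
  sp <- superpops$superpop[match(pops, superpops$population)]

  afr_cols <- daf_cols[!is.na(sp) & sp == "AFR"]
  eur_eas_cols <- daf_cols[!is.na(sp) & sp %in% c("EUR", "EAS")]
  if (length(afr_cols) == 0 || length(eur_eas_cols) == 0) {
    abort("panel must contain at least one African and one European or East-Asian population")
  }

  afr <- as.matrix(indels[afr_cols])
  oea <- as.matrix(indels[eur_eas_cols])
  afr_absent <- apply(afr, 1L, function(x) all(!is.na(x) & x == 0))
  oea_present <- apply(oea, 1L, function(x) any(!is.na(x) & x > 0))

  indels$introgressed <- indels$fixation == "polymorphic" &
    indels$sharing == "archaic_shared" &
    afr_absent & oea_present
  indels
}

#' Relative divergence from counts of lineage-specific and shared events
#'
#' The fraction of human-lineage indels that postdate the split from the
#' archaic population, i.e. `100 * specific / (specific + shared)`; with
#' counts of modern-human-specific and archaic-shared indels this measures
#' the divergence of the human reference to the archaic genome relative to
#' the divergence to the common ancestor with chimpanzee.
#'
#' @param n_modern_specific,n_shared Non-negative event counts, not both 0.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' divergence_fraction(37443, 265975)  # 12.3
divergence_fraction <- function(n_modern_specific, n_shared) {
  if (n_modern_specific < 0 || n_shared < 0) {
    abort("counts must be non-negative")
  }
  if (n_modern_specific + n_shared == 0) {
    abort("divergence is undefined when both counts are zero")
  }
  100 * n_modern_specific / (n_modern_specific + n_shared)
}
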