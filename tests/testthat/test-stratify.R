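make_panel <- function(variants, dosages, pops) {
  indelstrata:::new_genotype_panel(variants, dosages, pops)
}

two_pop <- tibble::tibble(
  individual = c("Y1", "Y2", "C1", "C2"),
  population = c("YRI", "YRI", "CEU", "CEU")
)

test_that("cohort variants polarize by the outgroup consensus", {
  variants <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = c("AT", "A", "AT", "AT"),
    alt = c("A", "AT", "ATT", "A"),
    length = 1L
  )
  dos <- matrix(c(1L, 0L, 0L, 1L,
                  2L, 2L, 1L, 1L,
                  0L, 0L, 1L, 0L,
                  0L, 1L, 0L, 0L), nrow = 4, byrow = TRUE,
                dimnames = list(NULL, two_pop$individual))
  outgroups <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    allele = c("AT", "AT", "AG")
  )
  res <- polarize_cohort(make_panel(variants, dos, two_pop), outgroups)

  # site 100: ancestral = REF, derived = ALT -> deletion, daf = alt freq
  s1 <- res$calls[res$calls$pos == 100, ]
  expect_equal(s1$event, "deletion")
  expect_equal(s1$ancestral, "AT")
  expect_equal(s1$derived, "A")
  expect_equal(s1$daf_YRI, 0.25)
  expect_equal(s1$daf_CEU, 0.25)

  # site 200: ancestral = ALT -> derived is REF "A": a deletion with
  # flipped frequencies (daf = 1 - alt frequency)
  s2 <- res$calls[res$calls$pos == 200, ]
  expect_equal(s2$event, "deletion")
  expect_equal(s2$derived, "A")
  expect_equal(s2$daf_YRI, 1 - 1)
  expect_equal(s2$daf_CEU, 1 - 0.5)

  # site 300: outgroups carry a third allele -> unpolarizable
  expect_equal(res$rejected$reason[res$rejected$pos == 300],
               "unpolarizable")
  # site 400: no outgroup consensus -> not aligned
  expect_equal(res$rejected$reason[res$rejected$pos == 400], "not_aligned")
})

test_that("polarization is invariant to swapping REF and ALT", {
  variants <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "AT",
                             alt = "A", length = 1L)
  dos <- matrix(c(1L, 0L, 2L, 1L), nrow = 1,
                dimnames = list(NULL, two_pop$individual))
  outgroups <- tibble::tibble(chrom = "chr1", pos = 100L, allele = "AT")

  swapped <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A",
                            alt = "AT", length = 1L)
  dos_swapped <- 2L - dos

  a <- polarize_cohort(make_panel(variants, dos, two_pop), outgroups)$calls
  b <- polarize_cohort(make_panel(swapped, dos_swapped, two_pop),
                       outgroups)$calls
  expect_equal(a, b)
})

test_that("fixation status follows cohort presence and frequencies", {
  ref_calls <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L), length = 1L, event = "deletion",
    ancestral = c("GT", "CA"), derived = c("G", "C"),
    origin = "reference_scan"
  )
  cohort_calls <- tibble::tibble(
    chrom = "chr1", pos = c(20L, 30L, 40L), length = 1L,
    event = "deletion", ancestral = c("CA", "TG", "AC"),
    derived = c("C", "T", "A"), origin = "cohort_vcf",
    fixation = "polymorphic",
    daf_YRI = c(0.4, 1, 0.2), daf_CEU = c(0.4, 1, 0)
  )
  m <- merge_and_fix_status(ref_calls, cohort_calls)
  fix <- setNames(m$indels$fixation, m$indels$pos)
  expect_equal(unname(fix[c("10", "20", "30", "40")]),
               c("fixed", "polymorphic", "fixed", "polymorphic"))
  # the cohort record wins at pos 20 and keeps its frequencies
  expect_equal(m$indels$daf_YRI[m$indels$pos == 20], 0.4)
})

test_that("allele collisions between sources drop both records", {
  ref_calls <- tibble::tibble(
    chrom = "chr1", pos = 10L, length = 1L, event = "deletion",
    ancestral = "GT", derived = "G", origin = "reference_scan"
  )
  cohort_calls <- tibble::tibble(
    chrom = "chr1", pos = 10L, length = 1L, event = "insertion",
    ancestral = "G", derived = "GA", origin = "cohort_vcf",
    fixation = "polymorphic", daf_YRI = 0.5, daf_CEU = 0.1
  )
  m <- merge_and_fix_status(ref_calls, cohort_calls)
  expect_equal(nrow(m$indels), 0)
  expect_equal(m$dropped$reason, "conflicting_alleles")
})

test_that("archaic sharing labels partition the indel set", {
  indels <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    ancestral = c("GT", "G", "AT", "AT"),
    derived = c("G", "GT", "A", "A")
  )
  archaic <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    ref = c("GT", "G", "AT"), alt = c("G", "GT", "A"),
    dosage = c(1L, 0L, 2L)
  )
  out <- annotate_archaic(indels, archaic)
  expect_equal(out$sharing,
               c("archaic_shared", "modern_specific", "archaic_shared",
                 "uncovered"))
  expect_equal(sum(table(out$sharing)), nrow(indels))
})

test_that("archaic orientation flips when the derived allele is REF", {
  indels <- tibble::tibble(chrom = "chr1", pos = 10L,
                           ancestral = "G", derived = "GT")
  # archaic VCF encodes the site with REF = derived insertion allele
  archaic <- tibble::tibble(chrom = "chr1", pos = 10L, ref = "GT",
                            alt = "G", dosage = 2L)
  # ALT dosage 2 means zero copies of REF (= derived) -> modern specific
  expect_equal(annotate_archaic(indels, archaic)$sharing, "modern_specific")
  archaic$dosage <- 1L
  expect_equal(annotate_archaic(indels, archaic)$sharing, "archaic_shared")
})

test_that("the introgression rule requires AFR absence plus archaic sharing", {
  base <- tibble::tibble(
    chrom = "chr1", pos = 1:4 * 10L,
    fixation = "polymorphic",
    sharing = c("archaic_shared", "archaic_shared", "modern_specific",
                "archaic_shared"),
    daf_YRI = c(0, 0.001, 0, 0),
    daf_CEU = c(0.03, 0.03, 0.03, 0),
    daf_CHB = c(0, 0, 0.02, 0.02)
  )
  out <- detect_introgressed(base)
  # row 1: AFR absent, EUR carrier, archaic shared -> introgressed
  # row 2: a single African carrier disqualifies
  # row 3: archaic does not carry the derived allele
  # row 4: EAS carrier + shared -> introgressed
  expect_equal(out$introgressed, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("divergence fraction reproduces the published percentage", {
  expect_equal(signif(divergence_fraction(37443, 265975), 3), 12.3)
  expect_equal(divergence_fraction(0, 10), 0)
  expect_equal(divergence_fraction(10, 10), 50)
  expect_error(divergence_fraction(0, 0), "undefined")
})

test_that("the full cohort pipeline recovers the simulated truth", {
  cfg <- sim_config(seed = 5, site_count = 300, n_introgressed = 2,
                    introgression_length = 50000L,
                    n_individuals = c(AFR = 30, EUR = 30, EAS = 30))
  sim <- simulate_cohort(cfg)
  pol <- polarize_cohort(sim$panel, sim$outgroups)
  expect_equal(nrow(pol$rejected), 0)
  merged <- merge_and_fix_status(pol$calls[0, ], pol$calls)$indels
  strat <- annotate_archaic(merged, sim$archaic)
  strat <- detect_introgressed(strat)

  truth <- dplyr::arrange(sim$truth, pos)
  strat <- dplyr::arrange(strat, pos)
  expect_equal(nrow(strat), nrow(truth))
  expect_equal(strat$event, truth$event)
  expect_equal(strat$fixation, truth$fixation)
  expect_equal(strat$sharing, truth$sharing)
  expect_equal(strat$introgressed, truth$introgressed)
})
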