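---
title: "Polarizing and stratifying small indels on the human lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarizing and stratifying small indels on the human lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelstrata)
library(dplyr)
```

## The problem

Small insertions and deletions (indels) are an order of magnitude rarer
than nucleotide substitutions but are more likely to disrupt function, and
they are harder to polarize: an identical indel can arise independently on
several lineages (homoplasy), flipping the inferred ancestral state and
with it the apparent direction of the mutation. `indelstrata` implements a
conservative polarization-and-stratification pipeline for 1–5 bp indels on
the human lineage, together with the statistics used to compare selection
pressures between insertions and deletions and between indel age classes,
and rule-based detection of indels introduced into non-African populations
by archaic (Neandertal) admixture.

The pipeline's guard against homoplasy is unanimity: an event is polarized
only when **all seven** primate outgroups of an eight-species alignment
carry an identical ancestral allele. A human deletion is called only where
every outgroup carries the same ungapped allele opposite a human gap; a
human insertion only where every outgroup is gapped opposite human
sequence. Any disagreement among outgroups — including one outgroup
sharing the human state, the signature of homoplasy — routes the candidate
to a rejection table with a reason code instead of the call set. This
selects for sites that are stable over tens of millions of years, a bias
towards conserved and against repetitive regions that any user of the
output inherits.

## Pipeline stages

1. **`read_maf()` / `normalize_gaps()` / `scan_alignment()`** — ingest
   multiz-style MAF blocks (only blocks with all eight species are
   usable), canonicalize gap placement, and call reference-scan indels.
2. **`load_cohort_indels()` / `polarize_cohort()`** — load 1–5 bp
   biallelic cohort indels (symbolic `<CN>`-style alleles and multiallelic
   sites excluded) and polarize them against the per-site outgroup
   consensus: the VCF allele matching the outgroup state is ancestral.
3. **`merge_and_fix_status()`** — an indel is *fixed* only if it is seen
   in the reference scan and is not segregating in the cohort (or is at
   derived frequency 1 in every population); otherwise *polymorphic*.
4. **`annotate_archaic()`** — *archaic-shared* if the archaic genotype
   carries ≥ 1 derived allele at a covered site, *modern-specific* if
   covered without the derived allele, *uncovered* otherwise. Uncovered
   sites are excluded from shared-vs-specific contrasts.
5. **`detect_introgressed()`** — a polymorphic, archaic-shared indel is
   putatively introgressed when its derived allele frequency is exactly 0
   in every African population and positive in the European or East-Asian
   super-population.
6. **Statistics** — `mk_test()`, `afs_compare()`,
   `region_class_contrast()`, `category_contrast()`, `score_filter()`,
   `fst_hudson()`, `perfect_ld()`, `shared_extent()`,
   `ils_probability()`.

## The modified McDonald–Kreitman contrast

Deletions arise roughly twice as often as insertions. Under neutrality the
deletion/insertion ratio (rDI) of *fixed* events and of *polymorphic*
events both reflect that mutation-rate ratio alone, so the 2×2 table of
(fixed, polymorphic) × (deletions, insertions) should show no association.
Selection that handicaps one event type on its way to fixation skews the
table. `mk_test()` runs the exact Fisher test per event length and pooled;
the same contrast applies to (archaic-shared, modern-specific) as age
classes.

Genome-wide tables make the two-sided exact p far smaller than double
precision, so `fisher_exact_2x2()` sums hypergeometric log-probabilities
("as or more extreme" with the same relative-error rule as
`stats::fisher.test`) and reports `log10_p` alongside the underflowed
`p_value`. Two odds ratios are reported — the sample cross-product OR and
the conditional maximum-likelihood OR under the noncentral hypergeometric
model — because published ORs are consistent with either at the printed
precision; tests in this package assert on the sample OR.

```{r}
indel_survey_counts("sharing") |>
  mk_test(split_by = "class", count = "count") |>
  glance()
```

## Allele frequency spectra

`afs_compare()` contrasts the derived allele frequencies of two indel
classes with a two-sided Wilcoxon rank sum test: exact for small tie-free
samples, otherwise the normal approximation with mid-ranks, tie correction
and continuity correction (the regime any genome-scale comparison runs
in). Spectra are additionally returned in 20 equal-width frequency bins —
a plotting granularity choice only; the test always uses unbinned
frequencies.

## Region classes, categories, scores

`region_class_contrast()` tests, for each region class (coding, intron,
intergenic, UTR, ... — one class per indel, assigned upstream by a
most-severe rule) and each pair of indel classes, the 2×2 of (in-region,
out-of-region) × (class A, class B). The Benjamini–Hochberg adjustment is
applied over the combined p-value list of all region × contrast tests, and
the 95% CI comes from the normal approximation on the log sample OR.
Degenerate tables (an empty cell) are flagged, not fatal.

`category_contrast()` compares two indel classes within gene categories by
an exact binomial test of the category's class-A count against the global
class-A share; contrasting classes within a category cancels gene-length
and mutation-rate differences between categories. The family-wise error
rate is controlled by Bonferroni — a deliberate simplification relative to
specialised GO machinery with refinement algorithms, which is out of scope
here.

`score_filter()` keeps indels with a phred-scaled deleteriousness C-score
≥ 20 (the top 1% most disruptive variants); `fst_hudson()` ranks
introgressed indels by the per-site Hudson FST estimator between EUR and
EAS. The original analysis does not name its FST estimator; Hudson's was
chosen for its freedom from within-population weighting choices and is
labelled as such.

## Introgression at haplotype scale

`perfect_ld()` implements the tag-SNP criterion: two variants are
completely linked when their genotype dosage vectors are identical over
all individuals, after orienting the SNP to the derived allele (either
orientation may match; with both variants polymorphic this is r² = 1).
Pairs with any missing genotype among the compared individuals are
excluded, a conservative choice. `gwas_link_report()` screens SNPs within
1 Mb at association p ≤ 1e−5.

`shared_extent()` estimates the minimum introgressed segment length as the
intersection, over all carriers of a focal introgressed indel, of each
carrier's maximal contiguous run of carried introgressed variants.
Genotypes are unphased, so "haplotype" is approximated at the individual
level — extents can only be underestimated by this, never inflated.

The competing explanation for a long shared segment is incomplete lineage
sorting. A segment surviving from the human–Neandertal ancestral
population is whittled by recombination for `t` generations on both
lineages; extending independently left and right from a focal point with
exponential(mean `L = 1/(r·t)`) lengths, its total length is
Gamma(shape 2, mean `2L`) and

```
P(length >= m) = (1 + m/L) * exp(-m/L).
```

The shape-2 form follows the approach established for testing candidate
introgressed loci. The branch length default, `t = 19000` generations
(≈ 550 ky at 29 years/generation, consistent with the archaic genome's
split-time estimate), and the cM/Mb → per-bp conversion `1 cM/Mb = 1e−8`
are package choices exposed as arguments; `t` in particular is an
assumption the user should revisit for other split-time beliefs.

```{r}
ils_probability(m = 180900, rate_cm_mb = 0.23, t_generations = 19000)
```

## The synthetic-data generators

Every pipeline stage is testable without external downloads because the
package ships the generators that produce its study conditions.

`simulate_alignment()` plants human-lineage events on an ancestral
sequence: deletions at twice the insertion rate (defaults 1/300 and 1/600
per bp, i.e. ≈ 500 events per 100 kb), lengths uniform on 1–5 bp, a
configurable fraction of events replayed in one random outgroup
(homoplasy), and substitution noise in the outgroups kept ≥ 3 bp away from
event columns. Event contexts are locally adjusted so that gap
left-normalization cannot move a planted run (the anchor base is forced to
differ from the base closing the run); without this, truth positions and
left-aligned calls would disagree in repeat tracts by construction rather
than by error.

`simulate_cohort()` draws background polymorphic sites with a discretized
1/x frequency spectrum (the constant-size coalescent expectation — the
analysis only measures spectra, so a neutral-like shape suffices), a small
fraction of sites at derived frequency 1 everywhere, and plants
introgressed haplotypes: 200 kb runs of variants at ≈ 2 kb spacing, all
carried by the archaic sample and by a few heterozygous EUR/EAS carriers
(targets: derived allele frequency 0.027 in EUR, 0.048 in EAS), with the
derived allele absent from every African individual. Two guarantees keep
the planted truth exact: planted introgressed sites are always
archaic-covered (they would otherwise be undetectable by any method), and
archaic-shared background sites are forced to carry at least one African
derived allele, so the introgression rule has specificity 1 against the
truth table by construction. Sites outside planted haplotypes are
unlinked; this is adequate for rule-based detection but means the
generator does not exercise LD-based methods, background selection, or
demography — passing tests show the rules are implemented correctly, not
that they are robust on real, linked, demographically structured data.

`simulate_mk_counts()` draws 2×2 tables with deletion:insertion rate ratio
`rho` and relative deletion fixation probability `sel_diff`.

## Numerical and design choices

* Coordinates: MAF input is 0-based half-open; emitted positions are the
  1-based coordinate of the base left of the event, with alleles sharing
  that anchor base (VCF indel convention), so reference-scan and cohort
  calls merge on identical keys.
* Gap normalization slides each gap run left while the base before the
  run equals the base after it (leftmost placement in a tandem repeat
  tract), then drops all-gap columns; the operation is idempotent and
  strand-symmetric.
* Unanimity is enforced on the event columns plus the anchor base only;
  outgroup mismatches in flanking columns do not reject. Runs within one
  column of another gap run are rejected as `complex_region`; N or
  soft-masked bases in event columns as `ambiguous_base`. The source
  analyses are silent on these cases; the choices here are conservative.
* "Absent in Africans" means a derived allele count of exactly 0 across
  all African populations — a single carrier disqualifies. Archaic sharing
  needs ≥ 1 derived allele (a heterozygous archaic counts). Missing
  genotypes never enter frequency denominators. AMR/SAS populations are
  ignored by the introgression rule but keep their frequency columns.
* Archaic site-quality filtering is represented only by the coverage mask
  (presence of a called genotype in the archaic VCF); no mappability or
  deamination modelling.
* Calibration test sizes: the neutrality calibration uses 2,000 replicate
  tables of 2,000 fixed + 2,000 polymorphic events, large enough that the
  exact test's discreteness does not bias its rejection rate detectably
  below the nominal 0.05; rate-ratio recovery uses 1e5 draws per stratum.

## Limitations

* The unanimity guard discards genuinely polymorphic outgroup sites and
  all repetitive regions that fail to align in all eight species.
* Fixation status depends on the cohort: an indel called "fixed" is only
  fixed relative to the sampled populations.
* Introgression detection is rule-based; it has no power against
  introgressed alleles that drifted into Africa or were lost from the
  archaic sample, and incomplete lineage sorting can only be argued
  against segment-by-segment via `ils_probability()`.
* `shared_extent()` on unphased genotypes underestimates haplotype
  extents when carriers are heterozygous for recombined haplotypes.
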