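Package: indelstrata
Title: Lineage Assignment and Selection Tests for Small Human Indels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polarizes small (1-5 bp) insertions and deletions on the human
    lineage from an eight-species primate alignment, requiring an identical
    ancestral allele in all seven outgroups to guard against homoplasy.
    Stratifies indels into fixed and polymorphic, archaic-shared and modern
    human specific classes using a Neandertal genotype track, and flags
    putatively introgressed indels (derived allele absent in Africans,
    present in Europeans or East Asians, carried by the archaic genome).
    Implements the accompanying statistics: deletion/insertion ratios,
    modified McDonald-Kreitman contingency contrasts with an underflow-safe
    exact Fisher p-value, derived allele frequency spectrum comparisons,
    region-class enrichment with FDR control, per-category binomial
    contrasts, per-site Hudson FST, perfect-LD pairing of indels with GWAS
    SNPs, shared-haplotype extent, and the closed-form incomplete lineage
    sorting segment-length probability. A synthetic-data module generates
    desk-scale alignments and cohorts with planted truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
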