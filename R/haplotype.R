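#' Perfect linkage disequilibrium between two genotype vectors
#'
#' Two variants are completely linked when every individual carries the
#' identical combination of reference/non-reference genotypes at both.
#' Because VCF orientation is arbitrary, the second vector is also
#' compared after flipping to the opposite allele (`2 - dosage`); perfect
#' LD holds if either orientation matches exactly. With both variants
#' polymorphic this is equivalent to r-squared = 1.
#'
#' @param dosage_a,dosage_b Integer dosage vectors in \{0, 1, 2\} over the
#'   same individuals, without missing entries.
#' @return `TRUE` or `FALSE`.
#' @export
perfect_ld <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) {
    abort("dosage vectors must cover the same individuals")
  }
  if (anyNA(dosage_a) || anyNA(dosage_b)) {
    abort("dosage vectors must be complete (no missing genotypes)")
  }
  all(dosage_a == dosage_b) || all(dosage_a == 2L - dosage_b)
}

#' Shared extent of an introgressed haplotype around a focal indel
#'
#' Estimates the minimum length of the introgressed segment carrying a
#' focal indel: the carriers are the individuals with at least one copy of
#' the focal derived allele; each carrier's run is the maximal contiguous
#' stretch of introgressed variants (in position order) that the carrier
#' carries and that contains the focal variant; the shared extent is the
#' intersection of all carrier runs, reported as the distance between its
#' outermost introgressed variants. Dosages are unphased, so "haplotype"
#' is approximated at the individual level.
#'
#' @param dosages Derived-allele dosage matrix of the introgressed variants
#'   (rows = variants in any order, columns = individuals); `NA` treated as
#'   non-carrier.
#' @param positions Integer vector of 1-based variant positions matching
#'   the rows of `dosages`.
#' @param focal_pos Position of the focal introgressed indel; must be one
#'   of `positions`.
#' @param window Only variants within `window` bp of the focal position
#'   are considered.
#' @return One-row tibble: `focal_pos`, `n_carriers`, `shared_start`,
#'   `shared_end`, `length` (= `shared_end - shared_start + 1`).
#' @export
shared_extent <- function(dosages, positions, focal_pos, window = Inf) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(positions)) {
    abort("`positions` must match the rows of `dosages`")
  }
  o <- order(positions)
  positions <- positions[o]
  dosages <- dosages[o, , drop = FALSE]
  keep <- abs(positions - focal_pos) <= window
  positions <- positions[keep]
  dosages <- dosages[keep, , drop = FALSE]

  fi <- match(focal_pos, positions)
  if (is.na(fi)) abort("`focal_pos` is not among the introgressed variants")

  carried <- !is.na(dosages) & dosages >= 1L
  carriers <- which(carried[fi, ])
  if (length(carriers) == 0) abort("no carrier of the focal derived allele")

  lo <- 1L; hi <- length(positions)
  for (ind in carriers) {
    v <- carried[, ind]
    i <- fi
    while (i > 1L && v[i - 1L]) i <- i - 1L
    j <- fi
    while (j < length(v) && v[j + 1L]) j <- j + 1L
    lo <- max(lo, i)
    hi <- min(hi, j)
  }
  tibble(
    focal_pos = focal_pos,
    n_carriers = length(carriers),
    shared_start = positions[lo],
    shared_end = positions[hi],
    length = positions[hi] - positions[lo] + 1L
  )
}

#' Pair introgressed indels with trait-associated SNPs in perfect LD
#'
#' Indels are usually absent from GWAS panels; an introgressed indel can
#' nonetheless be tied to a phenotype through a tag SNP whose genotype
#' pattern is identical in every individual. For each introgressed indel,
#' SNPs within `window` bp with association `p <= p_max` are screened for
#' perfect LD against the indel's derived-dosage vector; pairs with any
#' missing genotype among the compared individuals are excluded
#' (conservative).
#'
#' @param indels Stratified indel tibble with `introgressed`, `daf_*`
#'   columns, and allele columns.
#' @param gwas Tibble of SNP associations: `chrom`, `pos`, `rsid`, `p`,
#'   `trait`.
#' @param panel `genotype_panel` containing genotypes for both the indels
#'   and the GWAS SNPs.
#' @param window Search window around each indel in bp.
#' @param p_max Association p-value ceiling.
#' @param superpops Population to super-population map used to report
#'   EUR/EAS derived allele frequencies.
#' @return Tibble with one row per linked indel-SNP-trait combination:
#'   indel and SNP positions, rsid, p, trait, EUR/EAS derived allele
#'   frequency of the indel, and `score` when present in `indels`.
#' @export
gwas_link_report <- function(indels, gwas, panel, window = 1e6,
                             p_max = 1e-5,
                             superpops = default_superpops()) {
  gwas <- as_tibble(gwas)
  intro <- filter(indels, .data$introgressed)
  out <- list()
  if (nrow(intro) == 0 || nrow(gwas) == 0) return(gwas_report_empty())

  daf_cols <- grep("^daf_", names(intro), value = TRUE)
  sp <- superpops$superpop[match(sub("^daf_", "", daf_cols),
                                 superpops$population)]
  eur_cols <- daf_cols[!is.na(sp) & sp == "EUR"]
  eas_cols <- daf_cols[!is.na(sp) & sp == "EAS"]

  for (i in seq_len(nrow(intro))) {
    row <- intro[i, ]
    vi <- which(panel$variants$chrom == row$chrom &
                  panel$variants$pos == row$pos)
    if (length(vi) != 1L) next
    dos_indel <- panel$dosages[vi, ]
    # orient to the derived allele
    if (row$derived == panel$variants$ref[vi]) dos_indel <- 2L - dos_indel

    cand <- filter(gwas, .data$chrom == row$chrom,
                   abs(.data$pos - row$pos) <= window,
                   .data$p <= p_max)
    for (k in seq_len(nrow(cand))) {
      snp <- cand[k, ]
      si <- which(panel$variants$chrom == snp$chrom &
                    panel$variants$pos == snp$pos)
      if (length(si) != 1L) next
      dos_snp <- panel$dosages[si, ]
      if (anyNA(dos_indel) || anyNA(dos_snp)) next
      if (!perfect_ld(dos_indel, dos_snp)) next
      out[[length(out) + 1L]] <- tibble(
        chrom = row$chrom,
        indel_pos = row$pos,
        snp_pos = snp$pos,
        rsid = snp$rsid,
        p = snp$p,
        trait = snp$trait,
        eur_af = if (length(eur_cols)) mean(unlist(row[eur_cols]),
                                            na.rm = TRUE) else NA_real_,
        eas_af = if (length(eas_cols)) mean(unlist(row[eas_cols]),
                                            na.rm = TRUE) else NA_real_,
        score = if ("score" %in% names(row)) row$score else NA_real_
      )
    }
  }
  if (length(out) == 0) return(gwas_report_empty())
  bind_rows(out) %>% arrange(.data$chrom, .data$indel_pos, .data$p)
}

gwas_report_empty <- function() {
  tibble(chrom = character(), indel_pos = integer(), snp_pos = integer(),
         rsid = character(), p = numeric(), trait = character(),
         eur_af = numeric(), eas_af = numeric(), score = numeric())
}
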