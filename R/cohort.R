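#' Load 1-5 bp biallelic indels from a cohort VCF into a genotype panel
#'
#' Reads a cohort VCF (plain or bgzipped) and keeps only biallelic indel
#' records whose REF/ALT length difference is between `min_len` and
#' `max_len` bp. Symbolic alleles (`<CN0>`, `<INS>`, ...) describe copy
#' number and structural events longer than the scale considered here and
#' are excluded; multiallelic sites (more than one derived variant) are
#' dropped entirely. Genotypes are tabulated as ALT-allele dosages in
#' \{0, 1, 2, NA\}.
#'
#' @param vcf Path to the cohort VCF.
#' @param pops Data frame with columns `individual` and `population`, or a
#'   path to a two-column TSV. Every individual in the VCF must appear here.
#' @param min_len,max_len Inclusive allele-length-difference bounds in bp.
#' @return A `genotype_panel`: list with `variants` (tibble: chrom, pos, ref,
#'   alt, length, event relative to REF), `dosages` (variant x individual
#'   integer matrix), and `pops` (tibble individual/population).
#' @export
load_cohort_indels <- function(vcf, pops, min_len = 1L, max_len = 5L) {
  pops <- read_pops(pops)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(gt)

  inds <- colnames(gt)
  missing_inds <- setdiff(inds, pops$individual)
  if (length(missing_inds) > 0) {
    abort(paste0("individuals in VCF absent from the population table: ",
                 paste(missing_inds, collapse = ", ")))
  }

  ref <- fix$REF
  alt <- fix$ALT
  biallelic <- !grepl(",", alt, fixed = TRUE)
  plain <- grepl("^[ACGTacgt]+$", ref) & grepl("^[ACGTacgt]+$", alt)
  plain[is.na(plain)] <- FALSE
  diff_len <- abs(nchar(alt) - nchar(ref))
  keep <- biallelic & plain & !is.na(diff_len) &
    diff_len >= min_len & diff_len <= max_len
  keep[is.na(keep)] <- FALSE

  variants <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = toupper(ref[keep]),
    alt = toupper(alt[keep]),
    length = diff_len[keep]
  )
  dos <- gt_to_dosage(gt[keep, , drop = FALSE])
  rownames(dos) <- NULL
  new_genotype_panel(variants, dos, pops)
}

# "0/1", "0|1", "./." ... -> ALT dosage 0/1/2/NA
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]
  d
}

new_genotype_panel <- function(variants, dosages, pops) {
  stopifnot(nrow(variants) == nrow(dosages),
            ncol(dosages) == nrow(pops) || ncol(dosages) == 0 ||
              all(colnames(dosages) %in% pops$individual))
  structure(
    list(variants = variants, dosages = dosages, pops = pops),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d variants x %d individuals (%d populations)\n",
              nrow(x$variants), ncol(x$dosages),
              length(unique(x$pops$population))))
  invisible(x)
}

read_pops <- function(pops) {
  if (is.character(pops) && length(pops) == 1L) {
    pops <- utils::read.table(pops, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  pops <- as_tibble(pops)
  if (!all(c("individual", "population") %in% names(pops))) {
    abort("population table needs columns `individual` and `population`")
  }
  pops
}

#' Derived-orientation allele frequencies per population
#'
#' ALT-allele frequency of every panel variant in every population, using
#' called genotypes only (missing genotypes are excluded from the
#' denominator).
#'
#' @param panel A `genotype_panel`.
#' @return Matrix (variants x populations) of ALT allele frequencies.
#' @export
panel_alt_freq <- function(panel) {
  pops <- unique(panel$pops$population)
  out <- matrix(NA_real_, nrow = nrow(panel$variants), ncol = length(pops),
                dimnames = list(NULL, pops))
  for (p in pops) {
    inds <- panel$pops$individual[panel$pops$population == p]
    d <- panel$dosages[, colnames(panel$dosages) %in% inds, drop = FALSE]
    called <- rowSums(!is.na(d))
    out[, p] <- ifelse(called > 0, rowSums(d, na.rm = TRUE) / (2 * called),
                       NA_real_)
  }
  out
}

#' Load an archaic genotype track from a VCF
#'
#' The archaic (Neandertal) VCF carries one sample; a site is considered
#' covered when it appears in the file with a called genotype, and the
#' coverage mask downstream is exactly this presence/absence. Monomorphic
#' reference records (ALT = ".") are kept with dosage 0.
#'
#' @param vcf Path to the archaic VCF.
#' @return Tibble with columns chrom, pos, ref, alt, dosage (ALT dosage).
#' @export
load_archaic_track <- function(vcf) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- t(gt)
  dos <- gt_to_dosage(gt)[, 1]
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = ifelse(is.na(fix$ALT) | fix$ALT == ".", NA_character_,
                 toupper(fix$ALT)),
    dosage = as.integer(dos)
  )
  filter(out, !is.na(.data$dosage))
}

# getFIX() collapses to a bare vector for single-record files
vcf_fix_frame <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  as.data.frame(fix, stringsAsFactors = FALSE)
}
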