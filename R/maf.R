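#' Alignment block constructor
#'
#' A light container for one multiple-alignment block anchored on the human
#' reference: equal-length gapped sequences for the human and the seven
#' outgroups, plus reference coordinates. Blocks are produced by [read_maf()]
#' and consumed by [normalize_gaps()] and [call_reference_indels()].
#'
#' @param ref_chrom Human reference chromosome name.
#' @param ref_start 0-based start of the human sequence on `ref_chrom`.
#' @param seqs Named character vector of gapped sequences (names are species
#'   labels); all the same length; human first in `species_order`.
#' @param species_order Character vector of the 8 species labels, human first.
#' @param strand Reference strand; always `"+"` after ingestion.
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(ref_chrom, ref_start, seqs, species_order,
                            strand = "+") {
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L) {
    abort("all gapped sequences in a block must have identical length")
  }
  if (!all(species_order %in% names(seqs)) ||
      length(seqs) != length(species_order)) {
    abort("`seqs` must contain exactly the species in `species_order`")
  }
  structure(
    list(
      ref_chrom = ref_chrom,
      ref_start = as.integer(ref_start),
      strand = strand,
      seqs = seqs[species_order],
      species_order = species_order
    ),
    class = "alignment_block"
  )
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf(
    "<alignment_block> %s:%d (+), %d species, %d columns\n",
    x$ref_chrom, x$ref_start, length(x$seqs), nchar(x$seqs[[1]])
  ))
  invisible(x)
}

# human ungapped length of a block
block_ref_width <- function(block) {
  human <- block$seqs[[block$species_order[1]]]
  nchar(gsub("-", "", human, fixed = TRUE))
}

revcomp <- function(s) {
  chartr(
    "ACGTRYSWKMBDHVNacgtryswkmbdhvn",
    "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
    vapply(strsplit(s, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
  )
}

#' Read an eight-species MAF alignment
#'
#' Parses multiz-style MAF `s` lines into [alignment_block()] objects. Only
#' blocks that contain sequence from all eight configured species are
#' retained, because the ancestral allele is defined by unanimity of the
#' seven outgroups; blocks missing any species carry no usable polarization
#' signal and are dropped. Blocks whose human row is on the `-` strand are
#' reverse-complemented so that all downstream coordinates are forward-strand.
#'
#' @param path Path to a MAF file.
#' @param species Named vector of 8 species labels, human first; see
#'   [default_species()].
#' @return List of `alignment_block` objects (possibly empty).
#' @export
read_maf <- function(path, species = default_species()) {
  check_species(species)
  lines <- readLines(path)
  human_label <- species[[1]]

  blocks <- list()
  cur <- NULL      # accumulating s-lines for the current block
  cur_lines <- integer()

  flush_block <- function(srecs) {
    if (length(srecs) == 0) return(NULL)
    labs <- vapply(srecs, `[[`, character(1), "species")
    if (anyDuplicated(labs)) {
      abort(sprintf("MAF block near line %d lists species '%s' twice",
                    srecs[[1]]$line, labs[anyDuplicated(labs)]))
    }
    if (!all(species %in% labs)) return(NULL)  # incomplete block: dropped
    srecs <- srecs[match(species, labs)]
    widths <- vapply(srecs, function(r) nchar(r$text), integer(1))
    if (length(unique(widths)) != 1L) {
      abort(sprintf("MAF block near line %d has rows of unequal length",
                    srecs[[1]]$line))
    }
    human <- srecs[[1]]
    seqs <- setNames(
      vapply(srecs, `[[`, character(1), "text"),
      vapply(srecs, `[[`, character(1), "species")
    )
    ref_start <- human$start
    if (human$strand == "-") {
      seqs <- vapply(seqs, revcomp, character(1))
      ref_start <- human$src_size - (human$start + human$size)
    }
    alignment_block(
      ref_chrom = human$chrom,
      ref_start = ref_start,
      seqs = seqs,
      species_order = unname(species)
    )
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (startsWith(line, "a")) {
      b <- flush_block(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- list()
    } else if (startsWith(line, "s")) {
      if (is.null(cur)) {
        abort(sprintf("MAF line %d: 's' record outside an 'a' block", i))
      }
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(f) != 7L) {
        abort(sprintf("MAF line %d: expected 7 fields in 's' record, got %d",
                      i, length(f)))
      }
      src <- f[2]
      # species labels may themselves contain dots (e.g. panpan1.1), so match
      # the configured labels as prefixes of "label.chrom"
      hit <- species[src == species | startsWith(src, paste0(species, "."))]
      if (length(hit) == 0) {
        abort(sprintf("MAF line %d: species label '%s' is not in the configured panel",
                      i, sub("\\.[^.]*$", "", src)))
      }
      sp <- hit[which.max(nchar(hit))]
      chrom <- if (nchar(src) > nchar(sp)) {
        substr(src, nchar(sp) + 2L, nchar(src))
      } else {
        NA_character_
      }
      size <- suppressWarnings(as.integer(f[4]))
      txt <- f[7]
      if (is.na(size) ||
          nchar(gsub("-", "", txt, fixed = TRUE)) != size) {
        abort(sprintf("MAF line %d: sequence length does not match declared size", i))
      }
      cur[[length(cur) + 1L]] <- list(
        species = sp, chrom = chrom,
        start = suppressWarnings(as.integer(f[3])), size = size,
        strand = f[5], src_size = suppressWarnings(as.integer(f[6])),
        text = txt, line = i
      )
    }
    # other line types (#, i, e, q, empty) are ignored
  }
  b <- flush_block(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

# Write blocks back out as MAF (used by the simulator). `starts` bookkeeping is
# carried inside each block's attributes when present; outgroup coordinates are
# informational only.
write_maf <- function(blocks, path, species = default_species()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (block in blocks) {
    writeLines("", con)
    writeLines("a score=0.0", con)
    meta <- attr(block, "maf_meta")
    for (sp in block$species_order) {
      seqtxt <- block$seqs[[sp]]
      size <- nchar(gsub("-", "", seqtxt, fixed = TRUE))
      if (sp == block$species_order[1]) {
        src <- paste0(sp, ".", block$ref_chrom)
        start <- block$ref_start
      } else {
        src <- paste0(sp, ".", block$ref_chrom)
        start <- if (!is.null(meta)) meta$starts[[sp]] else 0L
      }
      srcsize <- if (!is.null(meta)) meta$src_size else start + size
      writeLines(sprintf("s %s %d %d + %d %s", src, start, size, srcsize, seqtxt),
                 con)
    }
  }
  invisible(path)
}
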