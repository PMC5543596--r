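#' Left-normalize gaps within an alignment block
#'
#' Canonicalizes gap placement so that identical events are represented
#' identically across species before indel calling. Each gap run is shifted
#' to its leftmost equivalent placement within its repeat context (the run
#' moves left one column while the base immediately before the run equals the
#' base immediately after it), mirroring the left-alignment convention used
#' for VCF indels. Columns that become gap in every species are removed.
#' The operation is idempotent.
#'
#' @param block An [alignment_block()].
#' @return The normalized `alignment_block`.
#' @export
normalize_gaps <- function(block) {
  mat <- block_matrix(block)
  for (r in seq_len(nrow(mat))) {
    mat[r, ] <- shift_gaps_left(mat[r, ])
  }
  all_gap <- colSums(mat != "-") == 0L
  if (any(all_gap)) mat <- mat[, !all_gap, drop = FALSE]
  block$seqs <- setNames(
    apply(mat, 1L, paste, collapse = ""),
    rownames(mat)
  )[block$species_order]
  block
}

# character matrix view of a block: rows = species, cols = alignment columns
block_matrix <- function(block) {
  chars <- strsplit(unname(block$seqs), "", fixed = TRUE)
  mat <- do.call(rbind, chars)
  rownames(mat) <- names(block$seqs)
  mat
}

# shift every gap run leftwards while the base preceding the run equals the
# base following it (equivalent placement in a repeat tract)
shift_gaps_left <- function(ch) {
  n <- length(ch)
  runs <- gap_runs(ch)
  if (nrow(runs) == 0) return(ch)
  for (k in seq_len(nrow(runs))) {
    i <- runs$start[k]; j <- runs$end[k]
    while (i > 1L && j < n && ch[i - 1L] != "-" && ch[i - 1L] == ch[j + 1L]) {
      ch[j] <- ch[i - 1L]
      ch[i - 1L] <- "-"
      i <- i - 1L; j <- j - 1L
    }
  }
  ch
}

# start/end columns of maximal gap runs in a character vector
gap_runs <- function(ch) {
  is_gap <- ch == "-"
  if (!any(is_gap)) return(tibble(start = integer(), end = integer()))
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}
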