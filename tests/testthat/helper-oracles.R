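# Shared fixtures and independent oracles used across the suite.

# build an 8-species block from a human row and a shared outgroup row;
# individual outgroups can be overridden by assembly label
make_block <- function(human, outgroup, ref_start = 0, chrom = "chr1",
                       overrides = list()) {
  sp <- default_species()
  seqs <- c(
    stats::setNames(human, sp[[1]]),
    stats::setNames(rep(outgroup, 7), unname(sp[-1]))
  )
  for (nm in names(overrides)) seqs[[nm]] <- overrides[[nm]]
  alignment_block(chrom, ref_start, seqs, unname(sp))
}

# independent column-by-column indel scanner: walks alignment columns of a
# clean (already normalized) block and emits deletion/insertion calls under
# the unanimity rule, with no shared code with the package implementation
oracle_scan <- function(block, min_len = 1, max_len = 5) {
  m <- do.call(rbind, strsplit(unname(block$seqs), "", fixed = TRUE))
  nc <- ncol(m)
  hpos <- block$ref_start + cumsum(m[1, ] != "-")
  gapcol <- apply(m == "-", 2, any)
  out <- list()
  col <- 1
  while (col <= nc) {
    if (!gapcol[col]) { col <- col + 1; next }
    start <- col
    while (col <= nc && gapcol[col]) col <- col + 1
    end <- col - 1
    len <- end - start + 1
    near <- (start - 2 >= 1 && gapcol[start - 2]) ||
      (end + 2 <= nc && gapcol[end + 2])
    if (near || len < min_len || len > max_len || start == 1) next
    anchor <- m[1, start - 1]
    if (!anchor %in% c("A", "C", "G", "T")) next
    hrun <- m[1, start:end]
    orun <- m[2:8, start:end, drop = FALSE]
    ostr <- apply(orun, 1, paste, collapse = "")
    if (all(hrun == "-") && all(!grepl("-", ostr, fixed = TRUE)) &&
        length(unique(ostr)) == 1 && grepl("^[ACGT]+$", ostr[1])) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = block$ref_chrom, pos = hpos[start - 1], length = len,
        event = "deletion", ancestral = paste0(anchor, ostr[1]),
        derived = anchor
      )
    } else if (all(hrun != "-") && all(ostr == strrep("-", len)) &&
               grepl("^[ACGT]+$", paste(hrun, collapse = ""))) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = block$ref_chrom, pos = hpos[start - 1], length = len,
        event = "insertion", ancestral = anchor,
        derived = paste0(anchor, paste(hrun, collapse = ""))
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    chrom = character(), pos = integer(), length = integer(),
    event = character(), ancestral = character(), derived = character()
  )
}

# exact two-sided Fisher p by direct enumeration with binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  k <- a + b; m <- a + c; N <- a + b + c + d
  xs <- max(0, k - (N - m)):min(k, m)
  probs <- choose(m, xs) * choose(N - m, k - xs) / choose(N, k)
  p_obs <- choose(m, a) * choose(N - m, k - a) / choose(N, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all group assignments
# (doubling rule, as in the exact Wilcoxon test)
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b); n <- length(a); N <- length(x)
  r <- rank(x)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(N, n)
  ws <- apply(combs, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# quadrature oracle for the ILS survival probability: integrate the
# shape-2 gamma density x exp(-x/L)/L^2 from m to infinity
oracle_ils_p <- function(m, L) {
  # truncate the upper limit where the integrand is < 1e-30 of its peak
  stats::integrate(function(x) x * exp(-x / L) / L^2, m, m + 100 * L,
                   rel.tol = 1e-12, abs.tol = 1e-14,
                   subdivisions = 500L)$value
}

# reverse-complement a block (columns reversed, bases complemented)
revcomp_block <- function(block) {
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(strsplit(s, "", fixed = TRUE),
                  function(ch) paste(rev(ch), collapse = ""), character(1)))
  }
  block$seqs <- vapply(block$seqs, rc, character(1))
  block
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
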