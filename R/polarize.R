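#' Call human-lineage indels from one alignment block
#'
#' Scans a gap-normalized block for maximal gap runs of 1-5 bp and polarizes
#' them on the human lineage under the homoplasy guard: a human deletion is
#' called only where the human row is gapped and all seven outgroups carry an
#' identical ungapped allele; a human insertion only where the human row
#' carries bases and all seven outgroups are gapped. Runs where outgroups
#' disagree with each other, mix gap and base states, contain ambiguous or
#' soft-masked bases, sit within one column of another gap run, or exceed the
#' length bound are routed to a rejection table with a reason code rather
#' than silently skipped, so that homoplasy candidates remain auditable.
#'
#' Emitted positions follow the VCF indel convention: `pos` is the 1-based
#' human reference coordinate of the base immediately left of the event, and
#' the ancestral/derived alleles share that anchor base.
#'
#' @param block A normalized [alignment_block()] (see [normalize_gaps()]).
#' @param min_len,max_len Inclusive bounds on event length in bp.
#' @return List with `calls` (tibble: chrom, pos, length, event, ancestral,
#'   derived, origin) and `rejected` (tibble: chrom, pos, length, reason).
#' @export
call_reference_indels <- function(block, min_len = 1L, max_len = 5L) {
  mat <- block_matrix(block)
  human <- mat[1, ]
  outs <- mat[-1, , drop = FALSE]
  n_col <- ncol(mat)

  any_gap <- colSums(mat == "-") > 0L
  runs <- gap_runs(ifelse(any_gap, "-", "A"))

  calls <- list()
  rejected <- list()
  emit_reject <- function(pos, len, reason) {
    rejected[[length(rejected) + 1L]] <<- tibble(
      chrom = block$ref_chrom, pos = pos, length = len, reason = reason
    )
  }

  if (nrow(runs) == 0) {
    return(list(calls = empty_calls(), rejected = empty_rejections()))
  }

  # cumulative human (reference) bases per column, for coordinate mapping
  hb <- cumsum(human != "-")

  # runs within <= 1 intervening column of another gap run are complex
  complex_flag <- rep(FALSE, nrow(runs))
  if (nrow(runs) > 1) {
    gaps_between <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
    for (k in which(gaps_between <= 1L)) {
      complex_flag[k] <- TRUE
      complex_flag[k + 1L] <- TRUE
    }
  }

  for (k in seq_len(nrow(runs))) {
    i <- runs$start[k]; j <- runs$end[k]
    len <- j - i + 1L
    anchor_col <- i - 1L
    pos <- if (anchor_col >= 1L) {
      block$ref_start + hb[anchor_col]
    } else {
      NA_integer_
    }

    if (complex_flag[k]) {
      emit_reject(pos, len, "complex_region")
      next
    }
    if (len > max_len || len < min_len) {
      emit_reject(pos, len, "length_out_of_range")
      next
    }
    if (anchor_col < 1L || human[anchor_col] == "-") {
      emit_reject(pos, len, "block_edge")
      next
    }

    human_run <- human[i:j]
    out_run <- outs[, i:j, drop = FALSE]
    human_gapped <- all(human_run == "-")
    human_clean <- all(human_run != "-")
    out_gapped <- apply(out_run == "-", 1L, all)
    out_clean <- apply(out_run != "-", 1L, all)

    anchor <- human[anchor_col]
    if (!grepl("^[ACGT]$", anchor)) {
      emit_reject(pos, len, "ambiguous_base")
      next
    }

    if (human_gapped && all(out_clean)) {
      alleles <- apply(out_run, 1L, paste, collapse = "")
      if (length(unique(alleles)) != 1L) {
        emit_reject(pos, len, "outgroup_disagreement")
        next
      }
      anc_run <- alleles[[1]]
      if (grepl("[^ACGT]", anc_run)) {
        emit_reject(pos, len, "ambiguous_base")
        next
      }
      calls[[length(calls) + 1L]] <- tibble(
        chrom = block$ref_chrom, pos = pos, length = len,
        event = "deletion",
        ancestral = paste0(anchor, anc_run),
        derived = anchor,
        origin = "reference_scan"
      )
    } else if (human_clean && all(out_gapped)) {
      ins <- paste(human_run, collapse = "")
      if (grepl("[^ACGT]", ins)) {
        emit_reject(pos, len, "ambiguous_base")
        next
      }
      calls[[length(calls) + 1L]] <- tibble(
        chrom = block$ref_chrom, pos = pos, length = len,
        event = "insertion",
        ancestral = anchor,
        derived = paste0(anchor, ins)
      ) %>% mutate(origin = "reference_scan")
    } else {
      # outgroups mix gap and base states, or some share the human state:
      # the hallmark of homoplasy / lineage-discordant events
      emit_reject(pos, len, "outgroup_disagreement")
    }
  }

  list(
    calls = if (length(calls)) bind_rows(calls) else empty_calls(),
    rejected = if (length(rejected)) bind_rows(rejected) else empty_rejections()
  )
}

empty_calls <- function() {
  tibble(
    chrom = character(), pos = integer(), length = integer(),
    event = character(), ancestral = character(), derived = character(),
    origin = character()
  )
}

empty_rejections <- function() {
  tibble(chrom = character(), pos = integer(), length = integer(),
         reason = character())
}

#' Scan a whole alignment for human-lineage indels
#'
#' Normalizes every block, calls indels with [call_reference_indels()], and
#' aggregates the results: calls are sorted by position, duplicate calls from
#' overlapping blocks are collapsed, and positions where overlapping blocks
#' yield contradictory alleles are dropped from the call set and logged.
#'
#' @param blocks List of [alignment_block()] objects (e.g., from
#'   [read_maf()]).
#' @inheritParams call_reference_indels
#' @return List with `calls` and `rejected` tibbles (see
#'   [call_reference_indels()]); contradictory overlaps appear in `rejected`
#'   with reason `conflicting_overlap`.
#' @export
scan_alignment <- function(blocks, min_len = 1L, max_len = 5L) {
  res <- purrr::map(blocks, function(b) {
    call_reference_indels(normalize_gaps(b), min_len = min_len,
                          max_len = max_len)
  })
  calls <- bind_rows(purrr::map(res, "calls"))
  rejected <- bind_rows(purrr::map(res, "rejected"))
  if (nrow(calls) == 0) {
    return(list(calls = empty_calls(), rejected = rejected))
  }
  calls <- distinct(calls) %>% arrange(.data$chrom, .data$pos)
  # contradictory calls: same site, different alleles or event
  dup_sites <- calls %>%
    count(.data$chrom, .data$pos) %>%
    filter(n > 1L) %>%
    select("chrom", "pos")
  if (nrow(dup_sites) > 0) {
    dropped <- semi_join(calls, dup_sites, by = c("chrom", "pos"))
    calls <- anti_join(calls, dup_sites, by = c("chrom", "pos"))
    rejected <- bind_rows(
      rejected,
      dropped %>%
        select("chrom", "pos", "length") %>%
        mutate(reason = "conflicting_overlap")
    )
  }
  list(calls = calls, rejected = rejected)
}
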