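test_that("a unanimous outgroup base opposite a human gap is a deletion", {
  b <- make_block("ACG-TA", "ACGTTA")
  res <- call_reference_indels(normalize_gaps(b))
  expect_equal(nrow(res$calls), 1)
  call <- res$calls[1, ]
  expect_equal(call$event, "deletion")
  expect_equal(call$length, 1L)
  expect_equal(call$pos, 3L)          # anchor = the G at reference pos 3
  expect_equal(call$ancestral, "GT")
  expect_equal(call$derived, "G")
  expect_equal(call$origin, "reference_scan")
})

test_that("a human run opposite unanimous outgroup gaps is an insertion", {
  b <- make_block("ACGTTA", "ACG-TA")
  res <- call_reference_indels(normalize_gaps(b))
  expect_equal(nrow(res$calls), 1)
  call <- res$calls[1, ]
  expect_equal(call$event, "insertion")
  expect_equal(call$length, 1L)
  expect_equal(call$pos, 3L)
  expect_equal(call$ancestral, "G")
  expect_equal(call$derived, "GT")
})

test_that("outgroup disagreement rejects the run (homoplasy guard)", {
  # marmoset carries a C where the others carry T
  b <- make_block("ACG-TA", "ACGTTA",
                  overrides = list(calJac3 = "ACGCTA"))
  res <- call_reference_indels(normalize_gaps(b))
  expect_equal(nrow(res$calls), 0)
  expect_equal(res$rejected$reason, "outgroup_disagreement")

  # one outgroup shares the human gap: mixed gap/base states
  b2 <- make_block("ACG-TA", "ACGTTA",
                   overrides = list(panTro4 = "ACG-TA"))
  res2 <- call_reference_indels(normalize_gaps(b2))
  expect_equal(nrow(res2$calls), 0)
  expect_equal(res2$rejected$reason, "outgroup_disagreement")
})

test_that("ambiguous and soft-masked bases reject the run", {
  bN <- make_block("ACG-TA", "ACGNTA")
  expect_equal(call_reference_indels(bN)$rejected$reason, "ambiguous_base")
  blc <- make_block("ACG-TA", "ACGtTA")
  expect_equal(call_reference_indels(blc)$rejected$reason, "ambiguous_base")
})

test_that("length bounds and adjacency are enforced", {
  b_long <- make_block("AC------TA", "ACGTGTGTTA")
  res <- call_reference_indels(normalize_gaps(b_long))
  expect_equal(nrow(res$calls), 0)
  expect_equal(res$rejected$reason, "length_out_of_range")

  # two runs separated by a single base column -> complex region, both out
  b_near <- make_block("ACG-T-AA", "ACGTTCAA")
  res2 <- call_reference_indels(b_near)
  expect_equal(nrow(res2$calls), 0)
  expect_equal(res2$rejected$reason, rep("complex_region", 2))

  # a gap run with no preceding human base cannot be anchored
  b_edge <- make_block("-CGTTA", "ACGTTA")
  res3 <- call_reference_indels(b_edge)
  expect_equal(res3$rejected$reason, "block_edge")
})

test_that("calls are invariant to reverse-complementing the block", {
  sim <- simulate_alignment(sim_config(seed = 21, n_blocks = 2,
                                       block_length = 900,
                                       homoplasy_rate = 0))
  for (b in sim$blocks) {
    fwd <- call_reference_indels(normalize_gaps(b))$calls
    width <- nchar(gsub("-", "", b$seqs[[1]]))
    rev_calls <- call_reference_indels(normalize_gaps(revcomp_block(b)))$calls
    expect_equal(nrow(rev_calls), nrow(fwd))
    # reverse-complementation anchors each event at the base on its other
    # side: a deletion anchored at offset q maps back to width - q, an
    # insertion of length L to width - q - L
    q <- rev_calls$pos - b$ref_start
    mapped <- ifelse(rev_calls$event == "deletion",
                     width - q, width - q - rev_calls$length)
    mapped_tbl <- tibble::tibble(pos = b$ref_start + mapped,
                                 event = rev_calls$event,
                                 length = rev_calls$length)
    expect_equal(
      dplyr::arrange(mapped_tbl, pos),
      dplyr::arrange(fwd[c("pos", "event", "length")], pos)
    )
  }
})

test_that("the brute-force column scanner yields the identical call set", {
  sim <- simulate_alignment(sim_config(seed = 33, n_blocks = 5,
                                       block_length = 1200,
                                       homoplasy_rate = 0.15))
  for (b in sim$blocks) {
    nb <- normalize_gaps(b)
    impl <- call_reference_indels(nb)$calls
    orc <- oracle_scan(nb)
    expect_equal(
      dplyr::arrange(impl[names(orc)], pos),
      dplyr::arrange(orc, pos)
    )
    expect_true(all(impl$length >= 1 & impl$length <= 5))
  }
})

test_that("scan_alignment collapses duplicates and drops contradictions", {
  b1 <- make_block("ACG-TA", "ACGTTA")
  b2 <- make_block("ACG-TA", "ACGTTA")       # identical overlapping call
  res <- scan_alignment(list(b1, b2))
  expect_equal(nrow(res$calls), 1)

  # overlapping blocks disagreeing at the same position: both dropped
  b3 <- make_block("ACGT-A", "ACGTTA", ref_start = 0)
  b4 <- make_block("ACGTCA", "ACGT-A", ref_start = 0)  # insertion at pos 4
  res2 <- scan_alignment(list(b3, b4))
  expect_equal(nrow(res2$calls), 0)
  expect_true(all(res2$rejected$reason == "conflicting_overlap"))

  empty <- scan_alignment(list())
  expect_equal(nrow(empty$calls), 0)
  expect_equal(nrow(empty$rejected), 0)
})
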