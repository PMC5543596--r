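#' Configuration for the synthetic alignment and cohort generators
#'
#' Collects every tunable of the simulators with defaults matching the
#' study conditions the pipeline is designed for: deletions arise at twice
#' the insertion rate, event lengths are uniform on 1-5 bp, the cohort has
#' three super-populations of 100 individuals each, planted introgressed
#' haplotypes are 200 kb with ~2 kb variant spacing and target derived
#' allele frequencies of 0.027 (EUR) and 0.048 (EAS), and the archaic
#' track covers 90% of sites. Identical configurations (including the
#' seed) produce byte-identical output files.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_blocks,block_length Alignment size: number of blocks and
#'   ancestral bp per block.
#' @param deletion_rate,insertion_rate Per-bp probabilities of planting a
#'   human-lineage deletion/insertion.
#' @param homoplasy_rate Fraction of planted events that are also given to
#'   one randomly chosen outgroup (independent identical event).
#' @param substitution_rate Per-bp outgroup substitution noise, kept away
#'   from event columns.
#' @param n_individuals Named vector of diploid individuals per
#'   super-population (AFR, EUR, EAS).
#' @param site_count Background polymorphic indel sites in the cohort.
#' @param fixed_fraction Fraction of extra cohort sites carried at derived
#'   frequency 1 in every population.
#' @param shared_fraction Fraction of background sites whose derived
#'   allele is carried by the archaic genome.
#' @param n_introgressed,introgression_length,introgression_spacing Number
#'   of planted introgressed haplotypes, their span in bp, and the mean
#'   spacing between their variants.
#' @param target_freq Named vector of target derived allele frequencies
#'   for planted introgressed variants in EUR and EAS.
#' @param archaic_coverage Fraction of background sites covered by the
#'   archaic track.
#' @param chrom Chromosome label used by both simulators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_blocks = 25L,
                       block_length = 4000L,
                       deletion_rate = 1 / 300,
                       insertion_rate = 1 / 600,
                       homoplasy_rate = 0.1,
                       substitution_rate = 0.005,
                       n_individuals = c(AFR = 100L, EUR = 100L, EAS = 100L),
                       site_count = 1000L,
                       fixed_fraction = 0.05,
                       shared_fraction = 0.3,
                       n_introgressed = 5L,
                       introgression_length = 200000L,
                       introgression_spacing = 2000L,
                       target_freq = c(EUR = 0.027, EAS = 0.048),
                       archaic_coverage = 0.9,
                       chrom = "chr1") {
  cfg <- list(
    seed = as.integer(seed), n_blocks = as.integer(n_blocks),
    block_length = as.integer(block_length),
    deletion_rate = deletion_rate, insertion_rate = insertion_rate,
    homoplasy_rate = homoplasy_rate,
    substitution_rate = substitution_rate,
    n_individuals = n_individuals, site_count = as.integer(site_count),
    fixed_fraction = fixed_fraction, shared_fraction = shared_fraction,
    n_introgressed = as.integer(n_introgressed),
    introgression_length = as.integer(introgression_length),
    introgression_spacing = as.integer(introgression_spacing),
    target_freq = target_freq, archaic_coverage = archaic_coverage,
    chrom = chrom
  )
  probs <- c(cfg$deletion_rate, cfg$insertion_rate, cfg$homoplasy_rate,
             cfg$substitution_rate, cfg$fixed_fraction,
             cfg$shared_fraction, cfg$archaic_coverage, cfg$target_freq)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if ((cfg$deletion_rate + cfg$insertion_rate) > 1 / 20) {
    abort("indel rates too high: planted events cannot be packed with clean flanks")
  }
  if (any(c(cfg$n_blocks, cfg$block_length, cfg$site_count,
            cfg$n_introgressed) < 0)) {
    abort("counts must be non-negative")
  }
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(BASES, x), 1L), character(1))
}

#' Simulate an eight-species alignment with planted indel events
#'
#' Generates an ancestral sequence per block, plants human-lineage
#' insertions and deletions (1-5 bp, deletions at twice the insertion
#' rate), optionally replays a fraction of events in one randomly chosen
#' outgroup (homoplasy), and sprinkles substitution noise over the
#' outgroups away from event columns. Event contexts are chosen so that
#' gap left-normalization leaves planted events at their recorded anchors,
#' making the truth table directly comparable to the caller's output.
#'
#' @param cfg A [sim_config()].
#' @param maf_path Optional path; when given, the alignment is written as
#'   MAF (byte-identical across runs with the same `cfg`).
#' @return List with `blocks` (list of [alignment_block()]), `truth`
#'   (tibble: chrom, pos, length, event, homoplasic), and `maf_path`.
#' @export
simulate_alignment <- function(cfg = sim_config(), maf_path = NULL) {
  set.seed(cfg$seed)
  species <- default_species()
  outs <- species[-1]

  blocks <- list()
  truth <- list()
  human_offset <- 0L    # 0-based human start of the next block
  anc_offset <- 0L

  for (b in seq_len(cfg$n_blocks)) {
    L <- cfg$block_length
    anc <- sample(BASES, L, replace = TRUE)

    # plant events: positions thinned to keep >= 12 bp between anchors
    n_del <- rbinom(1L, L, cfg$deletion_rate)
    n_ins <- rbinom(1L, L, cfg$insertion_rate)
    n_ev <- n_del + n_ins
    ev <- NULL
    if (n_ev > 0) {
      anchors <- sort(sample(seq(10L, L - 10L), min(n_ev, L %/% 20L)))
      if (length(anchors) > 1) {
        keep <- c(TRUE, diff(anchors) >= 12L)
        # a dropped anchor resets the spacing reference; do a proper scan
        last <- anchors[1]
        for (i in seq_along(anchors)[-1]) {
          keep[i] <- (anchors[i] - last) >= 12L
          if (keep[i]) last <- anchors[i]
        }
        anchors <- anchors[keep]
      }
      if (length(anchors) > 0) {
        types <- sample(c("deletion", "insertion"), length(anchors),
                        replace = TRUE,
                        prob = c(cfg$deletion_rate, cfg$insertion_rate))
        ev <- tibble(
          anchor = anchors,
          event = types,
          length = sample(5L, length(anchors), replace = TRUE),
          homoplasic = runif(length(anchors)) < cfg$homoplasy_rate,
          homo_out = sample(7L, length(anchors), replace = TRUE)
        )
        # fix local context so left-normalization cannot move the run
        for (i in seq_len(nrow(ev))) {
          a <- ev$anchor[i]; l <- ev$length[i]
          nxt <- if (ev$event[i] == "deletion") a + l + 1L else a + 1L
          if (nxt <= L && anc[nxt] == anc[a]) anc[nxt] <- other_base(anc[a])
        }
      }
    }
    if (is.null(ev)) ev <- tibble(anchor = integer(), event = character(),
                                  length = integer(), homoplasic = logical(),
                                  homo_out = integer())

    # outgroup sequences: ancestral + noise away from events
    noise_ok <- rep(TRUE, L)
    for (i in seq_len(nrow(ev))) {
      lo <- max(1L, ev$anchor[i] - 2L)
      hi <- min(L, ev$anchor[i] + ev$length[i] + 2L)
      noise_ok[lo:hi] <- FALSE
    }
    out_seqs <- lapply(seq_len(7L), function(o) {
      s <- anc
      subs <- which(runif(L) < cfg$substitution_rate & noise_ok)
      if (length(subs)) s[subs] <- other_base(s[subs])
      s
    })

    # splice rows column-wise
    hum_parts <- character(0)
    out_parts <- rep(list(character(0)), 7L)
    prev <- 1L
    del_before <- 0L; ins_before <- 0L
    ev <- ev %>% arrange(.data$anchor)
    for (i in seq_len(nrow(ev))) {
      a <- ev$anchor[i]; l <- ev$length[i]
      seg <- prev:a
      hum_parts <- c(hum_parts, anc[seg])
      for (o in 1:7) out_parts[[o]] <- c(out_parts[[o]], out_seqs[[o]][seg])
      human_anchor_pos <- human_offset + a - del_before + ins_before
      if (ev$event[i] == "deletion") {
        hum_parts <- c(hum_parts, rep("-", l))
        for (o in 1:7) {
          piece <- if (ev$homoplasic[i] && ev$homo_out[i] == o) {
            rep("-", l)
          } else {
            out_seqs[[o]][(a + 1L):(a + l)]
          }
          out_parts[[o]] <- c(out_parts[[o]], piece)
        }
        prev <- a + l + 1L
        del_before <- del_before + l
      } else {
        inserted <- sample(BASES, l, replace = TRUE)
        # keep the inserted run from extending a repeat over the anchor
        if (inserted[1] == anc[a]) inserted[1] <- other_base(anc[a])
        hum_parts <- c(hum_parts, inserted)
        for (o in 1:7) {
          piece <- if (ev$homoplasic[i] && ev$homo_out[i] == o) {
            inserted
          } else {
            rep("-", l)
          }
          out_parts[[o]] <- c(out_parts[[o]], piece)
        }
        prev <- a + 1L
        ins_before <- ins_before + l
      }
      truth[[length(truth) + 1L]] <- tibble(
        chrom = cfg$chrom, pos = human_anchor_pos,
        length = l, event = ev$event[i], homoplasic = ev$homoplasic[i]
      )
    }
    if (prev <= L) {
      seg <- prev:L
      hum_parts <- c(hum_parts, anc[seg])
      for (o in 1:7) out_parts[[o]] <- c(out_parts[[o]], out_seqs[[o]][seg])
    }

    seqs <- c(
      setNames(paste(hum_parts, collapse = ""), species[[1]]),
      setNames(vapply(out_parts, paste, character(1), collapse = ""),
               unname(outs))
    )
    block <- alignment_block(
      ref_chrom = cfg$chrom, ref_start = human_offset,
      seqs = seqs, species_order = unname(species)
    )
    attr(block, "maf_meta") <- list(
      starts = setNames(as.list(rep(anc_offset, 7L)), unname(outs)),
      src_size = cfg$n_blocks * cfg$block_length + 10000L
    )
    blocks[[b]] <- block
    human_offset <- human_offset + (L - del_before + ins_before)
    anc_offset <- anc_offset + L
  }

  truth <- if (length(truth)) bind_rows(truth) else {
    tibble(chrom = character(), pos = integer(), length = integer(),
           event = character(), homoplasic = logical())
  }
  if (!is.null(maf_path)) write_maf(blocks, maf_path)
  list(blocks = blocks, truth = truth, maf_path = maf_path)
}

#' Simulate a cohort panel with planted introgressed haplotypes
#'
#' Draws background polymorphic indel sites whose derived allele
#' frequencies follow a neutral-like (discretized 1/x) spectrum, adds a
#' fraction of sites fixed at derived frequency 1 everywhere, and plants
#' contiguous introgressed haplotypes: runs of derived variants carried by
#' the archaic genome and a small set of heterozygous EUR/EAS carriers,
#' with the derived allele absent from every African individual. Archaic
#' coverage is Bernoulli per background site; planted introgressed sites
#' are always covered (they are unobservable otherwise). Background sites
#' whose derived allele is archaic-shared are guaranteed at least one
#' African carrier, so the introgression rule has specificity 1 against
#' the truth table by construction.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, writes `cohort.vcf`,
#'   `archaic.vcf`, `pops.tsv`, `outgroups.tsv`, `truth.tsv`.
#' @return List with `panel` (a `genotype_panel`), `archaic` (tibble as
#'   from [load_archaic_track()]), `outgroups` (consensus allele per
#'   site), `pops`, `truth`, and `paths` (when written).
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  n_ind <- cfg$n_individuals
  pop_labels <- c(AFR = "YRI", EUR = "CEU", EAS = "CHB")
  pops <- bind_rows(purrr::imap(as.list(n_ind), function(n, sp) {
    tibble(
      individual = sprintf("%s%03d", pop_labels[[sp]], seq_len(n)),
      population = pop_labels[[sp]]
    )
  }))
  n_total <- nrow(pops)
  idx_pop <- split(seq_len(n_total), pops$population)
  afr_idx <- idx_pop[[pop_labels[["AFR"]]]]
  eur_idx <- idx_pop[[pop_labels[["EUR"]]]]
  eas_idx <- idx_pop[[pop_labels[["EAS"]]]]

  # --- positions ---------------------------------------------------------
  hap_gap <- 300000L
  hap_starts <- 500000L +
    (seq_len(cfg$n_introgressed) - 1L) * (cfg$introgression_length + hap_gap)
  intro_sites <- list()
  for (h in seq_len(cfg$n_introgressed)) {
    p <- hap_starts[h]
    ps <- integer(0)
    while (p < hap_starts[h] + cfg$introgression_length) {
      ps <- c(ps, p)
      p <- p + max(50L, as.integer(round(
        runif(1L, 0.5, 1.5) * cfg$introgression_spacing)))
    }
    intro_sites[[h]] <- tibble(pos = ps, haplotype = h)
  }
  intro_sites <- if (length(intro_sites)) bind_rows(intro_sites) else {
    tibble(pos = integer(), haplotype = integer())
  }

  region_end <- max(1000000L,
                    if (nrow(intro_sites)) max(intro_sites$pos) + 500000L else 0L)
  n_fixed <- as.integer(round(cfg$site_count * cfg$fixed_fraction))
  bg_pos <- sample.int(region_end, cfg$site_count + n_fixed + 200L)
  bg_pos <- setdiff(bg_pos, intro_sites$pos)
  bg_pos <- sort(bg_pos[seq_len(cfg$site_count + n_fixed)])
  poly_pos <- sort(sample(bg_pos, cfg$site_count))
  fixed_pos <- sort(setdiff(bg_pos, poly_pos))

  sites <- bind_rows(
    tibble(pos = intro_sites$pos, haplotype = intro_sites$haplotype,
           kind = "introgressed"),
    tibble(pos = poly_pos, haplotype = NA_integer_, kind = "background"),
    tibble(pos = fixed_pos, haplotype = NA_integer_, kind = "fixed")
  ) %>% arrange(.data$pos)
  n_sites <- nrow(sites)

  # --- alleles -----------------------------------------------------------
  anchor <- sample(BASES, n_sites, replace = TRUE)
  ev_len <- sample(5L, n_sites, replace = TRUE)
  tail_seq <- vapply(ev_len, function(l) {
    paste(sample(BASES, l, replace = TRUE), collapse = "")
  }, character(1))
  event <- sample(c("deletion", "insertion"), n_sites, replace = TRUE,
                  prob = c(2, 1))
  long_allele <- paste0(anchor, tail_seq)
  ancestral <- ifelse(event == "deletion", long_allele, anchor)
  derived <- ifelse(event == "deletion", anchor, long_allele)
  anc_is_ref <- runif(n_sites) < 0.5
  ref <- ifelse(anc_is_ref, ancestral, derived)
  alt <- ifelse(anc_is_ref, derived, ancestral)

  # --- genotypes (derived dosage) ---------------------------------------
  dos <- matrix(0L, nrow = n_sites, ncol = n_total,
                dimnames = list(NULL, pops$individual))
  grid <- seq_len(2L * n_total - 1L)
  wts <- 1 / grid

  hap_carriers <- list()
  for (h in seq_len(cfg$n_introgressed)) {
    n_eur <- max(1L, as.integer(round(2 * length(eur_idx) *
                                        cfg$target_freq[["EUR"]])))
    n_eas <- max(1L, as.integer(round(2 * length(eas_idx) *
                                        cfg$target_freq[["EAS"]])))
    hap_carriers[[h]] <- c(sample(eur_idx, n_eur), sample(eas_idx, n_eas))
  }

  archaic_derived <- integer(n_sites)
  covered <- logical(n_sites)
  for (i in seq_len(n_sites)) {
    kind <- sites$kind[i]
    if (kind == "fixed") {
      dos[i, ] <- 2L
      covered[i] <- runif(1L) < cfg$archaic_coverage
      archaic_derived[i] <- 2L
    } else if (kind == "introgressed") {
      dos[i, hap_carriers[[sites$haplotype[i]]]] <- 1L
      covered[i] <- TRUE
      archaic_derived[i] <- 2L
    } else {
      repeat {
        x <- sample(grid, 1L, prob = wts) / (2L * n_total)
        g <- rbinom(n_total, 2L, x)
        if (sum(g) > 0L && sum(g) < 2L * n_total) break
      }
      dos[i, ] <- g
      covered[i] <- runif(1L) < cfg$archaic_coverage
      shared <- runif(1L) < cfg$shared_fraction
      archaic_derived[i] <- if (shared) sample(2L, 1L) else 0L
      # guarantee: an archaic-shared background site always has an African
      # carrier, so no background site can satisfy the introgression rule
      if (shared && sum(dos[i, afr_idx]) == 0L) {
        dos[i, sample(afr_idx, 1L)] <- 1L
      }
    }
  }

  # --- truth -------------------------------------------------------------
  sharing <- ifelse(!covered, "uncovered",
                    ifelse(archaic_derived >= 1L, "archaic_shared",
                           "modern_specific"))
  truth <- tibble(
    chrom = cfg$chrom, pos = sites$pos, ref = ref, alt = alt,
    ancestral = ancestral, derived = derived, event = event,
    length = ev_len,
    fixation = ifelse(sites$kind == "fixed", "fixed", "polymorphic"),
    sharing = sharing,
    introgressed = sites$kind == "introgressed",
    haplotype = sites$haplotype
  )

  # --- assemble objects --------------------------------------------------
  alt_dos <- dos
  flip <- !anc_is_ref  # derived allele is REF: ALT dosage = 2 - derived
  alt_dos[flip, ] <- 2L - alt_dos[flip, ]
  variants <- tibble(chrom = cfg$chrom, pos = sites$pos, ref = ref,
                     alt = alt, length = ev_len)
  panel <- new_genotype_panel(variants, alt_dos, pops)

  arch_alt_dos <- ifelse(anc_is_ref, archaic_derived, 2L - archaic_derived)
  archaic <- tibble(chrom = cfg$chrom, pos = sites$pos, ref = ref,
                    alt = alt, dosage = as.integer(arch_alt_dos))[covered, ]
  outgroups <- tibble(chrom = cfg$chrom, pos = sites$pos,
                      allele = ancestral, disagree = FALSE)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      cohort = file.path(dir, "cohort.vcf"),
      archaic = file.path(dir, "archaic.vcf"),
      pops = file.path(dir, "pops.tsv"),
      outgroups = file.path(dir, "outgroups.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_minimal_vcf(variants, alt_dos, pops$individual, paths$cohort,
                      contig = cfg$chrom)
    write_minimal_vcf(variants[covered, ],
                      matrix(as.integer(arch_alt_dos[covered]), ncol = 1,
                             dimnames = list(NULL, "AltaiNea")),
                      "AltaiNea", paths$archaic, contig = cfg$chrom)
    utils::write.table(pops, paths$pops, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(outgroups, paths$outgroups, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  list(panel = panel, archaic = archaic, outgroups = outgroups,
       pops = pops, truth = truth, paths = paths)
}

# minimal VCF 4.2 writer: variants tibble + ALT dosage matrix
write_minimal_vcf <- function(variants, alt_dos, samples, path, contig) {
  gt <- matrix("./.", nrow = nrow(variants), ncol = length(samples))
  gt[alt_dos == 0L] <- "0/0"
  gt[alt_dos == 1L] <- "0/1"
  gt[alt_dos == 2L] <- "1/1"
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gt[i, ]),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contig),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate one McDonald-Kreitman contingency table
#'
#' Draws event types for fixed and polymorphic indels under a model where
#' deletions arise at `rho` times the insertion rate and fix `sel_diff`
#' times as readily: polymorphic deletion proportion `rho/(rho+1)`, fixed
#' deletion proportion `rho*sel_diff/(rho*sel_diff+1)`. With
#' `sel_diff = 1` (neutrality) both strata share the same expected rDI and
#' the exact Fisher test should reject at its nominal rate.
#'
#' @param rho Deletion/insertion mutation-rate ratio (> 0).
#' @param sel_diff Relative fixation probability of deletions vs
#'   insertions (> 0).
#' @param n_fixed,n_poly Number of fixed and polymorphic events drawn.
#' @param seed Optional seed.
#' @return An `mk_table` tibble with rows fixed/polymorphic.
#' @export
simulate_mk_counts <- function(rho = 2, sel_diff = 1,
                               n_fixed = 1000L, n_poly = 1000L,
                               seed = NULL) {
  if (rho <= 0 || sel_diff <= 0) abort("rho and sel_diff must be positive")
  if (!is.null(seed)) set.seed(seed)
  p_fix <- rho * sel_diff / (rho * sel_diff + 1)
  p_poly <- rho / (rho + 1)
  d_fix <- rbinom(1L, n_fixed, p_fix)
  d_poly <- rbinom(1L, n_poly, p_poly)
  out <- tibble(
    class = c("fixed", "polymorphic"),
    deletions = c(d_fix, d_poly),
    insertions = c(n_fixed - d_fix, n_poly - d_poly)
  ) %>%
    mutate(rdi = ifelse(.data$insertions > 0,
                        .data$deletions / .data$insertions, NA_real_))
  class(out) <- c("mk_table", class(out))
  out
}
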