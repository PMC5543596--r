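test_that("perfect LD is exact genotype identity up to orientation", {
  a <- c(0L, 1L, 2L, 0L, 1L)
  expect_true(perfect_ld(a, a))
  expect_true(perfect_ld(a, 2L - a))        # opposite VCF orientation
  b <- a; b[3] <- 1L
  expect_false(perfect_ld(a, b))
  expect_error(perfect_ld(a, a[-1]), "same individuals")
  expect_error(perfect_ld(a, c(a[-1], NA)), "missing")
})

test_that("perfect LD coincides with r-squared of 1", {
  set.seed(2)
  for (i in 1:20) {
    a <- sample(0:2, 30, replace = TRUE)
    if (length(unique(a)) == 1) next
    flip <- sample(c(TRUE, FALSE), 1)
    b <- if (flip) 2L - a else a
    expect_true(perfect_ld(a, b))
    expect_equal(abs(cor(a, b)), 1)
    j <- sample(30, 1); b2 <- b; b2[j] <- (b2[j] + 1L) %% 3L
    expect_equal(perfect_ld(a, b2), isTRUE(all.equal(cor(a, b2)^2, 1)))
  }
})

test_that("the shared extent spans the outermost variants of all carriers", {
  pos <- c(100L, 50000L, 181000L)
  dos <- matrix(1L, nrow = 3, ncol = 3,
                dimnames = list(NULL, c("i1", "i2", "i3")))
  ext <- shared_extent(dos, pos, focal_pos = 50000L)
  expect_equal(ext$length, 180901L)
  expect_equal(ext$n_carriers, 3L)
})

test_that("a single carrier's extent equals its own run", {
  pos <- c(10L, 20L, 30L, 40L, 50L)
  dos <- matrix(c(0L, 1L, 1L, 1L, 0L), ncol = 1,
                dimnames = list(NULL, "i1"))
  ext <- shared_extent(dos, pos, focal_pos = 30L)
  expect_equal(c(ext$shared_start, ext$shared_end), c(20L, 40L))
})

test_that("adding a carrier never lengthens the shared extent", {
  set.seed(14)
  for (rep in 1:25) {
    n_var <- 40; n_ind <- 8
    pos <- sort(sample.int(100000L, n_var))
    focal_i <- sample(n_var, 1)
    dos <- matrix(rbinom(n_var * n_ind, 1, 0.7), n_var, n_ind)
    dos[focal_i, ] <- 1L
    colnames(dos) <- sprintf("i%d", seq_len(n_ind))
    prev <- NULL
    for (k in 2:n_ind) {
      ext <- shared_extent(dos[, 1:k, drop = FALSE], pos, pos[focal_i])
      if (!is.null(prev)) expect_lte(ext$length, prev)
      prev <- ext$length
    }
  }
})

test_that("planted haplotype extents are recovered to within the spacing", {
  set.seed(31)
  spacing <- 2000; hap_len <- 200000
  errs <- vapply(1:50, function(rep) {
    gaps <- pmax(50, round(runif(200, 0.5, 1.5) * spacing))
    pos <- 1000 + cumsum(c(0, gaps))
    pos <- pos[pos <= 1000 + hap_len]
    n_ind <- 12
    dos <- matrix(0L, length(pos), n_ind,
                  dimnames = list(NULL, sprintf("i%d", 1:n_ind)))
    carriers <- sample(n_ind, 4)
    dos[, carriers] <- 1L
    ext <- shared_extent(dos, pos, focal_pos = pos[ceiling(length(pos) / 2)])
    abs(hap_len - ext$length)
  }, numeric(1))
  expect_lt(mean(errs), spacing)
})

test_that("errors are raised without carriers or without the focal site", {
  dos <- matrix(0L, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(shared_extent(dos, c(10L, 20L), 10L), "no carrier")
  expect_error(shared_extent(dos, c(10L, 20L), 15L), "not among")
})

test_that("the GWAS report keeps only perfectly linked significant SNPs", {
  pops <- tibble::tibble(
    individual = sprintf("i%d", 1:6),
    population = c("YRI", "YRI", "CEU", "CEU", "CHB", "CHB")
  )
  variants <- tibble::tibble(
    chrom = "chr1", pos = c(1000L, 2000L, 3000L, 4000L),
    ref = c("AT", "C", "G", "T"), alt = c("A", "T", "A", "G"),
    length = c(1L, 0L, 0L, 0L)
  )
  # indel at 1000 (derived = ALT), SNP at 2000 in perfect LD, SNP at 3000
  # in perfect LD but weak association, SNP at 4000 unlinked
  dos <- matrix(c(0L, 0L, 1L, 0L, 1L, 0L,
                  0L, 0L, 1L, 0L, 1L, 0L,
                  0L, 0L, 1L, 0L, 1L, 0L,
                  0L, 1L, 1L, 0L, 0L, 0L),
                nrow = 4, byrow = TRUE,
                dimnames = list(NULL, pops$individual))
  panel <- indelstrata:::new_genotype_panel(variants, dos, pops)
  indels <- tibble::tibble(
    chrom = "chr1", pos = 1000L, ancestral = "AT", derived = "A",
    introgressed = TRUE, daf_YRI = 0, daf_CEU = 0.25, daf_CHB = 0.25
  )
  gwas <- tibble::tibble(
    chrom = "chr1", pos = c(2000L, 3000L, 4000L),
    rsid = c("rs1", "rs2", "rs3"),
    p = c(1e-9, 1e-4, 1e-9),
    trait = c("menarche", "height", "asthma")
  )
  rep <- gwas_link_report(indels, gwas, panel)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$rsid, "rs1")
  expect_equal(rep$eur_af, 0.25)
  expect_equal(rep$eas_af, 0.25)

  none <- gwas_link_report(dplyr::mutate(indels, introgressed = FALSE),
                           gwas, panel)
  expect_equal(nrow(none), 0)
})
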