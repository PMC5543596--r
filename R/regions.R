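#' Read a BED4 region-class annotation
#'
#' The fourth BED column carries the region class (e.g., `coding`,
#' `intron`, `intergenic`, `utr`) of each interval, standing in for a
#' most-severe-consequence annotation. Coordinates are converted from BED's
#' 0-based half-open convention to 1-based inclusive.
#'
#' @param path Path to a BED4 file.
#' @return Tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `region`.
#' @export
read_region_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_region_bed() needs the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    region = gr$name
  )
}

#' Assign each indel to one region class
#'
#' Overlaps indel anchor positions with the region annotation and attaches
#' the class of the first covering interval (the annotation is expected to
#' be non-overlapping, one class per base). Indels outside every annotated
#' interval get class `NA`.
#'
#' @param indels Indel tibble with `chrom` and `pos`.
#' @param regions Region tibble from [read_region_bed()] (or equivalent).
#' @return `indels` with a `region` column added.
#' @export
assign_region_class <- function(indels, regions) {
  q <- GenomicRanges::GRanges(indels$chrom,
                              IRanges::IRanges(indels$pos, indels$pos))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start, regions$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  indels$region <- regions$region[hit]
  indels
}

#' Add a combined lineage class column
#'
#' Collapses `sharing` and `introgressed` into one mutually exclusive
#' label: `introgressed`, `archaic_shared` (non-introgressed), or
#' `modern_specific`; uncovered sites get `NA`.
#'
#' @param indels Indel tibble with `sharing` and (optionally)
#'   `introgressed` columns.
#' @return `indels` with a `lineage_class` column.
#' @export
lineage_class <- function(indels) {
  intro <- if ("introgressed" %in% names(indels)) {
    indels$introgressed
  } else {
    rep(FALSE, nrow(indels))
  }
  indels$lineage_class <- dplyr::case_when(
    indels$sharing == "uncovered" ~ NA_character_,
    intro ~ "introgressed",
    indels$sharing == "archaic_shared" ~ "archaic_shared",
    TRUE ~ "modern_specific"
  )
  indels
}

#' Region-class enrichment contrasts with FDR control
#'
#' For every region class and every requested pair of indel classes, builds
#' the 2x2 table of counts (inside region, outside region) x (class A,
#' class B), computes the exact Fisher p and the sample odds ratio with a
#' normal-approximation 95% CI on its log, and Benjamini-Hochberg-adjusts
#' the combined p-value list over all region x contrast tests. An odds
#' ratio above 1 means class A is enriched inside the region relative to
#' class B.
#'
#' @param indels Indel tibble carrying a `region` column (see
#'   [assign_region_class()]) plus the contrast columns.
#' @param contrasts List of character triples `c(column, class_a, class_b)`.
#'   Defaults to insertion-vs-deletion, and the lineage-class pairs when a
#'   `lineage_class` column is present.
#' @param conf_level Confidence level for the odds-ratio CI.
#' @return Tibble of class `region_contrast`: one row per region x
#'   contrast with counts, `odds_ratio`, `conf.low`, `conf.high`,
#'   `p_value`, `p_adjusted`, and a `degenerate` flag for tables with an
#'   empty cell.
#' @export
region_class_contrast <- function(indels, contrasts = NULL,
                                  conf_level = 0.95) {
  if (!"region" %in% names(indels)) {
    abort("`indels` needs a `region` column; see assign_region_class()")
  }
  if (is.null(contrasts)) {
    contrasts <- list(c("event", "insertion", "deletion"))
    if ("lineage_class" %in% names(indels)) {
      contrasts <- c(contrasts, list(
        c("lineage_class", "modern_specific", "archaic_shared"),
        c("lineage_class", "introgressed", "archaic_shared"),
        c("lineage_class", "introgressed", "modern_specific")
      ))
    }
  }
  dat <- filter(indels, !is.na(.data$region))
  regions <- sort(unique(dat$region))

  rows <- purrr::map(contrasts, function(ct) {
    col <- ct[1]; ca <- ct[2]; cb <- ct[3]
    if (!col %in% names(dat)) return(NULL)
    is_a <- !is.na(dat[[col]]) & dat[[col]] == ca
    is_b <- !is.na(dat[[col]]) & dat[[col]] == cb
    if (!any(is_a) || !any(is_b)) return(NULL)
    purrr::map(regions, function(r) {
      in_r <- dat$region == r
      a <- sum(is_a & in_r); b <- sum(is_b & in_r)
      cc <- sum(is_a & !in_r); d <- sum(is_b & !in_r)
      ft <- suppressWarnings(fisher_exact_2x2(a, b, cc, d,
                                              conf_level = conf_level))
      tibble(
        region = r, contrast = paste(ca, "vs", cb),
        class_a = ca, class_b = cb,
        a_in = a, b_in = b, a_out = cc, b_out = d,
        odds_ratio = ft$odds_ratio,
        conf.low = ft$conf.low, conf.high = ft$conf.high,
        p_value = ft$p_value, log10_p = ft$log10_p,
        degenerate = any(c(a, b, cc, d) == 0)
      )
    }) %>% bind_rows()
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    abort("no testable region/contrast combination found")
  }
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  class(out) <- c("region_contrast", class(out))
  out
}

#' @rdname region_class_contrast
#' @param object A `region_contrast` tibble.
#' @param ... Unused.
#' @method autoplot region_contrast
#' @export
autoplot.region_contrast <- function(object, ...) {
  dat <- filter(as_tibble(object), !.data$degenerate)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$odds_ratio, y = .data$region,
                 xmin = .data$conf.low, xmax = .data$conf.high,
                 colour = .data$p_adjusted < 0.05)
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange() +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (class A in region)", y = NULL,
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
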