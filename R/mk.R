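#' Deletion/insertion ratio (rDI)
#'
#' @param deletions,insertions Non-negative counts; `insertions` must be
#'   positive, otherwise the ratio is undefined and an error is raised.
#' @return `deletions / insertions` as a double (vectorized).
#' @export
#' @examples
#' rdi(145303, 100217)  # 1.449...
rdi <- function(deletions, insertions) {
  if (any(insertions == 0)) {
    abort("rDI is undefined when the insertion count is 0")
  }
  if (any(deletions < 0) || any(insertions < 0)) {
    abort("counts must be non-negative")
  }
  deletions / insertions
}

#' Tabulate a deletion/insertion contingency table
#'
#' Builds the 2x2 count table behind the modified McDonald-Kreitman
#' contrast: rows are the two strata of `split_by` (fixed/polymorphic, or
#' archaic-shared/modern-human-specific), columns are deletions and
#' insertions, and each row carries its deletion/insertion ratio (rDI).
#' When `split_by = "sharing"`, indels labeled `uncovered` carry no sharing
#' information and are excluded. With `by_length = TRUE` the table is
#' stratified by event length (1-5 bp) and a pooled row set is appended.
#'
#' Pre-tabulated count data (one row per stratum with a count column, e.g.
#' published genome-wide totals) is supported through `count`.
#'
#' @param indels Tibble with columns `event`, the `split_by` column, and
#'   (for `by_length`) `length`.
#' @param split_by `"fixation"` or `"sharing"` (any 2-level column works).
#' @param by_length Stratify by indel length and append the pooled table?
#' @param count Optional name of a column of pre-tabulated counts.
#' @return Tibble of class `mk_table` with columns `length` (if requested),
#'   `class`, `deletions`, `insertions`, `rdi`. Row order puts the older /
#'   fixed stratum first.
#' @export
mk_table <- function(indels, split_by = c("fixation", "sharing"),
                     by_length = FALSE, count = NULL) {
  split_by <- if (is.character(split_by) && length(split_by) > 1) {
    match.arg(split_by)
  } else {
    split_by
  }
  if (!split_by %in% names(indels)) {
    abort(sprintf("column `%s` not found in `indels`", split_by))
  }
  dat <- indels
  if (split_by == "sharing") {
    dat <- filter(dat, .data$sharing != "uncovered")
  }
  w <- if (is.null(count)) rep(1L, nrow(dat)) else dat[[count]]

  tab_one <- function(d, wt) {
    classes <- class_order(d[[split_by]])
    out <- purrr::map(classes, function(cl) {
      sel <- d[[split_by]] == cl
      dels <- sum(wt[sel & d$event == "deletion"])
      inss <- sum(wt[sel & d$event == "insertion"])
      tibble(class = cl, deletions = dels, insertions = inss,
             rdi = if (inss > 0) dels / inss else NA_real_)
    })
    bind_rows(out)
  }

  if (!by_length) {
    out <- tab_one(dat, w)
  } else {
    lens <- sort(unique(dat$length))
    out <- bind_rows(
      purrr::map(lens, function(l) {
        sel <- dat$length == l
        tab_one(dat[sel, ], w[sel]) %>%
          mutate(length = as.character(l), .before = 1)
      })
    )
    out <- bind_rows(out, tab_one(dat, w) %>%
                       mutate(length = "pooled", .before = 1))
  }
  class(out) <- c("mk_table", class(out))
  out
}

# canonical stratum order: the older / reference class first
class_order <- function(x) {
  lv <- unique(stats::na.omit(x))
  pref <- c("fixed", "polymorphic", "archaic_shared", "modern_specific")
  c(intersect(pref, lv), setdiff(lv, pref))
}

#' Exact Fisher test for a 2x2 table, underflow-safe
#'
#' Two-sided exact test computed in log space by summing hypergeometric
#' point probabilities no larger than the observed one, so that p-values
#' far below double precision (the genome-wide contrasts reach p << 1e-300)
#' are still reported via `log10_p`. Two odds ratios are returned: the
#' sample (cross-product) odds ratio `(a*d)/(b*c)` and the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric model.
#'
#' @param a,b,c,d Counts laid out as rows = strata, columns =
#'   deletions/insertions: `a`,`b` are the first row, `c`,`d` the second.
#'   Alternatively pass an `mk_table` with exactly two rows as `a`.
#' @param conf_level Confidence level for the normal-approximation CI on
#'   the log sample odds ratio.
#' @return One-row tibble: `p_value`, `log10_p`, `odds_ratio` (sample),
#'   `or_conditional_mle`, `conf.low`, `conf.high`.
#' @export
#' @examples
#' fisher_exact_2x2(205075, 155818, 604423, 266969)
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             conf_level = 0.95) {
  if (is.data.frame(a)) {
    t <- a
    if (nrow(t) != 2) abort("`mk_table` input must have exactly two rows")
    b <- t$insertions[1]; c <- t$deletions[2]; d <- t$insertions[2]
    a <- t$deletions[1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be non-negative integers")
  }

  m <- a + c   # column 1 margin
  n2 <- b + d  # column 2 margin
  k <- a + b   # row 1 margin
  if (m == 0 || n2 == 0 || k == 0 || c + d == 0) {
    warn("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(tibble(p_value = 1, log10_p = 0,
                  odds_ratio = NA_real_, or_conditional_mle = NA_real_,
                  conf.low = NA_real_, conf.high = NA_real_))
  }

  xs <- seq.int(max(0, k - n2), min(k, m))
  lp <- dhyper(xs, m, n2, k, log = TRUE)
  lp_obs <- dhyper(a, m, n2, k, log = TRUE)
  # fisher.test's relative-error rule for "as or more extreme"
  sel <- lp <= lp_obs + log1p(1e-7)
  log_p <- log_sum_exp(lp[sel])
  log_p <- min(log_p, 0)

  or_sample <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.finite(se) && b > 0 && c > 0 && a > 0 && d > 0) {
    exp(log(or_sample) + c(-1, 1) * z * se)
  } else {
    c(NA_real_, NA_real_)
  }

  tibble(
    p_value = exp(log_p),
    log10_p = log_p / log(10),
    odds_ratio = or_sample,
    or_conditional_mle = cond_mle_or(a, xs, lp),
    conf.low = ci[1], conf.high = ci[2]
  )
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# conditional MLE of the odds ratio: solve E[X | psi] = a over the
# noncentral hypergeometric distribution on the table's support
cond_mle_or <- function(a, xs, lp) {
  if (a == min(xs)) return(0)
  if (a == max(xs)) return(Inf)
  cond_mean <- function(theta) {
    w <- lp + xs * theta
    w <- exp(w - max(w))
    sum(xs * w) / sum(w) - a
  }
  root <- uniroot(cond_mean, interval = c(-10, 10), extendInt = "yes",
                  tol = 1e-10)
  exp(root$root)
}

#' Modified McDonald-Kreitman test on an indel table
#'
#' Contrasts the deletion/insertion ratio between two strata of indels
#' (fixed vs polymorphic, or archaic-shared vs modern-human-specific).
#' Under neutrality both strata inherit the same deletion:insertion
#' mutation-rate ratio, so an unequal ratio indicates that selection moved
#' one event type toward (or away from) fixation. Runs the exact Fisher
#' test per table; with `by_length = TRUE` the test is repeated per event
#' length and pooled.
#'
#' @inheritParams mk_table
#' @return Object of class `indel_mk` with [tidy()] and [glance()] methods;
#'   `tidy()` reports one row per stratum pair with counts, rDIs, odds
#'   ratios, and (log) p-values.
#' @export
mk_test <- function(indels, split_by = c("fixation", "sharing"),
                    by_length = FALSE, count = NULL) {
  tab <- mk_table(indels, split_by = split_by, by_length = by_length,
                  count = count)
  strata <- if (by_length) split(tab, tab$length) else list(pooled = tab)
  tests <- purrr::imap(strata, function(t, nm) {
    ft <- fisher_exact_2x2(t$deletions[1], t$insertions[1],
                           t$deletions[2], t$insertions[2])
    tibble(
      length = nm,
      class_1 = t$class[1], class_2 = t$class[2],
      deletions_1 = t$deletions[1], insertions_1 = t$insertions[1],
      deletions_2 = t$deletions[2], insertions_2 = t$insertions[2],
      rdi_1 = t$rdi[1], rdi_2 = t$rdi[2]
    ) %>% bind_cols(ft)
  }) %>% bind_rows()
  structure(
    list(table = tab, tests = tests,
         split_by = if (length(split_by) > 1) split_by[1] else split_by),
    class = "indel_mk"
  )
}

#' @export
print.indel_mk <- function(x, ...) {
  cat(sprintf("Modified McDonald-Kreitman contrast (split by %s)\n",
              x$split_by))
  print(x$tests %>%
          select("length", "class_1", "class_2", "rdi_1", "rdi_2",
                 "odds_ratio", "log10_p"))
  invisible(x)
}

#' @rdname mk_test
#' @param x An `indel_mk` object.
#' @param ... Unused.
#' @method tidy indel_mk
#' @export
tidy.indel_mk <- function(x, ...) {
  x$tests
}

#' @rdname mk_test
#' @method glance indel_mk
#' @export
glance.indel_mk <- function(x, ...) {
  pooled <- filter(x$tests, .data$length == "pooled")
  pooled %>%
    select("rdi_1", "rdi_2", "odds_ratio", "or_conditional_mle",
           "p_value", "log10_p") %>%
    mutate(n_indels = sum(x$tests$deletions_1[1], x$tests$insertions_1[1],
                          x$tests$deletions_2[1], x$tests$insertions_2[1]))
}
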