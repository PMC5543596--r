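#' Incomplete-lineage-sorting model for shared-segment length
#'
#' Under incomplete lineage sorting, an ancestral haplotype block shared
#' between the human and archaic lineages is whittled down by
#' recombination over the branch separating them. A segment observed today
#' extends independently left and right from a focal point, each side
#' exponentially distributed with mean `L = 1/(r t)` bp, where `r` is the
#' local per-bp per-generation recombination rate and `t` the branch
#' length in generations. The total length is therefore Gamma-distributed
#' with shape 2 and mean `2L`, and the probability of retaining at least
#' `m` bp is the closed-form survival function
#' `P = (1 + m/L) exp(-m/L)`.
#'
#' Long shared segments are thus unlikely under ILS, whereas recent
#' admixture has had too few generations of recombination to break them
#' up: a small `P` favors introgression over ILS.
#'
#' @param m Observed segment length in bp (>= 0).
#' @param rate_cm_mb Local recombination rate in cM/Mb (converted
#'   internally via `1 cM/Mb = 1e-8` per bp per generation).
#' @param t_generations Branch length in generations separating the two
#'   lineages since their population split; the default of 19,000
#'   generations corresponds to roughly 550 ky at 29 years per generation.
#' @param rate_per_bp Recombination rate per bp per generation; overrides
#'   `rate_cm_mb` when supplied.
#' @return Survival probability in `(0, 1]`.
#' @export
#' @examples
#' ils_probability(180900, rate_cm_mb = 0.23, t_generations = 19000)
ils_probability <- function(m, rate_cm_mb = 0.23, t_generations = 19000,
                            rate_per_bp = NULL) {
  r <- if (is.null(rate_per_bp)) rate_cm_mb * 1e-8 else rate_per_bp
  if (any(r <= 0) || any(t_generations <= 0)) {
    abort("recombination rate and branch length must be positive")
  }
  if (any(m < 0)) abort("segment length must be non-negative")
  L <- 1 / (r * t_generations)
  # survival of Gamma(shape = 2, scale = L) at m
  (1 + m / L) * exp(-m / L)
}

#' Expected ILS tract length
#'
#' One-sided expected extension `L = 1/(r t)` in bp of an
#' incomplete-lineage-sorting segment; see [ils_probability()].
#'
#' @inheritParams ils_probability
#' @return Expected one-sided tract length in bp.
#' @export
ils_expected_length <- function(rate_cm_mb = 0.23, t_generations = 19000,
                                rate_per_bp = NULL) {
  r <- if (is.null(rate_per_bp)) rate_cm_mb * 1e-8 else rate_per_bp
  if (any(r <= 0) || any(t_generations <= 0)) {
    abort("recombination rate and branch length must be positive")
  }
  1 / (r * t_generations)
}
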