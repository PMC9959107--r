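#' Tumor mutational burden
#'
#' Number of somatic mutations per megabase of the targeted exome; the
#' default target size is the 45.0-Mb exonic capture probe.
#'
#' @param n_somatic Somatic mutation count (>= 0).
#' @param target_size_mb Targeted exome size in Mb (> 0).
#' @return Mutations per Mb.
#' @examples
#' compute_tmb(837) # 18.6 /Mb on the 45-Mb probe
#' @export
compute_tmb <- function(n_somatic, target_size_mb = 45.0) {
  if (!is.numeric(target_size_mb) || length(target_size_mb) != 1L ||
      is.na(target_size_mb) || target_size_mb <= 0)
    stop("target_size_mb must be positive", call. = FALSE)
  if (!is.numeric(n_somatic) || any(is.na(n_somatic)) || any(n_somatic < 0))
    stop("n_somatic must be a non-negative count", call. = FALSE)
  n_somatic / target_size_mb
}

#' Mutant-allele tumor heterogeneity (MATH)
#'
#' MATH = 100 * MAD / median of the mutant-allele fractions, where MAD is the
#' plain median of absolute deviations from the median VAF. Note the MAD here
#' is *unscaled*: some of the MATH literature multiplies by the 1.4826
#' normal-consistency factor, which is exposed through `scale_factor` but
#' defaults to 1. Even-length medians use the midpoint convention.
#'
#' Undefined for an empty VAF list or zero median; those return `NA` with a
#' message giving the reason, so cohort tables stay rectangular.
#'
#' @param vafs Mutant-allele fractions in percent.
#' @param scale_factor Multiplier applied to the MAD (1 = unscaled).
#' @return MATH (dimensionless), or `NA_real_` when undefined.
#' @examples
#' compute_math(c(10, 20, 30, 40, 50)) # 33.33
#' compute_math(c(30, 30, 30))         # 0
#' @export
compute_math <- function(vafs, scale_factor = 1) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) == 0L) {
    message("MATH undefined: no VAFs")
    return(NA_real_)
  }
  if (any(vafs < 0 | vafs > 100))
    stop("VAFs must lie in [0, 100] percent", call. = FALSE)
  med <- stats::median(vafs)
  if (med <= 0) {
    message("MATH undefined: median VAF is zero")
    return(NA_real_)
  }
  mad_raw <- stats::median(abs(vafs - med))
  100 * scale_factor * mad_raw / med
}

#' Shannon entropy of the VAF distribution
#'
#' The VAFs (percent) are binned into ten 10-percent-wide bins spanning
#' \[0, 100\] — half-open \[lo, hi) with the top bin closed at 100 — and the
#' entropy of the bin occupancy fractions P(f) is returned in bits, with
#' empty bins contributing zero (0 * log2(0) := 0). Ranges from 0 (one
#' occupied bin) to log2(10) ~ 3.32 (uniform occupancy).
#'
#' @param vafs Mutant-allele fractions in percent.
#' @return Entropy in bits, or `NA_real_` (with a message) for an empty list.
#' @examples
#' compute_shannon_entropy(c(21, 23, 29))  # 0: single bin
#' compute_shannon_entropy(c(5, 15))       # 1 bit: two equal bins
#' @export
compute_shannon_entropy <- function(vafs) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) == 0L) {
    message("Shannon entropy undefined: no VAFs")
    return(NA_real_)
  }
  if (any(vafs < 0 | vafs > 100))
    stop("VAFs must lie in [0, 100] percent", call. = FALSE)
  bin <- pmin(floor(vafs / 10), 9) + 1  # [90,100] closed at the top
  p <- tabulate(bin, nbins = 10L) / length(vafs)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Genomic feature sets at each PAF cutoff
#'
#' For every cutoff, performs the somatic call by PAF subtraction and computes
#' TMB, MATH and Shannon entropy of the surviving VAFs. The input is expected
#' to be quality-filtered already ([apply_quality_filters()]).
#'
#' @param variants Quality-filtered variant table.
#' @param cutoffs PAF cutoffs in percent (default the study's 1% and 0.01%).
#' @param target_size_mb Targeted exome size in Mb for TMB.
#' @return A data.frame with one row per cutoff: `paf_cutoff`, `n_somatic`,
#'   `tmb`, `math`, `shannon_entropy`.
#' @examples
#' tab <- generate_variant_table(cohort_spec(n_patients = 2, seed = 1), 1)
#' genomic_feature_sets(apply_quality_filters(tab)$variants)
#' @export
genomic_feature_sets <- function(variants, cutoffs = c(1, 0.01),
                                 target_size_mb = 45.0) {
  rows <- lapply(cutoffs, function(cut) {
    som <- call_somatic(variants, cut)$variants
    vafs <- som$vaf_percent
    data.frame(
      paf_cutoff = cut,
      n_somatic = nrow(som),
      tmb = compute_tmb(nrow(som), target_size_mb),
      math = if (nrow(som)) suppressMessages(compute_math(vafs)) else NA_real_,
      shannon_entropy = if (nrow(som))
        suppressMessages(compute_shannon_entropy(vafs)) else NA_real_
    )
  })
  do.call(rbind, rows)
}
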