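#' Validate an annotated variant table
#'
#' Checks the column contract shared by the generator, the filters and the
#' feature layer: VAF in percent within \[0, 100\], non-negative depth, and
#' non-negative PAFs where present. Errors name the first offending record.
#'
#' @param variants A data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `vaf_percent`, `depth`, `consequence`, `paf_general`, `paf_eas`.
#' @return The validated table, invisibly unchanged.
#' @export
validate_variants <- function(variants) {
  needed <- c("chrom", "pos", "ref", "alt", "vaf_percent", "depth",
              "consequence", "paf_general", "paf_eas")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(variants$vaf_percent) | variants$vaf_percent < 0 |
                 variants$vaf_percent > 100)
  if (length(bad))
    stop(sprintf("record %d (%s:%d) has VAF %s outside [0, 100] percent",
                 bad[1], variants$chrom[bad[1]], variants$pos[bad[1]],
                 format(variants$vaf_percent[bad[1]])), call. = FALSE)
  bad <- which(is.na(variants$depth) | variants$depth < 0)
  if (length(bad))
    stop(sprintf("record %d (%s:%d) has negative or missing depth",
                 bad[1], variants$chrom[bad[1]], variants$pos[bad[1]]),
         call. = FALSE)
  for (col in c("paf_general", "paf_eas")) {
    bad <- which(!is.na(variants[[col]]) & variants[[col]] < 0)
    if (length(bad))
      stop(sprintf("record %d (%s:%d) has negative %s",
                   bad[1], variants$chrom[bad[1]], variants$pos[bad[1]], col),
           call. = FALSE)
  }
  invisible(variants)
}

filter_report <- function(n_input, n_fail_depth = 0L, n_fail_vaf = 0L,
                          n_fail_consequence = 0L, n_germline = 0L,
                          n_somatic = 0L) {
  out <- list(n_input = as.integer(n_input),
              n_fail_depth = as.integer(n_fail_depth),
              n_fail_vaf = as.integer(n_fail_vaf),
              n_fail_consequence = as.integer(n_fail_consequence),
              n_germline = as.integer(n_germline),
              n_somatic = as.integer(n_somatic))
  stopifnot(out$n_input == out$n_fail_depth + out$n_fail_vaf +
              out$n_fail_consequence + out$n_germline + out$n_somatic)
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Filter report: %d in -> %d retained (depth fail %d, VAF fail %d, consequence fail %d, germline %d)\n",
    x$n_input, x$n_somatic, x$n_fail_depth, x$n_fail_vaf,
    x$n_fail_consequence, x$n_germline))
  invisible(x)
}

#' Quality filtering of variant records
#'
#' Retains a record iff depth >= 20x, VAF >= 5 percent, and the consequence is
#' a protein-coding missense change; everything else is filtered out. Failure
#' counts are reported under the precedence depth, then VAF, then consequence,
#' so the counts partition the input.
#'
#' @param variants Annotated variant table (see [validate_variants()]).
#' @param min_depth Minimum read depth (x); records strictly below fail.
#' @param min_vaf Minimum VAF (percent); records strictly below fail.
#' @param keep_consequence Consequence class retained.
#' @return A list with elements `variants` (retained rows) and `report`
#'   (a `filter_report`; `n_somatic` holds the retained count here).
#' @examples
#' tab <- generate_variant_table(cohort_spec(n_patients = 2, seed = 1), 1)
#' qf <- apply_quality_filters(tab)
#' qf$report
#' @export
apply_quality_filters <- function(variants, min_depth = 20, min_vaf = 5,
                                  keep_consequence = "missense") {
  validate_variants(variants)
  fail_depth <- variants$depth < min_depth
  fail_vaf <- !fail_depth & variants$vaf_percent < min_vaf
  fail_cons <- !fail_depth & !fail_vaf & variants$consequence != keep_consequence
  keep <- !(fail_depth | fail_vaf | fail_cons)
  report <- filter_report(nrow(variants),
                          n_fail_depth = sum(fail_depth),
                          n_fail_vaf = sum(fail_vaf),
                          n_fail_consequence = sum(fail_cons),
                          n_somatic = sum(keep))
  list(variants = subset_variants(variants, keep), report = report)
}

#' Somatic mutation calling by population-allele-frequency subtraction
#'
#' Tumor-only calling: a variant is labelled germline (and removed) iff its
#' population allele frequency reaches `paf_cutoff` in either the general or
#' the East-Asian population; missing PAFs count as zero, so novel variants
#' are presumed somatic. The study design contrasts cutoffs of 1% and 0.01%.
#'
#' @param variants Quality-filtered variant table.
#' @param paf_cutoff PAF cutoff in percent; must be positive.
#' @return A list with elements `variants` (somatic rows) and `report`.
#' @examples
#' tab <- generate_variant_table(cohort_spec(n_patients = 2, seed = 1), 1)
#' qf <- apply_quality_filters(tab)
#' som <- call_somatic(qf$variants, paf_cutoff = 1)
#' som$report
#' @export
call_somatic <- function(variants, paf_cutoff) {
  if (!is.numeric(paf_cutoff) || length(paf_cutoff) != 1L ||
      is.na(paf_cutoff) || paf_cutoff <= 0)
    stop("paf_cutoff must be a positive PAF in percent", call. = FALSE)
  validate_variants(variants)
  paf_max <- pmax(ifelse(is.na(variants$paf_general), 0, variants$paf_general),
                  ifelse(is.na(variants$paf_eas), 0, variants$paf_eas))
  germline <- paf_max >= paf_cutoff
  report <- filter_report(nrow(variants),
                          n_germline = sum(germline),
                          n_somatic = sum(!germline))
  list(variants = subset_variants(variants, !germline), report = report)
}

subset_variants <- function(variants, keep) {
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  truth <- attr(variants, "truth")
  if (!is.null(truth)) {
    truth$is_somatic <- truth$is_somatic[keep]
    attr(out, "truth") <- truth
  }
  out
}
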