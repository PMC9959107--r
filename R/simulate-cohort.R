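#' Simulate a full radiogenomic cohort
#'
#' Generates every patient's variant table and PET phantom, applies the
#' quality filters, computes the genomic features at both PAF cutoffs and
#' the PET features at both matrix sizes, and draws linked clinical records.
#' A patient whose table leaves no somatic variant at the strictest cutoff
#' is regenerated with a perturbed sub-seed (the retry count is messaged),
#' so downstream feature tables are never degenerate.
#'
#' After assembly the cohort feature means are compared to the reference
#' moments the generator is calibrated against (cohort means of TMB, MATH,
#' Shannon entropy at the 1% cutoff, SUVmax and PET entropy); deviations
#' beyond two reference SDs raise a warning, not an error — the calibration
#' is intentionally loose.
#'
#' @param spec A [cohort_spec()].
#' @param pet Logical; generate PET phantoms and features (disable for
#'   genomics-only studies, which is much faster).
#' @param calibration_check Logical; run the soft calibration warning.
#' @return Object of class `radhet_cohort`: list with `spec`, `patients`
#'   (per-patient list of `variants`, `pet`, `truth`), `features` (one row
#'   per patient) and `clinical`.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_patients = 3, seed = 2), pet = FALSE)
#' coh$features[, c("patient_id", "tmb_c", "tmb_m")]
#' @export
simulate_cohort <- function(spec, pet = TRUE, calibration_check = TRUE) {
  spec <- validate_cohort_spec(spec)
  cutoffs <- c(1, 0.01)
  patients <- vector("list", spec$n_patients)
  rows <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    retry <- 0L
    repeat {
      tab <- generate_variant_table(spec, i, retry = retry)
      qf <- apply_quality_filters(tab)
      gfeat <- genomic_feature_sets(qf$variants, cutoffs)
      if (min(gfeat$n_somatic) >= 1L || retry >= 10L) break
      retry <- retry + 1L
    }
    if (retry > 0L)
      message(sprintf("patient %d regenerated %d time(s) to retain a somatic variant",
                      i, retry))
    row <- data.frame(
      patient_id = sprintf("P%03d", i),
      tmb_c = gfeat$tmb[1], tmb_m = gfeat$tmb[2],
      math_c = gfeat$math[1], math_m = gfeat$math[2],
      shannon_c = gfeat$shannon_entropy[1], shannon_m = gfeat$shannon_entropy[2],
      n_somatic_c = gfeat$n_somatic[1], n_somatic_m = gfeat$n_somatic[2],
      stringsAsFactors = FALSE
    )
    pat <- list(variants = tab, quality_report = qf$report,
                truth = attr(tab, "truth"))
    if (pet) {
      ph <- generate_pet_volume(spec, i)
      pfeat <- pet_feature_sets(ph$volume, ph$voi)
      row <- cbind(row, data.frame(
        suv_max_std = pfeat$suv_max[1], suv_max_red = pfeat$suv_max[2],
        suv_mean_std = pfeat$suv_mean[1], suv_mean_red = pfeat$suv_mean[2],
        mtv_std = pfeat$mtv[1], mtv_red = pfeat$mtv[2],
        tlg_std = pfeat$tlg[1], tlg_red = pfeat$tlg[2],
        entropy_std = pfeat$entropy[1], entropy_red = pfeat$entropy[2]
      ))
      pat$pet <- ph
    }
    patients[[i]] <- pat
    rows[[i]] <- row
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  clinical <- generate_clinical(features, spec)
  if (calibration_check) check_calibration(features, pet = pet)
  structure(list(spec = spec, patients = patients, features = features,
                 clinical = clinical),
            class = "radhet_cohort")
}

# Reference cohort moments the generator defaults are calibrated against
# (means +/- SD of the emulated study population).
CALIBRATION_REFERENCE <- list(
  tmb_c = c(mean = 18.6, sd = 8.91),
  math_c = c(mean = 47.1, sd = 14.54),
  shannon_c = c(mean = 2.8, sd = 0.17),
  suv_max_std = c(mean = 11.9, sd = 7.01),
  entropy_std = c(mean = 4.2, sd = 0.84)
)

check_calibration <- function(features, pet = TRUE) {
  for (nm in names(CALIBRATION_REFERENCE)) {
    if (!nm %in% names(features)) next
    if (!pet && nm %in% c("suv_max_std", "entropy_std")) next
    ref <- CALIBRATION_REFERENCE[[nm]]
    m <- mean(features[[nm]], na.rm = TRUE)
    if (abs(m - ref["mean"]) > 2 * ref["sd"])
      warning(sprintf(
        "cohort mean %s = %.2f is outside the calibration envelope %.2f +/- %.2f",
        nm, m, ref["mean"], 2 * ref["sd"]), call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.radhet_cohort <- function(x, ...) {
  cat(sprintf("Synthetic radiogenomic cohort: %d patients (seed %d)\n",
              x$spec$n_patients, x$spec$seed))
  cat(sprintf("  mean TMBc %.1f /Mb, mean Shannon.c %.2f bits",
              mean(x$features$tmb_c), mean(x$features$shannon_c, na.rm = TRUE)))
  if ("suv_max_std" %in% names(x$features))
    cat(sprintf(", mean SUVmax %.1f", mean(x$features$suv_max_std)))
  cat("\n")
  invisible(x)
}
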