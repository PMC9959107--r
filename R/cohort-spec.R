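#' Specification of a synthetic radiogenomic cohort
#'
#' Bundles every knob of the synthetic cohort generator: the clonal structure
#' of the variant tables, the germline contamination model, the textured PET
#' phantom, and the clinical/survival links. Defaults emulate the structure of
#' a 46-patient prospective NSCLC cohort sequenced tumor-only on a 45-Mb exome
#' probe at ~119x mean depth, with tumor purity spanning 20-100%, and imaged
#' on a digital PET system at a 2.7 x 2.7 x 2.79 mm standard grid.
#'
#' VAFs are expressed in percent (0-100) throughout the package, population
#' allele frequencies (PAFs) likewise in percent, SUV in body-weight units,
#' lengths in mm, volumes in mL, survival times in months.
#'
#' @param n_patients Number of patients (>= 2).
#' @param bimodal_fraction Proportion of patients whose somatic VAF
#'   distribution is bimodal (two clones instead of one).
#' @param purity_range Range of per-patient tumor-cell fraction; a clonal
#'   heterozygous mutation has expected VAF `100 * purity / 2` percent.
#' @param mean_depth Mean sequencing depth (x). Per-variant depths are
#'   negative-binomial (size 5) around this mean.
#' @param n_somatic_range Integer range of true somatic mutations per patient.
#' @param n_germline_range Integer range of contaminating germline variants
#'   per patient (tumor-only calling retains these until PAF subtraction).
#' @param missense_fraction Fraction of variants annotated missense; the rest
#'   are split over synonymous/nonsense/indel/noncoding.
#' @param subclone_ccf Cancer-cell fraction of the second clone in bimodal
#'   patients (the first clone is clonal, CCF 1).
#' @param ccf_dispersion Lognormal sd applied per-variant to the clone CCF,
#'   emulating residual subclonal structure and copy-number distortion of the
#'   VAF spread.
#' @param vaf_overdispersion Beta-binomial intra-class correlation of the
#'   read counts, emulating the extra VAF dispersion of FFPE tumor-only
#'   sequencing beyond binomial sampling (0 gives plain binomial noise).
#' @param germline_hom_fraction Fraction of germline contaminants that are
#'   homozygous (VAF ~100% rather than ~50%).
#' @param paf_range Range (percent) of the log-uniform population allele
#'   frequency distribution for germline contaminants; spans both sides of
#'   the 1% and 0.01% cutoffs so both bite.
#' @param somatic_paf_missing_fraction Fraction of true somatic variants whose
#'   PAF is recorded as missing (absent from the database) rather than zero.
#' @param tumor_radius_mm_range Range of the mean tumor radius (mm).
#' @param ellipticity Relative perturbation of the three ellipsoid semi-axes
#'   around the drawn radius (0 gives spheres).
#' @param tumor_suv_range Range of the per-patient base tumor SUV.
#' @param texture_amplitude Relative amplitude of the Gaussian-random-field
#'   uptake texture (0 gives uniform tumors).
#' @param texture_corr_length_mm Spatial correlation length (mm) of the
#'   uptake texture.
#' @param background_suv Uniform background SUV outside the tumor.
#' @param volume_dim Grid dimensions (x, y, z) of the standard-matrix volume;
#'   in-plane dimensions must be even so the reduced matrix is exact.
#' @param stage_betas Named numeric vector of log-odds coefficients linking
#'   standardized features to the stage-IV indicator. Default empty (no link).
#' @param stage4_fraction Baseline stage-IV probability when `stage_betas`
#'   contribute nothing.
#' @param smoker_fraction,adeno_fraction Marginals of smoking status and
#'   adenocarcinoma histology.
#' @param survival_betas Named numeric vector of log-hazard coefficients per
#'   unit of the named feature. Default empty: null survival, so reliability
#'   analyses run on cohorts with no outcome links.
#' @param baseline_hazard Baseline exponential event rate (per month).
#' @param censor_rate Target proportion censored; implemented as independent
#'   exponential censoring with the matching rate (0 disables censoring).
#' @param seed Master seed; every random draw in the cohort descends from it.
#'
#' @return An object of class `cohort_spec` (a validated named list).
#' @examples
#' spec <- cohort_spec(n_patients = 4, seed = 7)
#' spec$n_patients
#' @export
cohort_spec <- function(n_patients = 46L,
                        bimodal_fraction = 0.4,
                        purity_range = c(0.2, 1.0),
                        mean_depth = 119,
                        n_somatic_range = c(150L, 620L),
                        n_germline_range = c(1050L, 1350L),
                        missense_fraction = 0.7,
                        subclone_ccf = 0.35,
                        ccf_dispersion = 0.45,
                        vaf_overdispersion = 0.005,
                        germline_hom_fraction = 0.1,
                        paf_range = c(1e-4, 50),
                        somatic_paf_missing_fraction = 0.7,
                        tumor_radius_mm_range = c(8, 30),
                        ellipticity = 0.15,
                        tumor_suv_range = c(2.5, 12),
                        texture_amplitude = 0.35,
                        texture_corr_length_mm = 8,
                        background_suv = 0.5,
                        volume_dim = c(64L, 64L, 48L),
                        stage_betas = numeric(0),
                        stage4_fraction = 0.435,
                        smoker_fraction = 0.587,
                        adeno_fraction = 0.761,
                        survival_betas = numeric(0),
                        baseline_hazard = log(2) / 24,
                        censor_rate = 0.76,
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients),
    bimodal_fraction = bimodal_fraction,
    purity_range = as.numeric(purity_range),
    mean_depth = mean_depth,
    n_somatic_range = as.integer(n_somatic_range),
    n_germline_range = as.integer(n_germline_range),
    missense_fraction = missense_fraction,
    subclone_ccf = subclone_ccf,
    ccf_dispersion = ccf_dispersion,
    vaf_overdispersion = vaf_overdispersion,
    germline_hom_fraction = germline_hom_fraction,
    paf_range = as.numeric(paf_range),
    somatic_paf_missing_fraction = somatic_paf_missing_fraction,
    tumor_radius_mm_range = as.numeric(tumor_radius_mm_range),
    ellipticity = ellipticity,
    tumor_suv_range = as.numeric(tumor_suv_range),
    texture_amplitude = texture_amplitude,
    texture_corr_length_mm = texture_corr_length_mm,
    background_suv = background_suv,
    volume_dim = as.integer(volume_dim),
    stage_betas = stage_betas,
    stage4_fraction = stage4_fraction,
    smoker_fraction = smoker_fraction,
    adeno_fraction = adeno_fraction,
    survival_betas = survival_betas,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param x A `cohort_spec` to validate.
#' @export
validate_cohort_spec <- function(x) {
  stopifnot(inherits(x, "cohort_spec"))
  if (is.na(x$n_patients) || x$n_patients < 2L)
    stop("n_patients must be an integer >= 2", call. = FALSE)
  props <- c("bimodal_fraction", "missense_fraction", "germline_hom_fraction",
             "somatic_paf_missing_fraction", "stage4_fraction",
             "smoker_fraction", "adeno_fraction", "censor_rate")
  for (p in props) {
    v <- x[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("%s must be a proportion in [0, 1]", p), call. = FALSE)
  }
  if (x$censor_rate >= 1)
    stop("censor_rate must be < 1", call. = FALSE)
  rngs <- c("purity_range", "n_somatic_range", "n_germline_range",
            "paf_range", "tumor_radius_mm_range", "tumor_suv_range")
  for (r in rngs) {
    v <- x[[r]]
    if (length(v) != 2L || anyNA(v) || v[1] > v[2])
      stop(sprintf("%s must be a non-empty range c(lo, hi)", r), call. = FALSE)
  }
  if (x$purity_range[1] < 0.2 - 1e-12 || x$purity_range[2] > 1)
    stop("purity_range must lie within [0.2, 1]", call. = FALSE)
  if (x$n_somatic_range[1] < 1L || x$n_germline_range[1] < 0L)
    stop("mutation count ranges must be positive", call. = FALSE)
  if (x$paf_range[1] <= 0)
    stop("paf_range must be strictly positive (log-uniform support)", call. = FALSE)
  if (x$mean_depth <= 0 || x$baseline_hazard <= 0)
    stop("mean_depth and baseline_hazard must be positive", call. = FALSE)
  if (x$vaf_overdispersion < 0 || x$vaf_overdispersion >= 1)
    stop("vaf_overdispersion must be in [0, 1)", call. = FALSE)
  if (x$subclone_ccf <= 0 || x$subclone_ccf >= 1)
    stop("subclone_ccf must be in (0, 1)", call. = FALSE)
  if (length(x$volume_dim) != 3L || any(x$volume_dim < 8L))
    stop("volume_dim must be three dimensions >= 8", call. = FALSE)
  if (any(x$volume_dim[1:2] %% 2L != 0L))
    stop("in-plane volume_dim must be even", call. = FALSE)
  for (nm in names(x$survival_betas)) {
    if (!nzchar(nm)) stop("survival_betas must be a named vector", call. = FALSE)
  }
  x
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic radiogenomic cohort spec\n")
  cat(sprintf("  patients: %d (bimodal fraction %.2f, purity %.2f-%.2f)\n",
              x$n_patients, x$bimodal_fraction,
              x$purity_range[1], x$purity_range[2]))
  cat(sprintf("  variants/patient: somatic %d-%d, germline %d-%d, depth ~%gx\n",
              x$n_somatic_range[1], x$n_somatic_range[2],
              x$n_germline_range[1], x$n_germline_range[2], x$mean_depth))
  cat(sprintf("  tumor: radius %g-%g mm, SUV %g-%g, texture amp %.2f (corr %g mm)\n",
              x$tumor_radius_mm_range[1], x$tumor_radius_mm_range[2],
              x$tumor_suv_range[1], x$tumor_suv_range[2],
              x$texture_amplitude, x$texture_corr_length_mm))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic sub-seed for (patient, stream); keeps everything reproducible
# from the master seed while letting each generator be called independently.
derive_seed <- function(master, patient_index, stream) {
  ((as.double(master) * 92821 + as.double(patient_index) * 13721 +
      as.double(stream) * 607) %% 2147483629) + 1
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
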