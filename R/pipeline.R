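#' Configuration of a full pipeline run
#'
#' @param cohort A [cohort_spec()] for synthetic mode, or `NULL` when
#'   `input_dir` points at real inputs written in the package's formats
#'   (variant TSVs `P*_variants.tsv`, optional NIfTI volumes `P*_pet.nii.gz`
#'   with VOI sidecars, and `clinical.csv`).
#' @param input_dir Directory of real inputs (ignored in synthetic mode).
#' @param paf_cutoffs PAF cutoffs in percent, sorted descending.
#' @param threshold_fraction,bin_width PET segmentation/entropy parameters.
#' @param small_mtv_ml MTV threshold (mL, standard grid) for the small-tumor
#'   reliability subgroup.
#' @param icc_type ICC variant, `"consistency"` or `"agreement"`.
#' @param group_test Two-group test policy for the stage comparison.
#' @param output_dir Directory the report bundle is written to.
#' @param seed Master seed (overrides the cohort spec's seed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), input_dir = NULL,
                       paf_cutoffs = c(1, 0.01),
                       threshold_fraction = 0.41, bin_width = 0.25,
                       small_mtv_ml = 10, icc_type = "consistency",
                       group_test = "auto",
                       output_dir = tempfile("radhet_run_"), seed = NULL) {
  if (any(paf_cutoffs <= 0)) stop("paf_cutoffs must be positive", call. = FALSE)
  if (is.unsorted(rev(paf_cutoffs)))
    stop("paf_cutoffs must be sorted descending", call. = FALSE)
  if (!is.null(seed) && !is.null(cohort)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, input_dir = input_dir,
                 paf_cutoffs = paf_cutoffs,
                 threshold_fraction = threshold_fraction,
                 bin_width = bin_width, small_mtv_ml = small_mtv_ml,
                 icc_type = icc_type, group_test = group_test,
                 output_dir = output_dir,
                 seed = if (!is.null(cohort)) cohort$seed else as.integer(seed)),
            class = "run_config")
}

#' Run the radiogenomic heterogeneity pipeline end to end
#'
#' Generates (or loads) the cohort, computes genomic features at both PAF
#' cutoffs and PET features at both matrix sizes, then produces the analysis
#' bundle: an ICC reliability table (genomic features across cutoffs, PET
#' features across matrix sizes, plus the small-tumor PET subgroup), the
#' pairwise feature correlation matrix, stage I-III vs IV group comparisons,
#' univariate Cox regressions of overall survival on every feature, and a
#' human-readable summary. A manifest with the config hash and per-file
#' checksums makes reruns verifiable: an unchanged config reproduces
#' identical checksums.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly; all tables are written under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character(0)

  if (!is.null(config$cohort)) {
    cohort <- withCallingHandlers(
      simulate_cohort(config$cohort, pet = TRUE),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    features <- cohort$features
    clinical <- cohort$clinical
  } else {
    loaded <- load_real_inputs(config)
    features <- loaded$features
    clinical <- loaded$clinical
  }

  out <- function(name) file.path(config$output_dir, name)
  utils::write.csv(features, out("features.csv"), row.names = FALSE)
  write_clinical_table(clinical, out("clinical.csv"))

  icc_tab <- pipeline_icc_table(features, config)
  utils::write.csv(icc_tab, out("icc.csv"), row.names = FALSE)

  cor_cols <- intersect(
    c("tmb_c", "tmb_m", "math_c", "math_m", "shannon_c", "shannon_m",
      "suv_max_std", "mtv_std", "tlg_std", "entropy_std"), names(features))
  cor_in <- cbind(features[cor_cols], pdl1 = clinical$pdl1_percent)
  cm <- correlation_matrix(cor_in)
  cor_long <- data.frame(
    feature_a = rownames(cm$r)[row(cm$r)][upper.tri(cm$r)],
    feature_b = colnames(cm$r)[col(cm$r)][upper.tri(cm$r)],
    r = cm$r[upper.tri(cm$r)], p = cm$p[upper.tri(cm$p)],
    n = cm$n[upper.tri(cm$n)],
    sig_raw = cm$sig_raw[upper.tri(cm$r)],
    sig_bonferroni = cm$sig_bonferroni[upper.tri(cm$r)])
  utils::write.csv(cor_long, out("correlations.csv"), row.names = FALSE)

  cmp_tab <- pipeline_group_table(features, clinical, config)
  utils::write.csv(cmp_tab, out("stage_comparisons.csv"), row.names = FALSE)

  cox_tab <- pipeline_cox_table(features, clinical)
  utils::write.csv(cox_tab, out("cox.csv"), row.names = FALSE)

  writeLines(pipeline_summary_text(features, icc_tab, cmp_tab, cox_tab),
             out("summary.txt"))

  files <- c("features.csv", "clinical.csv", "icc.csv", "correlations.csv",
             "stage_comparisons.csv", "cox.csv", "summary.txt")
  checksums <- tools::md5sum(vapply(files, out, character(1)))
  names(checksums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("radhet")),
    config_hash = config_hash(config),
    seed = config$seed,
    checksums = as.list(checksums),
    warnings = warnings_seen,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  canon <- config[setdiff(names(config), "output_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(lapply(canon, function(x)
    if (inherits(x, "cohort_spec")) unclass(x) else x)), tmp)
  unname(tools::md5sum(tmp))
}

icc_row <- function(feature, pairs, condition, type, subgroup = "all") {
  est <- suppressMessages(icc_consistency(pairs, type))
  data.frame(feature = feature, condition = condition, subgroup = subgroup,
             icc = est$value, band = ifelse(is.na(est$value), NA, est$band),
             n_used = est$n_used, stringsAsFactors = FALSE)
}

pipeline_icc_table <- function(features, config) {
  rows <- list(
    icc_row("tmb", features[c("tmb_c", "tmb_m")], "paf_cutoff", config$icc_type),
    icc_row("math", features[c("math_c", "math_m")], "paf_cutoff", config$icc_type),
    icc_row("shannon_entropy", features[c("shannon_c", "shannon_m")],
            "paf_cutoff", config$icc_type),
    icc_row("n_somatic", features[c("n_somatic_c", "n_somatic_m")],
            "paf_cutoff", config$icc_type))
  if ("suv_max_std" %in% names(features)) {
    pet_pairs <- list(suv_max = c("suv_max_std", "suv_max_red"),
                      mtv = c("mtv_std", "mtv_red"),
                      tlg = c("tlg_std", "tlg_red"),
                      entropy = c("entropy_std", "entropy_red"))
    small <- features$mtv_std < config$small_mtv_ml
    for (nm in names(pet_pairs)) {
      rows <- c(rows, list(
        icc_row(nm, features[pet_pairs[[nm]]], "matrix_size", config$icc_type),
        icc_row(nm, features[small, pet_pairs[[nm]]], "matrix_size",
                config$icc_type,
                subgroup = sprintf("mtv_lt_%g_ml", config$small_mtv_ml))))
    }
  }
  do.call(rbind, rows)
}

pipeline_group_table <- function(features, clinical, config) {
  cols <- intersect(c("tmb_c", "math_c", "shannon_c", "suv_max_std",
                      "mtv_std", "tlg_std", "entropy_std"), names(features))
  groups <- clinical$stage_group
  rows <- lapply(cols, function(nm) {
    if (length(unique(groups)) < 2L)
      return(data.frame(feature = nm, test = NA, statistic = NA, p = NA,
                        mean_I_III = NA, mean_IV = NA))
    cmpr <- compare_groups(features[[nm]], groups, config$group_test)
    gs <- cmpr$group_summary
    data.frame(feature = nm, test = cmpr$test_used,
               statistic = cmpr$statistic, p = cmpr$p_value,
               mean_I_III = gs$mean[gs$group == "I-III"],
               mean_IV = gs$mean[gs$group == "IV"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

pipeline_cox_table <- function(features, clinical) {
  cols <- intersect(c("tmb_c", "tmb_m", "math_c", "math_m", "shannon_c",
                      "shannon_m", "suv_max_std", "suv_max_red", "mtv_std",
                      "mtv_red", "tlg_std", "tlg_red", "entropy_std",
                      "entropy_red"), names(features))
  rows <- lapply(cols, function(nm) {
    res <- tryCatch(
      cox_univariate(clinical$os_months, clinical$os_event, features[[nm]]),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variable = nm, hr = NA, ci_low = NA, ci_high = NA,
                        p = NA, n_events = NA, flagged = NA))
    data.frame(variable = nm, hr = res$hr, ci_low = res$ci_low,
               ci_high = res$ci_high, p = res$p, n_events = res$n_events,
               flagged = res$flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

pipeline_summary_text <- function(features, icc_tab, cmp_tab, cox_tab) {
  c(sprintf("radhet pipeline summary (%d patients)", nrow(features)),
    "",
    "Feature reliability (ICC):",
    sprintf("  %-16s %-12s %-14s ICC %6s  %s",
            icc_tab$feature, icc_tab$condition, icc_tab$subgroup,
            ifelse(is.na(icc_tab$icc), "NA", sprintf("%.3f", icc_tab$icc)),
            ifelse(is.na(icc_tab$band), "undefined", icc_tab$band)),
    "",
    "Stage I-III vs IV comparisons:",
    sprintf("  %-16s %-14s p = %s", cmp_tab$feature, cmp_tab$test,
            format.pval(cmp_tab$p, digits = 3)),
    "",
    "Univariate Cox (OS):",
    sprintf("  %-16s HR %.3f (%.3f-%.3f), p = %s", cox_tab$variable,
            cox_tab$hr, cox_tab$ci_low, cox_tab$ci_high,
            format.pval(cox_tab$p, digits = 3)))
}

load_real_inputs <- function(config) {
  dir <- config$input_dir
  if (is.null(dir) || !dir.exists(dir))
    stop("input_dir must exist in real-data mode", call. = FALSE)
  vfiles <- sort(list.files(dir, pattern = "_variants\\.tsv$", full.names = TRUE))
  if (!length(vfiles)) stop("no *_variants.tsv found in input_dir", call. = FALSE)
  rows <- lapply(vfiles, function(f) {
    pid <- sub("_variants\\.tsv$", "", basename(f))
    tab <- read_variant_table(f)
    qf <- apply_quality_filters(tab)
    g <- genomic_feature_sets(qf$variants, config$paf_cutoffs)
    row <- data.frame(patient_id = pid,
                      tmb_c = g$tmb[1], tmb_m = g$tmb[2],
                      math_c = g$math[1], math_m = g$math[2],
                      shannon_c = g$shannon_entropy[1],
                      shannon_m = g$shannon_entropy[2],
                      n_somatic_c = g$n_somatic[1], n_somatic_m = g$n_somatic[2],
                      stringsAsFactors = FALSE)
    pfile <- file.path(dir, paste0(pid, "_pet.nii.gz"))
    if (file.exists(pfile)) {
      pv <- read_suv_volume(pfile)
      if (is.null(pv$voi)) stop("PET volume without VOI sidecar: ", pfile)
      p <- pet_feature_sets(pv$volume, pv$voi, config$threshold_fraction,
                            config$bin_width)
      row <- cbind(row, data.frame(
        suv_max_std = p$suv_max[1], suv_max_red = p$suv_max[2],
        suv_mean_std = p$suv_mean[1], suv_mean_red = p$suv_mean[2],
        mtv_std = p$mtv[1], mtv_red = p$mtv[2],
        tlg_std = p$tlg[1], tlg_red = p$tlg[2],
        entropy_std = p$entropy[1], entropy_red = p$entropy[2]))
    }
    row
  })
  features <- do.call(rbind, rows)
  clinical <- read_clinical_table(file.path(dir, "clinical.csv"))
  list(features = features, clinical = clinical)
}
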