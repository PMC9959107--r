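#' Simulate survival outcomes from a linear log-hazard
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(linear_predictor)`. Censoring is independent
#' exponential with its rate chosen so the expected censored fraction equals
#' `censor_rate` (exact under a null linear predictor): with event rate
#' lambda and censoring rate mu, P(censored) = mu / (mu + lambda).
#' `censor_rate = 0` disables censoring entirely.
#'
#' @param linear_predictor Per-subject log-hazard offsets.
#' @param baseline_hazard Baseline exponential rate (per month).
#' @param censor_rate Target censored proportion, in \[0, 1).
#' @return Data.frame with `os_months` and `os_event` (1 = death).
#' @export
simulate_survival <- function(linear_predictor, baseline_hazard,
                              censor_rate = 0) {
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  n <- length(linear_predictor)
  rate <- baseline_hazard * exp(linear_predictor)
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    mu <- censor_rate / (1 - censor_rate) * baseline_hazard * mean(exp(linear_predictor))
    t_cens <- stats::rexp(n, mu)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(os_months = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}

#' Generate clinical records linked to cohort features
#'
#' Draws per-patient clinical covariates with configurable links to the
#' computed radiogenomic features: the stage-IV indicator follows a logistic
#' model with coefficients `spec$stage_betas` on standardized features;
#' overall survival is exponential with log-hazard
#' `sum(spec$survival_betas * feature)` on the raw feature scale (so a Cox
#' fit recovers the betas per unit); smoking and histology follow configured
#' marginals; PD-L1 expression is drawn from a zero-inflated-looking beta
#' scaled to percent. With all betas empty (the default) the cohort is null:
#' no feature-outcome links.
#'
#' @param features Data.frame of per-patient features, one row per patient.
#' @param spec A [cohort_spec()].
#' @return Data.frame of class `clinical_table`: `patient_id`, `stage_group`
#'   (`"I-III"`/`"IV"`), `smoking`, `histology`, `pdl1_percent`, `os_months`,
#'   `os_event`, plus the attribute `truth` with the realized linear
#'   predictors.
#' @export
generate_clinical <- function(features, spec) {
  spec <- validate_cohort_spec(spec)
  n <- nrow(features)
  for (betas in list(spec$stage_betas, spec$survival_betas)) {
    unknown <- setdiff(names(betas), names(features))
    if (length(unknown))
      stop("unknown feature name in betas: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  with_seed(derive_seed(spec$seed, 0L, 3L), {
    stage_lp <- rep(stats::qlogis(spec$stage4_fraction), n)
    for (nm in names(spec$stage_betas)) {
      v <- features[[nm]]
      z <- if (stats::sd(v, na.rm = TRUE) > 0)
        (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE) else rep(0, n)
      z[is.na(z)] <- 0
      stage_lp <- stage_lp + spec$stage_betas[[nm]] * z
    }
    stage4 <- stats::runif(n) < stats::plogis(stage_lp)

    surv_lp <- rep(0, n)
    for (nm in names(spec$survival_betas)) {
      v <- features[[nm]]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      surv_lp <- surv_lp + spec$survival_betas[[nm]] * v
    }
    surv_lp <- surv_lp - mean(surv_lp)  # center so baseline_hazard is the cohort rate
    os <- simulate_survival(surv_lp, spec$baseline_hazard, spec$censor_rate)

    out <- data.frame(
      patient_id = if ("patient_id" %in% names(features))
        features$patient_id else sprintf("P%03d", seq_len(n)),
      stage_group = ifelse(stage4, "IV", "I-III"),
      smoking = ifelse(stats::runif(n) < spec$smoker_fraction, "ever", "never"),
      histology = ifelse(stats::runif(n) < spec$adeno_fraction,
                         "adenocarcinoma", "squamous"),
      pdl1_percent = round(100 * stats::rbeta(n, 0.35, 1.4), 1),
      os_months = os$os_months,
      os_event = os$os_event,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(stage_lp = stage_lp, surv_lp = surv_lp)
    class(out) <- c("clinical_table", "data.frame")
    out
  })
}
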