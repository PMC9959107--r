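#' Consistency intraclass correlation coefficient, ICC(C,1)
#'
#' Two-way random-effects model, single measurement, consistency definition
#' (McGraw & Wong C,1): subjects and conditions are crossed, and
#' `ICC = (MSR - MSE) / (MSR + (k - 1) * MSE)` from the two-way ANOVA mean
#' squares, where MSR is the between-subject and MSE the residual mean
#' square. Consistency ICC ignores a uniform shift between conditions, which
#' is the appropriate reliability notion when comparing the same feature
#' under two processing choices (PAF cutoffs, image matrix sizes).
#' The absolute-agreement variant ICC(A,1), which penalises such shifts, is
#' available via `type = "agreement"`.
#'
#' Rows with any missing value are dropped (listwise deletion). With fewer
#' than 3 complete rows, or zero variance overall, the ICC is undefined and
#' returned as `NA` with a message.
#'
#' @param pairs An n x 2 numeric matrix or data.frame: one row per subject,
#'   one column per condition.
#' @param type `"consistency"` (default) or `"agreement"`.
#' @return Object of class `icc_estimate`: `value`, `model`, `ms_rows`,
#'   `ms_error`, `ms_cols`, `k`, `n_used`, `band`.
#' @examples
#' x <- rnorm(20)
#' icc_consistency(cbind(x, x + 5))$value  # 1: uniform shift ignored
#' @export
icc_consistency <- function(pairs, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  m <- as.matrix(pairs)
  if (!is.numeric(m) || ncol(m) != 2L)
    stop("pairs must be an n x 2 numeric table", call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  undefined <- function(reason) {
    message("ICC undefined: ", reason)
    structure(list(value = NA_real_, model = type, ms_rows = NA_real_,
                   ms_error = NA_real_, ms_cols = NA_real_, k = k, n_used = n,
                   band = NA_character_),
              class = "icc_estimate")
  }
  if (n < 3L) return(undefined(sprintf("only %d complete pairs (need >= 3)", n)))
  grand <- mean(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) return(undefined("zero total variance"))
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  value <- if (type == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  structure(list(
    value = value,
    model = sprintf("two-way random, single measurement, %s (ICC(%s,1))",
                    type, if (type == "consistency") "C" else "A"),
    ms_rows = msr, ms_error = mse, ms_cols = msc, k = k, n_used = n,
    band = classify_icc(value)),
    class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC = %s [%s], n = %d (%s)\n",
              ifelse(is.na(x$value), "NA", sprintf("%.3f", x$value)),
              ifelse(is.na(x$band), "undefined", x$band), x$n_used, x$model))
  invisible(x)
}

#' Reliability band of an ICC value
#'
#' Conventional interpretation bands: below 0.5 poor, 0.5 to 0.75 moderate,
#' above 0.75 up to 0.9 good, above 0.9 excellent. The endpoints are
#' assigned as poor < 0.5 <= moderate <= 0.75 < good <= 0.9 < excellent.
#'
#' @param value Finite ICC value(s).
#' @return Character vector of band labels.
#' @examples
#' classify_icc(c(-0.416, 0.736, 0.894, 0.958))
#' @export
classify_icc <- function(value) {
  if (any(!is.finite(value)))
    stop("ICC value must be finite", call. = FALSE)
  # endpoints: 0.5 and 0.75 fall in "moderate", 0.9 in "good"
  ifelse(value < 0.5, "poor",
         ifelse(value <= 0.75, "moderate",
                ifelse(value <= 0.9, "good", "excellent")))
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations over the numeric columns of a
#' cohort table, with two-sided p-values, the n used per pair, and both raw
#' and Bonferroni-corrected significance flags over the family of all pairs.
#' A zero-variance column yields missing entries (with a message).
#'
#' @param cohort Data.frame of per-patient features (numeric columns used).
#' @param method Correlation method passed to [stats::cor.test()].
#' @param alpha Family-wise significance level for the flags.
#' @return Object of class `correlation_matrix`: matrices `r`, `p`, `n`,
#'   `sig_raw`, `sig_bonferroni`, plus `n_tests` and `alpha`.
#' @export
correlation_matrix <- function(cohort, method = "pearson", alpha = 0.05) {
  num <- cohort[vapply(cohort, is.numeric, logical(1))]
  cols <- names(num)
  q <- length(cols)
  if (q < 2L) stop("need at least two numeric columns", call. = FALSE)
  r <- p <- matrix(NA_real_, q, q, dimnames = list(cols, cols))
  nmat <- matrix(0L, q, q, dimnames = list(cols, cols))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(q)) nmat[i, i] <- sum(!is.na(num[[i]]))
  for (i in seq_len(q - 1)) {
    for (j in (i + 1):q) {
      ok <- stats::complete.cases(num[[i]], num[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      x <- num[[i]][ok]; y <- num[[j]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        message(sprintf("zero variance in pair (%s, %s); correlation undefined",
                        cols[i], cols[j]))
        next
      }
      ct <- stats::cor.test(x, y, method = method)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  n_tests <- q * (q - 1) / 2
  structure(list(r = r, p = p, n = nmat,
                 sig_raw = p < alpha,
                 sig_bonferroni = p < alpha / n_tests,
                 n_tests = n_tests, alpha = alpha, method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pairwise %s correlations (%d tests, Bonferroni alpha %.3g)\n",
              x$method, x$n_tests, x$alpha / x$n_tests))
  print(round(x$r, digits))
  invisible(x)
}

#' Two-group comparison with an algorithmic test choice
#'
#' Compares a feature between two groups with a t-test or Mann-Whitney U
#' test. The `"auto"` policy makes the "as appropriate" choice reproducible:
#' it uses Mann-Whitney when either group is small (n < 20) or fails a
#' Shapiro-Wilk normality screen at p < 0.05, and a Welch t-test otherwise.
#' The chosen test is always recorded in the output.
#'
#' @param values Numeric feature vector.
#' @param groups Two-level grouping (factor or character), same length.
#' @param test `"auto"`, `"t"`, or `"mann_whitney"`.
#' @return Object of class `group_comparison`: `test_used`, `statistic`,
#'   `p_value`, and a per-group summary data.frame.
#' @export
compare_groups <- function(values, groups, test = c("auto", "t", "mann_whitney")) {
  test <- match.arg(test)
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels", call. = FALSE)
  split_vals <- split(values, groups)
  if (any(lengths(split_vals) == 0L))
    stop("both groups must be non-empty", call. = FALSE)
  if (test == "auto") {
    non_normal <- vapply(split_vals, function(v) {
      n <- length(v)
      if (n < 20L) return(TRUE)
      if (stats::sd(v) == 0) return(TRUE)
      stats::shapiro.test(v)$p.value < 0.05
    }, logical(1))
    test <- if (any(non_normal)) "mann_whitney" else "t"
  }
  x <- split_vals[[1]]; y <- split_vals[[2]]
  if (test == "t") {
    ht <- stats::t.test(x, y)
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    n1 <- length(x); n2 <- length(y)
    if (stats::sd(values) == 0) {
      # fully tied data: midranks give W at its null mean, no evidence
      statistic <- n1 * n2 / 2; p <- 1
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  }
  summ <- data.frame(
    group = levels(groups), n = lengths(split_vals),
    mean = vapply(split_vals, mean, numeric(1)),
    sd = vapply(split_vals, stats::sd, numeric(1)),
    median = vapply(split_vals, stats::median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(test_used = test, statistic = statistic, p_value = p,
                 group_summary = summ),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.3f, p = %.4g\n",
              ifelse(x$test_used == "t", "Welch t", "Mann-Whitney U"),
              x$statistic, x$p_value))
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits a single-covariate Cox model by Newton-Raphson maximization of the
#' partial likelihood (Breslow tie handling by default, Efron available) and
#' reports the hazard ratio per unit of the feature as provided (no internal
#' standardization), its Wald 95% CI and p-value. Monotone-likelihood fits
#' (perfect separation, infinite coefficient) are flagged rather than
#' returned silently.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = death, 0 = censored).
#' @param feature Numeric covariate.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Confidence level of the Wald interval.
#' @return Object of class `cox_result`: `beta`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `se`, `n`, `n_events`, `flagged` (monotone likelihood).
#' @examples
#' set.seed(1)
#' x <- rnorm(120)
#' t <- rexp(120, 0.05 * exp(0.5 * x))
#' cox_univariate(t, rep(1, 120), x)
#' @export
cox_univariate <- function(time, event, feature, ties = c("breslow", "efron"),
                           conf_level = 0.95) {
  ties <- match.arg(ties)
  ok <- stats::complete.cases(time, event, feature)
  time <- time[ok]; event <- event[ok]; feature <- feature[ok]
  if (sum(event) < 2L)
    stop("need at least 2 events", call. = FALSE)
  if (!all(is.finite(feature)))
    stop("feature must be finite", call. = FALSE)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ feature, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(beta = beta, hr = exp(beta),
                 ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                 p = 2 * stats::pnorm(-abs(beta / se)), se = se,
                 n = length(time), n_events = sum(event),
                 ties = ties, flagged = flagged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), p = %.4g, %d events / %d subjects%s\n",
              x$hr, x$ci_low, x$ci_high, x$p, x$n_events, x$n,
              if (x$flagged) " [monotone likelihood]" else ""))
  invisible(x)
}
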