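# Independent oracles the implementation is checked against. These stay
# deliberately naive: they re-derive each quantity from first principles.

# MATH by brute force: explicit sort-based medians, no stats::median/mad.
oracle_math <- function(vafs) {
  naive_median <- function(x) {
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  med <- naive_median(vafs)
  100 * naive_median(abs(vafs - med)) / med
}

# Shannon entropy by explicit bin loop.
oracle_shannon <- function(vafs) {
  h <- 0
  n <- length(vafs)
  for (b in 1:10) {
    lo <- (b - 1) * 10; hi <- b * 10
    cnt <- if (b < 10) sum(vafs >= lo & vafs < hi) else sum(vafs >= lo & vafs <= hi)
    if (cnt > 0) {
      p <- cnt / n
      h <- h - p * log2(p)
    }
  }
  h
}

# ICC(C,1) via a from-scratch two-way ANOVA fitted with aov().
oracle_icc_c1 <- function(m) {
  m <- as.matrix(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                  condition = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + condition, data = d))[[1]]
  msr <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse)
}

# Breslow negative log partial likelihood, written directly from the
# definition, maximized by coarse grid search refined with optimize().
oracle_cox_beta <- function(time, event, x) {
  nlpl <- function(beta) {
    eta <- beta * x
    s <- 0
    for (t in sort(unique(time[event == 1]))) {
      d_set <- which(time == t & event == 1)
      risk <- which(time >= t)
      s <- s - sum(eta[d_set]) + length(d_set) * log(sum(exp(eta[risk])))
    }
    s
  }
  grid <- seq(-4, 4, by = 0.05)
  b0 <- grid[which.min(vapply(grid, nlpl, numeric(1)))]
  stats::optimize(nlpl, c(b0 - 0.1, b0 + 0.1), tol = 1e-10)$minimum
}

# Count modes of a kernel density estimate (interior local maxima).
density_mode_locations <- function(x, bw = 2.5) {
  d <- stats::density(x, bw = bw, n = 1024)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- peaks[y[peaks] > 0.05 * max(y)]  # ignore negligible bumps
  d$x[peaks]
}

# Small deterministic variant table exercising every filter boundary.
make_boundary_fixture <- function() {
  data.frame(
    chrom = rep("chr1", 12), pos = 1:12, ref = "A", alt = "T",
    vaf_percent = c(40, 40, 4.9, 5.0, 30, 30, 40, 40, 40, 40, 40, 0),
    depth = c(19L, 20L, 100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L, 19L, 100L),
    consequence = c("missense", "missense", "missense", "missense", "synonymous",
                    "indel", "missense", "missense", "missense", "missense",
                    "synonymous", "missense"),
    paf_general = c(0, 0, 0, 0, 0, 0, 2, 0.5, 0.005, NA, 2, NA),
    paf_eas = c(0, 0, 0, 0, 0, 0, 0.2, 0.5, 0.005, NA, 2, NA),
    stringsAsFactors = FALSE
  )
}

# Uniform ellipsoid phantom on a constant background.
make_phantom <- function(dims = c(40L, 40L, 30L), spacing = c(2.7, 2.7, 2.79),
                         semi_axes = c(13, 13, 13), center_mm = NULL,
                         tumor_suv = 8, background = 0.5) {
  if (is.null(center_mm)) center_mm <- dims * spacing / 2
  ax <- lapply(1:3, function(i) (seq_len(dims[i]) - 0.5) * spacing[i])
  d2 <- outer(outer(((ax[[1]] - center_mm[1]) / semi_axes[1])^2,
                    ((ax[[2]] - center_mm[2]) / semi_axes[2])^2, "+"),
              ((ax[[3]] - center_mm[3]) / semi_axes[3])^2, "+")
  vals <- array(background, dims)
  vals[d2 <= 1] <- tumor_suv
  suv_volume(vals, spacing, "standard")
}

full_voi <- function(volume) {
  list(lo = c(1L, 1L, 1L), hi = dim(volume$values))
}
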