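#' Generate one patient's annotated variant table
#'
#' Draws true somatic mutations from one or two clonal VAF modes plus a set of
#' germline contaminants, with binomial read-count noise at a drawn depth, and
#' annotates each record with consequence class and population allele
#' frequencies (general and East-Asian, percent). This emulates the variant
#' table an annotated tumor-only exome pipeline hands to downstream filtering.
#'
#' Somatic clone CCFs are 1 (clonal) and, for bimodal patients,
#' `spec$subclone_ccf`; the expected VAF of a variant with cancer-cell
#' fraction CCF is `100 * purity * CCF / 2` percent (heterozygous, diploid).
#' Germline contaminants sit at ~50% (het) or ~100% (hom) VAF with nonzero
#' PAFs drawn log-uniformly over `spec$paf_range`; variants absent from the
#' population database carry PAF zero or missing. Variants with zero observed
#' alternate reads are dropped (they would never be called).
#'
#' @param spec A [cohort_spec()].
#' @param patient_index Patient number in `1:spec$n_patients`.
#' @param retry Internal offset added to the sub-seed when a degenerate table
#'   must be regenerated.
#' @return A `data.frame` of class `variant_table` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `vaf_percent`, `depth`, `consequence`,
#'   `paf_general`, `paf_eas`, and an attribute `truth` recording the
#'   generating parameters (purity, clone VAF modes, true counts).
#' @examples
#' tab <- generate_variant_table(cohort_spec(n_patients = 2, seed = 1), 1)
#' head(tab)
#' attr(tab, "truth")$clone_vaf_modes
#' @export
generate_variant_table <- function(spec, patient_index, retry = 0L) {
  spec <- validate_cohort_spec(spec)
  patient_index <- as.integer(patient_index)
  if (is.na(patient_index) || patient_index < 1L)
    stop("patient_index must be a positive integer", call. = FALSE)
  with_seed(derive_seed(spec$seed, patient_index, 1L + 1000L * retry), {
    # scaled beta: median ~50%, IQR ~0.33, over the 20-100% specimen range
    purity <- spec$purity_range[1] +
      diff(spec$purity_range) * rbeta(1, 1.1, 1.7)
    # per-specimen coverage varies around the platform average (surgical
    # resections vs small biopsies); lognormal factor, cohort mean preserved
    depth_mu <- spec$mean_depth * exp(rnorm(1, -0.35^2 / 2, 0.35))
    bimodal <- runif(1) < spec$bimodal_fraction
    n_som <- sample_range(spec$n_somatic_range)
    n_germ <- sample_range(spec$n_germline_range)
    ccfs <- if (bimodal) c(1, spec$subclone_ccf) else 1
    clone_modes <- 100 * purity * ccfs / 2

    # somatic: assign clones, perturb CCF per variant, binomial read noise
    clone_id <- if (bimodal) sample(1:2, n_som, replace = TRUE) else rep(1L, n_som)
    ccf_i <- pmin(ccfs[clone_id] * exp(rnorm(n_som, 0, spec$ccf_dispersion)), 1)
    vaf_true_som <- 100 * purity * ccf_i / 2
    paf_missing <- runif(n_som) < spec$somatic_paf_missing_fraction
    som <- draw_records(n_som, vaf_true_som, spec, depth_mu,
                        paf_general = ifelse(paf_missing, NA_real_, 0),
                        paf_eas = ifelse(paf_missing, NA_real_, 0))

    # germline contaminants: VAF ~50/100, long-tailed PAFs in both populations
    hom <- runif(n_germ) < spec$germline_hom_fraction
    vaf_true_germ <- ifelse(hom, 100, 50)
    lp <- log(spec$paf_range)
    paf_gen <- exp(runif(n_germ, lp[1], lp[2]))
    paf_eas <- pmin(pmax(paf_gen * exp(rnorm(n_germ, 0, 0.8)),
                         spec$paf_range[1] / 100), spec$paf_range[2])
    germ <- draw_records(n_germ, vaf_true_germ, spec, depth_mu,
                         paf_general = paf_gen, paf_eas = paf_eas)

    is_somatic <- c(rep(TRUE, nrow(som)), rep(FALSE, nrow(germ)))
    tab <- rbind(som, germ)
    ord <- order(tab$chrom, tab$pos)
    tab <- tab[ord, , drop = FALSE]
    is_somatic <- is_somatic[ord]
    rownames(tab) <- NULL
    attr(tab, "truth") <- list(
      patient_index = patient_index,
      purity = purity,
      bimodal = bimodal,
      clone_ccfs = ccfs,
      clone_vaf_modes = clone_modes,
      n_somatic_true = n_som,
      n_germline_true = n_germ,
      is_somatic = is_somatic
    )
    class(tab) <- c("variant_table", "data.frame")
    tab
  })
}

sample_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  sample(seq.int(r[1], r[2]), 1L)
}

CONSEQUENCE_LEVELS <- c("missense", "synonymous", "nonsense", "indel", "noncoding")

draw_records <- function(n, vaf_true, spec, depth_mu, paf_general, paf_eas) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vaf_percent = numeric(),
                      depth = integer(), consequence = character(),
                      paf_general = numeric(), paf_eas = numeric(),
                      stringsAsFactors = FALSE))
  }
  depth <- pmax(rnbinom(n, size = 5, mu = depth_mu), 1L)
  p <- pmin(vaf_true, 100) / 100
  rho <- spec$vaf_overdispersion
  if (rho > 0) {
    # beta-binomial read counts: extra VAF dispersion beyond sampling noise
    s <- (1 - rho) / rho
    mid <- p > 0 & p < 1
    p[mid] <- rbeta(sum(mid), p[mid] * s, (1 - p[mid]) * s)
  }
  alt_reads <- rbinom(n, depth, p)
  rest <- (1 - spec$missense_fraction) * c(0.45, 0.2, 0.15, 0.2)
  consequence <- sample(CONSEQUENCE_LEVELS, n, replace = TRUE,
                        prob = c(spec$missense_fraction, rest))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                USE.NAMES = FALSE)
  df <- data.frame(
    chrom = sprintf("chr%d", sample(1:22, n, replace = TRUE)),
    pos = sample.int(2.4e8, n, replace = TRUE),
    ref = ref,
    alt = ifelse(consequence == "indel", paste0(alt, alt), alt),
    vaf_percent = 100 * alt_reads / depth,
    depth = as.integer(depth),
    consequence = consequence,
    paf_general = paf_general,
    paf_eas = paf_eas,
    stringsAsFactors = FALSE
  )
  df[alt_reads > 0L, , drop = FALSE]
}
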