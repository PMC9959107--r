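#' Threshold-based tumor segmentation at 41% of SUVmax
#'
#' Finds SUVmax inside the volume of interest, thresholds the VOI at
#' `threshold_fraction * SUVmax`, and keeps only the 26-connected component
#' containing the peak voxel, so disjoint hot structures inside a generous
#' VOI do not leak into the tumor mask.
#'
#' @param volume An [suv_volume()].
#' @param voi List with integer `lo` and `hi` (1-based, inclusive) voxel
#'   coordinates of an axis-aligned box inside the grid.
#' @param threshold_fraction Fraction of VOI SUVmax used as the threshold
#'   (study value 0.41).
#' @return Object of class `segmentation`: `mask` (logical array on the full
#'   grid), `threshold_suv`, `voi`, `peak` (voxel coordinates of the maximum)
#'   and `n_voxels`.
#' @examples
#' ph <- generate_pet_volume(cohort_spec(n_patients = 2, seed = 1), 1)
#' seg <- segment_tumor(ph$volume, ph$voi)
#' seg$n_voxels
#' @export
segment_tumor <- function(volume, voi, threshold_fraction = 0.41) {
  stopifnot(inherits(volume, "suv_volume"))
  d <- dim(volume$values)
  lo <- as.integer(voi$lo); hi <- as.integer(voi$hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 1L) || any(hi > d) ||
      any(lo > hi))
    stop("voi must be a non-empty box inside the grid", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must be in (0, 1]", call. = FALSE)
  crop <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  suv_max <- max(crop)
  if (suv_max <= 0)
    stop("voi contains no positive voxel", call. = FALSE)
  thr <- threshold_fraction * suv_max
  cand <- crop >= thr
  peak_flat <- which.max(crop)
  comp <- connected_component_26(cand, peak_flat)
  mask <- array(FALSE, d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- comp
  peak <- lo - 1L + arrayInd(peak_flat, dim(crop))[1, ]
  structure(list(mask = mask, threshold_suv = thr,
                 voi = list(lo = lo, hi = hi),
                 peak = as.integer(peak), n_voxels = sum(comp)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d voxels at SUV >= %.3f (peak at [%s])\n",
              x$n_voxels, x$threshold_suv, paste(x$peak, collapse = ", ")))
  invisible(x)
}

# 26-connected component of `cand` containing flat index `seed`, by frontier
# dilation on a FALSE-padded copy (padding makes flat-offset moves safe).
connected_component_26 <- function(cand, seed) {
  d <- dim(cand)
  dp <- d + 2L
  padded <- array(FALSE, dp)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cand
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  flat_off <- off$dx + dp[1] * (off$dy + dp[2] * off$dz)
  seed_idx <- arrayInd(seed, d) + 1L
  seed_flat <- seed_idx[1] + dp[1] * ((seed_idx[2] - 1L) + dp[2] * (seed_idx[3] - 1L))
  visited <- array(FALSE, dp)
  visited[seed_flat] <- TRUE
  frontier <- seed_flat
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, flat_off, "+")))
    nb <- nb[padded[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

#' First-order glycolytic features of a segmented tumor
#'
#' SUVmax and SUVmean over the masked voxels, metabolic tumor volume
#' MTV = n_voxels x voxel volume (mL), and total lesion glycolysis
#' TLG = MTV x SUVmean.
#'
#' @param volume An [suv_volume()].
#' @param segmentation A [segment_tumor()] result aligned to `volume`.
#' @return A one-row data.frame: `grid_label`, `suv_max`, `suv_mean`, `mtv`,
#'   `tlg`, `n_voxels`.
#' @export
first_order_features <- function(volume, segmentation) {
  stopifnot(inherits(volume, "suv_volume"), inherits(segmentation, "segmentation"))
  vals <- volume$values[segmentation$mask]
  if (length(vals) == 0L)
    stop("empty segmentation mask", call. = FALSE)
  mtv <- length(vals) * voxel_volume_mm3(volume) / 1000
  suv_mean <- mean(vals)
  data.frame(grid_label = volume$grid_label,
             suv_max = max(vals), suv_mean = suv_mean,
             mtv = mtv, tlg = mtv * suv_mean,
             n_voxels = length(vals),
             stringsAsFactors = FALSE)
}

#' First-order intensity entropy of the segmented tumor
#'
#' Masked SUVs are discretized into fixed-width bins (0.25 SUV, edges
#' anchored at integer multiples of the bin width), and the entropy
#' `-sum P(i) log2(P(i) + eps)` is returned over the occupied levels, with
#' `eps ~ 2.2e-16` guarding the logarithm as in the standardized
#' feature-extraction definition.
#'
#' @param volume An [suv_volume()].
#' @param segmentation A [segment_tumor()] result aligned to `volume`.
#' @param bin_width Discretization bin width in SUV (study value 0.25).
#' @param epsilon Small positive guard added inside the logarithm.
#' @return Entropy in bits.
#' @export
compute_pet_entropy <- function(volume, segmentation, bin_width = 0.25,
                                epsilon = 2.2e-16) {
  stopifnot(inherits(volume, "suv_volume"), inherits(segmentation, "segmentation"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  vals <- volume$values[segmentation$mask]
  if (length(vals) == 0L)
    stop("empty segmentation mask", call. = FALSE)
  level <- floor(vals / bin_width)
  p <- as.vector(table(level)) / length(vals)
  -sum(p * log2(p + epsilon))
}

#' PET feature sets at standard and reduced matrix sizes
#'
#' Derives the reduced-matrix volume by in-plane block averaging, segments
#' each grid independently (each with its own SUVmax and 41% threshold), and
#' computes the first-order features and intensity entropy on both.
#'
#' @param standard_volume A standard-grid [suv_volume()].
#' @param voi VOI box in standard-grid voxel coordinates.
#' @param threshold_fraction Segmentation threshold fraction.
#' @param bin_width Entropy bin width (SUV).
#' @return A two-row data.frame (standard, reduced) with the
#'   [first_order_features()] columns plus `entropy`.
#' @examples
#' ph <- generate_pet_volume(cohort_spec(n_patients = 2, seed = 1), 1)
#' pet_feature_sets(ph$volume, ph$voi)
#' @export
pet_feature_sets <- function(standard_volume, voi, threshold_fraction = 0.41,
                             bin_width = 0.25) {
  stopifnot(identical(standard_volume$grid_label, "standard"))
  reduced <- downsample_inplane(standard_volume, 2L)
  voi_red <- list(lo = c(ceiling(voi$lo[1:2] / 2), voi$lo[3]),
                  hi = c(ceiling(voi$hi[1:2] / 2), voi$hi[3]))
  rows <- lapply(list(list(v = standard_volume, b = voi),
                      list(v = reduced, b = voi_red)), function(g) {
    seg <- segment_tumor(g$v, g$b, threshold_fraction)
    feats <- first_order_features(g$v, seg)
    feats$entropy <- compute_pet_entropy(g$v, seg, bin_width)
    feats
  })
  do.call(rbind, rows)
}
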