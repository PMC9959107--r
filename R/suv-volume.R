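#' SUV volume container
#'
#' A 3-D grid of non-negative standardized uptake values with its voxel
#' spacing (mm) and a grid label. The study's standard matrix has
#' 2.7 x 2.7 x 2.79 mm voxels; the reduced matrix 5.4 x 5.4 x 2.79 mm.
#'
#' @param values Numeric 3-D array of SUVs (>= 0).
#' @param spacing Voxel spacing `c(x, y, z)` in mm.
#' @param grid_label `"standard"` or `"reduced"`.
#' @return Object of class `suv_volume`.
#' @export
suv_volume <- function(values, spacing = c(2.7, 2.7, 2.79),
                       grid_label = c("standard", "reduced")) {
  grid_label <- match.arg(grid_label)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array", call. = FALSE)
  if (any(is.na(values)) || any(values < 0))
    stop("SUVs must be non-negative and complete", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths (mm)", call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 grid_label = grid_label),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUV volume [%s]: %d x %d x %d voxels at %.2f x %.2f x %.2f mm, SUV %.2f-%.2f\n",
              x$grid_label, d[1], d[2], d[3], x$spacing[1], x$spacing[2],
              x$spacing[3], min(x$values), max(x$values)))
  invisible(x)
}

voxel_volume_mm3 <- function(volume) prod(volume$spacing)

#' In-plane block-average downsampling to the reduced matrix
#'
#' Halving the reconstruction matrix (256 x 256 to 128 x 128) doubles the
#' in-plane voxel footprint; this is emulated by averaging each
#' `factor` x `factor` in-plane block, leaving the z axis untouched. The
#' total uptake (SUV sum times voxel volume) is conserved exactly, and the
#' maximum can only decrease — the partial-volume direction seen when
#' comparing SUVmax across matrix sizes. Odd in-plane dimensions are padded
#' by edge replication first (with a message); padding breaks exact mass
#' conservation at the rim.
#'
#' @param volume A standard-grid [suv_volume()].
#' @param factor Integer in-plane downsampling factor (default 2).
#' @return A `suv_volume` with `grid_label = "reduced"` and doubled in-plane
#'   spacing.
#' @export
downsample_inplane <- function(volume, factor = 2L) {
  stopifnot(inherits(volume, "suv_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("factor must be a positive integer", call. = FALSE)
  v <- volume$values
  d <- dim(v)
  pad_to <- ceiling(d[1:2] / factor) * factor
  if (any(pad_to != d[1:2])) {
    message(sprintf("padding in-plane dimensions %d x %d to %d x %d by edge replication",
                    d[1], d[2], pad_to[1], pad_to[2]))
    v <- v[c(seq_len(d[1]), rep(d[1], pad_to[1] - d[1])),
           c(seq_len(d[2]), rep(d[2], pad_to[2] - d[2])),
           , drop = FALSE]
    d <- dim(v)
  }
  # mean over factor-wide blocks along x, then along y
  a <- array(v, c(factor, d[1] %/% factor, d[2], d[3]))
  m1 <- colMeans(a)                                  # (x/f, y, z)
  b <- aperm(m1, c(2, 1, 3))                         # (y, x/f, z)
  m2 <- colMeans(array(b, c(factor, d[2] %/% factor, d[1] %/% factor, d[3])))
  out <- aperm(m2, c(2, 1, 3))                       # (x/f, y/f, z)
  suv_volume(out,
             spacing = volume$spacing * c(factor, factor, 1),
             grid_label = "reduced")
}

# Stationary Gaussian random field with unit variance, generated by FFT
# convolution of white noise with a (circularly wrapped) Gaussian kernel.
gaussian_random_field <- function(dim, spacing, corr_length_mm) {
  w <- array(rnorm(prod(dim)), dim)
  if (corr_length_mm <= 0) return(w)
  ax <- lapply(1:3, function(i) {
    n <- dim[i]
    d <- pmin(0:(n - 1), n - (0:(n - 1))) * spacing[i]
    exp(-d^2 / (2 * corr_length_mm^2))
  })
  kern <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  dim(kern) <- dim
  f <- Re(fft(fft(w) * fft(kern), inverse = TRUE)) / prod(dim)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a textured PET tumor phantom
#'
#' Places an ellipsoidal tumor on a uniform background at the standard grid
#' (2.7 x 2.7 x 2.79 mm). Tumor uptake is `base_suv * (1 + a * G)` where `G`
#' is a unit-variance Gaussian random field with correlation length
#' `spec$texture_corr_length_mm` and `a = spec$texture_amplitude`, clipped to
#' be positive. The VOI is the tumor bounding box plus a margin. The tumor
#' must fit inside the field of view with at least a 2-voxel margin.
#'
#' @param spec A [cohort_spec()].
#' @param patient_index Patient number.
#' @param retry Internal sub-seed offset for regeneration.
#' @return A list with `volume` (a standard-grid [suv_volume()]), `voi`
#'   (list of 1-based inclusive `lo`/`hi` voxel coordinates) and `truth`
#'   (semi-axes in mm, base SUV, center).
#' @examples
#' ph <- generate_pet_volume(cohort_spec(n_patients = 2, seed = 1), 1)
#' ph$volume
#' @export
generate_pet_volume <- function(spec, patient_index, retry = 0L) {
  spec <- validate_cohort_spec(spec)
  spacing <- c(2.7, 2.7, 2.79)
  dims <- spec$volume_dim
  with_seed(derive_seed(spec$seed, as.integer(patient_index), 2L + 1000L * retry), {
    radius <- runif(1, spec$tumor_radius_mm_range[1], spec$tumor_radius_mm_range[2])
    semi <- radius * (1 + runif(3, -spec$ellipticity, spec$ellipticity))
    base_suv <- runif(1, spec$tumor_suv_range[1], spec$tumor_suv_range[2])
    fov_mm <- dims * spacing
    if (any(2 * semi + 4 * spacing > fov_mm))
      stop("tumor does not fit inside the field of view with a 2-voxel margin",
           call. = FALSE)
    center <- fov_mm / 2 + runif(3, -1, 1) * spacing

    coords <- lapply(1:3, function(i) ((seq_len(dims[i]) - 0.5) * spacing[i]))
    dx2 <- outer(outer(((coords[[1]] - center[1]) / semi[1])^2,
                       ((coords[[2]] - center[2]) / semi[2])^2, "+"),
                 ((coords[[3]] - center[3]) / semi[3])^2, "+")
    inside <- dx2 <= 1

    g <- gaussian_random_field(dims, spacing, spec$texture_corr_length_mm)
    tumor_suv <- pmax(base_suv * (1 + spec$texture_amplitude * g), 0)
    vals <- array(spec$background_suv, dims)
    vals[inside] <- tumor_suv[inside]

    idx <- which(inside, arr.ind = TRUE)
    margin <- 3L
    voi <- list(lo = pmax(apply(idx, 2, min) - margin, 1L),
                hi = pmin(apply(idx, 2, max) + margin, dims))
    list(volume = suv_volume(vals, spacing, "standard"),
         voi = voi,
         truth = list(patient_index = as.integer(patient_index),
                      semi_axes_mm = semi, base_suv = base_suv,
                      center_mm = center,
                      true_volume_ml = 4 / 3 * pi * prod(semi) / 1000))
  })
}
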