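#' Read and write the package's on-disk formats
#'
#' Variant tables are tab-separated with the columns `chrom`, `pos`, `ref`,
#' `alt`, `vaf_percent`, `depth`, `consequence`, `paf_general`, `paf_eas`
#' (missing PAFs written as `NA`). Clinical tables are CSV. SUV volumes go
#' to NIfTI with the voxel spacing in the header (the header is
#' authoritative on read); the VOI box travels in a JSON sidecar with
#' 1-based inclusive `lo`/`hi` voxel coordinates. Cohort specs round-trip
#' through YAML.
#'
#' @param variants,path,clinical,volume,voi,spec,file Objects/paths as named.
#' @return Readers return the parsed object; writers return the path,
#'   invisibly.
#' @name radhet-io
NULL

#' @rdname radhet-io
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  utils::write.table(as.data.frame(variants), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname radhet-io
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_variants(tab)
  class(tab) <- c("variant_table", "data.frame")
  tab
}

#' @rdname radhet-io
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE)
  invisible(path)
}

#' @rdname radhet-io
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' @rdname radhet-io
#' @export
write_suv_volume <- function(volume, path, voi = NULL) {
  stopifnot(inherits(volume, "suv_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(voi)) {
    jsonlite::write_json(list(lo = as.integer(voi$lo), hi = as.integer(voi$hi),
                              grid_label = volume$grid_label),
                         sidecar_path(path), auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname radhet-io
#' @export
read_suv_volume <- function(path, grid_label = "standard") {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  vol <- suv_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                    spacing = spacing, grid_label = grid_label)
  sc <- sidecar_path(path)
  voi <- if (file.exists(sc)) {
    j <- jsonlite::read_json(sc, simplifyVector = TRUE)
    list(lo = as.integer(j$lo), hi = as.integer(j$hi))
  } else NULL
  list(volume = vol, voi = voi)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0("_voi.json")
}

#' @rdname radhet-io
#' @export
write_cohort_spec <- function(spec, file) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(unclass(spec), file, precision = 15)
  invisible(file)
}

#' @rdname radhet-io
#' @export
read_cohort_spec <- function(file) {
  vals <- yaml::read_yaml(file)
  vals <- lapply(vals, function(v) {
    if (is.list(v)) {
      if (length(v) == 0L) numeric(0) else unlist(v)
    } else v
  })
  do.call(cohort_spec, vals)
}
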