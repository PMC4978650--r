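# On-disk interchange: NIfTI-1 for images and phase maps, paired real/imag
# CSV arrays with a JSON sidecar for complex k-space.

#' Write / read an image as NIfTI-1
#'
#' Magnitude (or signed difference) images are written as NIfTI-1 with the
#' pixel spacing in the header; complex images must be split by the caller
#' (e.g. magnitude and phase as separate files).
#'
#' @param img An [image_volume()] or [phase_field()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `read_image_nifti()` returns an [image_volume()].
#' @export
write_image_nifti <- function(img, path) {
  vals <- if (inherits(img, "phase_field")) img$values else .image_values(img)
  if (is.complex(vals))
    .stopf("write complex images as separate magnitude and phase files")
  spacing <- if (inherits(img, "image_volume")) img$pixel_spacing_mm else c(1, 1)
  nii <- RNifti::asNifti(vals)
  RNifti::pixdim(nii) <- spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(nii)[1:2]
  image_volume(matrix(as.numeric(nii), dim(nii)[1L], dim(nii)[2L]),
               pixel_spacing_mm = spacing, label = basename(path))
}

#' Write / read complex k-space as paired text arrays with a JSON sidecar
#'
#' Writes `<prefix>_real.csv` and `<prefix>_imag.csv` (plain
#' platform-independent numeric arrays, no headers) plus `<prefix>_meta.json`
#' recording shape, noise level, seed, and — when present — the sampling
#' scheme. `read_kspace()` restores the [kspace_data()] including its mask.
#'
#' @param k A [kspace_data()].
#' @param prefix Path prefix for the three files.
#' @return `read_kspace()` returns the restored [kspace_data()].
#' @export
write_kspace <- function(k, prefix) {
  if (!inherits(k, "kspace_data")) .stopf("k must be kspace_data")
  utils::write.table(Re(k$values), paste0(prefix, "_real.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(k$values), paste0(prefix, "_imag.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(rows = nrow(k$values), cols = ncol(k$values),
               noise_sigma = k$noise_sigma, seed = k$seed,
               geometry = k$geometry,
               scheme = if (!is.null(k$scheme)) unclass(k$scheme))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  re <- as.matrix(utils::read.table(paste0(prefix, "_real.csv"), sep = ","))
  im <- as.matrix(utils::read.table(paste0(prefix, "_imag.csv"), sep = ","))
  vals <- matrix(complex(real = as.numeric(re), imaginary = as.numeric(im)),
                 meta$rows, meta$cols)
  scheme <- NULL
  mask <- NULL
  if (!is.null(meta$scheme)) {
    scheme <- make_pf_mask(meta$scheme$n_lines, meta$scheme$fraction,
                           meta$scheme$phase_axis, meta$scheme$side)
    mask <- .scheme_mask(scheme, dim(vals))
  }
  kspace_data(vals, mask = mask,
              noise_sigma = meta$noise_sigma %||% 0,
              seed = meta$seed %||% NA_integer_,
              geometry = meta$geometry, scheme = scheme)
}

#' Write a phantom (magnitude + phase) as NIfTI-1 pairs
#'
#' @param phantom The list returned by [make_liver_phantom()] (elements
#'   `image` and `phase`).
#' @param prefix Path prefix; writes `<prefix>_mag.nii.gz` and
#'   `<prefix>_phase.nii.gz`.
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  write_image_nifti(phantom$image, paste0(prefix, "_mag.nii.gz"))
  write_image_nifti(phantom$phase, paste0(prefix, "_phase.nii.gz"))
  invisible(prefix)
}
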