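#' Image volume container
#'
#' A light container for a single-slice (matrix) image: complex images carry
#' the full reconstructed signal, real images are either magnitude images
#' (non-negative) or signed difference images.
#'
#' @param values Numeric or complex matrix of finite samples.
#' @param pixel_spacing_mm Length-2 positive numeric: (row, column) spacing in
#'   millimetres. Rows are the phase-encode axis throughout the package.
#' @param is_ground_truth Logical flag marking synthetic ground truth.
#' @param label Free-text label (e.g. `"P1"`, `"C3"`).
#' @return An object of class `image_volume` with fields `values`,
#'   `pixel_spacing_mm`, `is_ground_truth`, `label`.
#' @export
image_volume <- function(values, pixel_spacing_mm = c(1, 1),
                         is_ground_truth = FALSE, label = "") {
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    .stopf("image_volume values must be a matrix")
  if (is.complex(values)) {
    if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
      .stopf("image_volume values must be finite")
  } else {
    if (!is.numeric(values) || any(!is.finite(values)))
      .stopf("image_volume values must be finite numeric")
  }
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    .stopf("pixel_spacing_mm must be two positive numbers")
  structure(list(values = values,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 is_ground_truth = isTRUE(is_ground_truth),
                 label = as.character(label)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d %s%s label=\"%s\" spacing=%.3f x %.3f mm\n",
              d[1L], d[2L], if (is.complex(x$values)) "complex" else "real",
              if (x$is_ground_truth) " (ground truth)" else "", x$label,
              x$pixel_spacing_mm[1L], x$pixel_spacing_mm[2L]))
  invisible(x)
}

.image_values <- function(img) {
  if (inherits(img, "image_volume")) img$values else img
}

#' Phase field container
#'
#' Per-pixel phase in radians, either the synthetic ground truth or the
#' low-frequency estimate extracted from the symmetric central k-space band.
#'
#' @param values Numeric matrix with entries in `(-pi, pi]`.
#' @param provenance `"ground_truth"` or `"low_frequency_estimate"`.
#' @return An object of class `phase_field`.
#' @export
phase_field <- function(values,
                        provenance = c("ground_truth", "low_frequency_estimate")) {
  provenance <- match.arg(provenance)
  if (is.null(dim(values)) || !is.numeric(values) || any(!is.finite(values)))
    .stopf("phase_field values must be a finite numeric matrix")
  if (any(values <= -pi - 1e-12) || any(values > pi + 1e-12))
    .stopf("phase values must lie in (-pi, pi]")
  structure(list(values = values, provenance = provenance),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("<phase_field> %d x %d (%s), range [%.3f, %.3f] rad\n",
              nrow(x$values), ncol(x$values), x$provenance,
              min(x$values), max(x$values)))
  invisible(x)
}

#' k-space data container
#'
#' Complex spatial-frequency samples in the DC-centred convention: for even
#' matrix dimensions the DC sample sits at index `floor(N/2) + 1` on each axis
#' (0-based index `floor(N/2)`). The sampling mask records which phase-encode
#' lines were acquired; wherever the mask is `FALSE` the stored value is
#' exactly zero.
#'
#' @param values Complex matrix with even dimensions.
#' @param mask Logical matrix of the same shape, `TRUE` where acquired
#'   (default: fully sampled).
#' @param noise_sigma Per-channel complex Gaussian noise SD used when the data
#'   were simulated (metadata).
#' @param seed Seed used for the noise draw (metadata).
#' @param geometry Optional list of geometry metadata (e.g. `pixel_spacing_mm`).
#' @param scheme Optional [make_pf_mask()] sampling scheme that produced the
#'   mask.
#' @return An object of class `kspace_data`.
#' @export
kspace_data <- function(values, mask = NULL, noise_sigma = 0, seed = NA_integer_,
                        geometry = NULL, scheme = NULL) {
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    .stopf("kspace values must be a matrix")
  if (any(dim(values) %% 2L != 0L))
    .stopf("kspace dimensions must be even (DC-centred convention), got %d x %d",
           nrow(values), ncol(values))
  d <- dim(values)
  values <- as.complex(values)
  dim(values) <- d
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    .stopf("kspace values must be finite")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    .stopf("mask must be a logical matrix matching the k-space shape")
  if (any(values[!mask] != 0))
    .stopf("unacquired k-space samples must be exactly zero")
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0)
    .stopf("noise_sigma must be a single non-negative number")
  structure(list(values = values, mask = mask, noise_sigma = noise_sigma,
                 seed = seed, geometry = geometry, scheme = scheme),
            class = "kspace_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %d x %d, %d/%d lines acquired, noise_sigma=%g\n",
              nrow(x$values), ncol(x$values),
              sum(apply(x$mask, 1L, any)), nrow(x$values), x$noise_sigma))
  invisible(x)
}

#' Centred orthonormal Fourier transforms
#'
#' `k_from_image()` maps an image-domain matrix to DC-centred k-space;
#' `image_from_k()` is its exact inverse. Both use orthonormal scaling
#' (division by `sqrt(N)` each way) so that round trips are exact to machine
#' precision and Parseval energy is preserved, and both require even matrix
#' dimensions so the DC-centring quadrant swap is an involution.
#'
#' @param x Image-domain matrix (numeric or complex), even dimensions.
#' @param k DC-centred k-space matrix (complex), even dimensions.
#' @return A complex matrix of the same shape.
#' @export
k_from_image <- function(x) {
  x <- .image_values(x)
  fftshift2(stats::fft(fftshift2(as.matrix(x)))) / sqrt(length(x))
}

#' @rdname k_from_image
#' @export
image_from_k <- function(k) {
  k <- if (inherits(k, "kspace_data")) k$values else k
  fftshift2(stats::fft(fftshift2(as.matrix(k)), inverse = TRUE)) / sqrt(length(k))
}

#' Simulate the complex k-space of a phantom
#'
#' Forward model for a (noisy) fully sampled acquisition: the magnitude image
#' is combined with its phase map into a complex image, transformed with the
#' centred orthonormal FFT, and independent complex Gaussian noise with
#' per-channel standard deviation `noise_sigma` is added to every sample.
#' Because the transform is unitary, `noise_sigma` is also the per-channel
#' noise SD in the reconstructed complex image.
#'
#' @param image An [image_volume()] (magnitude) or matrix.
#' @param phase Optional [phase_field()] or matrix of the same shape; `NULL`
#'   means zero phase.
#' @param noise_sigma Per-channel complex Gaussian noise SD (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return A fully sampled [kspace_data()].
#' @export
simulate_kspace <- function(image, phase = NULL, noise_sigma = 0, seed = 1L) {
  mag <- .image_values(image)
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L ||
      !is.finite(noise_sigma) || noise_sigma < 0)
    .stopf("noise_sigma must be a single non-negative number")
  if (!is.null(phase)) {
    ph <- if (inherits(phase, "phase_field")) phase$values else phase
    if (!identical(dim(ph), dim(mag)))
      .stopf("phase map shape (%s) does not match image shape (%s)",
             paste(dim(ph), collapse = "x"), paste(dim(mag), collapse = "x"))
    cplx <- mag * exp(1i * ph)
  } else {
    cplx <- mag + 0i
  }
  k <- k_from_image(cplx)
  if (noise_sigma > 0) {
    n <- length(k)
    eps <- with_seed(seed, complex(real = stats::rnorm(n, 0, noise_sigma),
                                   imaginary = stats::rnorm(n, 0, noise_sigma)))
    k <- k + matrix(eps, nrow(k), ncol(k))
  }
  spacing <- if (inherits(image, "image_volume")) image$pixel_spacing_mm else c(1, 1)
  kspace_data(k, noise_sigma = noise_sigma, seed = as.integer(seed),
              geometry = list(pixel_spacing_mm = spacing))
}
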