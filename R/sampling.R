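# Asymmetric partial-Fourier sampling on the phase-encode axis.
#
# Indexing convention: lines are numbered 0-based in the DC-centred order, so
# DC sits at line floor(N/2) and a fraction f in (1/2, 1] acquires the
# contiguous block of m = round(f * N) lines containing DC and one full
# half-space. The conjugate-symmetric central band {N - m, ..., m - 1} (width
# 2m - N > 0) is what the low-frequency phase estimate is extracted from.
# Which side is truncated is an arbitrary convention ("late" = high-index side
# by default); a flag flips it and reconstructions are mirror-symmetric.

#' Build an asymmetric partial-Fourier sampling scheme
#'
#' @param n_lines Even number of phase-encode lines.
#' @param fraction Acquired fraction in `(1/2, 1]` (default 6/8).
#' @param phase_axis Axis the lines run across: 1 = rows (default), 2 = cols.
#' @param side Which side of k-space is truncated: `"late"` (high-index, the
#'   default) or `"early"`. Results under the two conventions are mirror
#'   images of each other.
#' @return An object of class `sampling_scheme` with fields `n_lines`,
#'   `fraction`, `phase_axis`, `side`, `acquired_indices` (0-based,
#'   DC-centred), `symmetric_band` (0-based), and `transition_width`
#'   (metadata; the merging-filter ramp width used by [merge_filter()] is a
#'   reconstruction parameter).
#' @export
make_pf_mask <- function(n_lines, fraction = 6 / 8, phase_axis = 1L,
                         side = c("late", "early")) {
  side <- match.arg(side)
  if (!.is_count(n_lines) || n_lines < 4 || n_lines %% 2L != 0L)
    .stopf("n_lines must be an even integer >= 4")
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0.5 || fraction > 1)
    .stopf("fraction must lie in (1/2, 1]: below 1/2 no symmetric central band exists and the phase is inestimable")
  if (!phase_axis %in% c(1L, 2L)) .stopf("phase_axis must be 1 or 2")
  n_lines <- as.integer(n_lines)
  m <- as.integer(round(fraction * n_lines))
  if (2L * m - n_lines <= 0L)
    .stopf("fraction %g leaves no symmetric central band for n_lines = %d", fraction, n_lines)
  acquired <- if (side == "late") 0:(m - 1L) else (n_lines - m):(n_lines - 1L)
  band <- (n_lines - m):(m - 1L)
  structure(list(n_lines = n_lines, fraction = fraction,
                 phase_axis = as.integer(phase_axis), side = side,
                 acquired_indices = as.integer(acquired),
                 symmetric_band = as.integer(band),
                 transition_width = 0L),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme> %d lines, fraction %.3f (%d acquired, %s side truncated), band width %d, axis %d\n",
              x$n_lines, x$fraction, length(x$acquired_indices), x$side,
              length(x$symmetric_band), x$phase_axis))
  invisible(x)
}

# 1-based line indices along the scheme's phase axis.
.acquired_lines <- function(scheme) scheme$acquired_indices + 1L
.band_lines <- function(scheme) scheme$symmetric_band + 1L
.unacquired_lines <- function(scheme)
  setdiff(seq_len(scheme$n_lines), .acquired_lines(scheme))

.check_axis <- function(k, scheme) {
  n <- dim(k$values)[scheme$phase_axis]
  if (n != scheme$n_lines)
    .stopf("scheme has %d lines but k-space axis %d has %d",
           scheme$n_lines, scheme$phase_axis, n)
}

# Assign `value` (matrix block or scalar) to the given lines along the axis.
.line_assign <- function(x, lines, value, axis) {
  if (axis == 1L) x[lines, ] <- value else x[, lines] <- value
  x
}

.scheme_mask <- function(scheme, dims) {
  mask <- matrix(FALSE, dims[1L], dims[2L])
  .line_assign(mask, .acquired_lines(scheme), TRUE, scheme$phase_axis)
}

#' Apply a partial-Fourier mask to fully sampled k-space
#'
#' Sets every sample outside the acquired lines to exactly zero and records
#' the mask; acquired samples are bit-identical to the input. Idempotent.
#'
#' @param k A [kspace_data()].
#' @param scheme A [make_pf_mask()] scheme matching the phase axis length.
#' @return A masked [kspace_data()] carrying the scheme.
#' @export
apply_mask <- function(k, scheme) {
  if (!inherits(k, "kspace_data")) .stopf("k must be kspace_data")
  if (!inherits(scheme, "sampling_scheme")) .stopf("scheme must be a sampling_scheme")
  .check_axis(k, scheme)
  vals <- .line_assign(k$values, .unacquired_lines(scheme), 0 + 0i, scheme$phase_axis)
  kspace_data(vals, mask = .scheme_mask(scheme, dim(vals)),
              noise_sigma = k$noise_sigma, seed = k$seed,
              geometry = k$geometry, scheme = scheme)
}

#' Treat masked k-space as complete (zero-filling)
#'
#' The zero-filled protocol simply keeps the zeros stored on the unacquired
#' lines and reconstructs as if the data were complete. This is an explicit
#' no-op on the stored values: only the mask is cleared, which documents the
#' semantics of the zero-filled protocol (P2/C2).
#'
#' @param k_masked A masked [kspace_data()].
#' @return A [kspace_data()] with an all-true mask and unchanged values.
#' @export
zero_fill <- function(k_masked) {
  if (!inherits(k_masked, "kspace_data")) .stopf("k must be kspace_data")
  kspace_data(k_masked$values, mask = NULL, noise_sigma = k_masked$noise_sigma,
              seed = k_masked$seed, geometry = k_masked$geometry,
              scheme = k_masked$scheme)
}

#' Serialise / restore a sampling scheme as JSON
#'
#' @param scheme A [make_pf_mask()] scheme.
#' @param path File path; `scheme_to_json()` writes, `scheme_from_json()` reads.
#' @return `scheme_from_json()` returns the restored `sampling_scheme`.
#' @export
scheme_to_json <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scheme_to_json
#' @export
scheme_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_pf_mask(x$n_lines, x$fraction, x$phase_axis, x$side)
}
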