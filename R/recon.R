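# The three reconstruction protocols: full inverse FFT (P1/C1), zero-filled
# partial Fourier (P2/C2) and the iterative phase-constrained POCS
# reconstruction (P3/C3).
#
# POCS alternates projections between two convex sets of images: those whose
# k-space agrees with the measured lines, and those whose phase equals the
# low-frequency phase estimate extracted from the symmetric central band. The
# final iteration replaces the hard data-consistency substitution with a
# merging filter that ramps between measured and estimated k-space across the
# truncation edge.

#' POCS reconstruction configuration
#'
#' @param n_iterations Number of projection/consistency passes (default 2,
#'   the scanner's stated iteration count; the final pass ends in the merging
#'   filter).
#' @param phase_window Window applied across the symmetric central band when
#'   estimating the low-frequency phase: `"hann"` (default, suppresses Gibbs
#'   ringing in the estimate) or `"rectangular"`.
#' @param merge_ramp_lines Width in lines of the merging-filter ramp
#'   (default 8; 0 gives the hard data-consistency switch).
#' @param convergence_tol Optional early-stop tolerance on the relative image
#'   change between passes; `NULL` (default) runs exactly `n_iterations`.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 2L,
                         phase_window = c("hann", "rectangular"),
                         merge_ramp_lines = 8L,
                         convergence_tol = NULL) {
  phase_window <- match.arg(phase_window)
  if (!.is_count(n_iterations) || n_iterations < 1)
    .stopf("n_iterations must be a positive integer")
  if (!.is_count(merge_ramp_lines))
    .stopf("merge_ramp_lines must be a non-negative integer")
  if (!is.null(convergence_tol) &&
      (!is.numeric(convergence_tol) || convergence_tol <= 0))
    .stopf("convergence_tol must be NULL or a positive number")
  structure(list(n_iterations = as.integer(n_iterations),
                 phase_window = phase_window,
                 merge_ramp_lines = as.integer(merge_ramp_lines),
                 convergence_tol = convergence_tol),
            class = "recon_config")
}

.geom_spacing <- function(k)
  (k$geometry$pixel_spacing_mm %||% c(1, 1))

#' Full (conventional) reconstruction
#'
#' Magnitude of the centred orthonormal inverse Fourier transform of fully
#' sampled k-space. Refuses masked input: partial-Fourier data go through
#' [recon_zerofill()] or [recon_pocs()].
#'
#' @param k A fully sampled [kspace_data()].
#' @return A magnitude [image_volume()].
#' @export
recon_full <- function(k) {
  if (!inherits(k, "kspace_data")) .stopf("k must be kspace_data")
  if (any(!k$mask))
    .stopf("recon_full() requires fully sampled k-space; use recon_zerofill() or recon_pocs() for partial-Fourier data")
  image_volume(Mod(image_from_k(k$values)), .geom_spacing(k), label = "full")
}

#' Zero-filled partial-Fourier reconstruction
#'
#' Magnitude of the inverse transform of the masked data with the unacquired
#' lines left at zero. The truncation acts as an asymmetric low-pass filter
#' along the phase axis, which blurs edges relative to [recon_full()].
#'
#' @param k_masked A masked (or already zero-filled) [kspace_data()].
#' @return A magnitude [image_volume()].
#' @export
recon_zerofill <- function(k_masked) {
  if (!inherits(k_masked, "kspace_data")) .stopf("k must be kspace_data")
  image_volume(Mod(image_from_k(k_masked$values)), .geom_spacing(k_masked),
               label = "zerofill")
}

#' Low-frequency phase estimate from the symmetric central band
#'
#' The acquired samples inside the conjugate-symmetric central band are
#' windowed along the phase axis (the rest of k-space set to zero, i.e. the
#' central zone extended by zero filling), inverse transformed to a
#' low-resolution image, and the pixelwise argument is taken as the phase
#' estimate.
#'
#' The window is symmetric about the DC line. On the even grid the stored
#' band has one line more on the low-frequency side than on the high side;
#' that unpaired extreme line is given zero weight, because any asymmetric
#' weighting would make the windowed data of a real-valued object
#' non-Hermitian and so leak a spurious phase into the estimate.
#'
#' @param k_masked Masked [kspace_data()].
#' @param scheme The [make_pf_mask()] scheme (defaults to the one carried by
#'   `k_masked`).
#' @param window `"hann"` or `"rectangular"` window over the band.
#' @return A [phase_field()] with provenance `"low_frequency_estimate"`.
#' @export
estimate_phase <- function(k_masked, scheme = NULL,
                           window = c("hann", "rectangular")) {
  window <- match.arg(window)
  scheme <- scheme %||% k_masked$scheme
  if (is.null(scheme)) .stopf("no sampling scheme supplied or carried by k")
  .check_axis(k_masked, scheme)
  n <- scheme$n_lines
  band <- .band_lines(scheme)
  if (length(band) < 2L) .stopf("symmetric central band is empty; phase inestimable")
  dc <- n %/% 2L + 1L                       # 1-based DC line
  half <- min(dc - min(band), max(band) - dc)
  lines <- (dc - half):(dc + half)          # DC-symmetric sub-band
  d <- lines - dc
  w <- if (window == "hann" && half > 0L)
    0.5 * (1 + cos(pi * d / (half + 1L))) else rep(1, length(lines))
  kc <- matrix(0 + 0i, nrow(k_masked$values), ncol(k_masked$values))
  if (scheme$phase_axis == 1L) {
    kc[lines, ] <- k_masked$values[lines, ] * w
  } else {
    kc[, lines] <- sweep(k_masked$values[, lines, drop = FALSE], 2L, w, `*`)
  }
  phase_field(Arg(image_from_k(kc)), "low_frequency_estimate")
}

#' Project a complex image onto the phase-estimate line
#'
#' Pixelwise geometric projection of the complex value onto the line through
#' the origin at angle `phase_hat`:
#' `rho_corrected = Re(rho * exp(-i * phi_hat)) * exp(i * phi_hat)`.
#' The output phase equals `phi_hat` (or `phi_hat + pi` where the projection
#' is negative) and the operation is idempotent — it is the orthogonal
#' projection onto a convex set.
#'
#' @param img Complex [image_volume()] or matrix.
#' @param phase_hat A [phase_field()] or matrix of matching shape.
#' @return A complex matrix (or [image_volume()] if one was supplied).
#' @export
project_phase <- function(img, phase_hat) {
  vals <- .image_values(img)
  ph <- if (inherits(phase_hat, "phase_field")) phase_hat$values else phase_hat
  if (!identical(dim(ph), dim(vals)))
    .stopf("phase map shape does not match image shape")
  out <- Re(vals * exp(-1i * ph)) * exp(1i * ph)
  if (inherits(img, "image_volume")) {
    img$values <- out
    img
  } else out
}

# Hermitian mirror of a DC-centred matrix: H[r, c] = Conj(K[-r, -c]) with
# frequency negation in the centred convention (DC and Nyquist lines are
# self-mirrored).
.conj_mirror <- function(values) {
  Conj(values[.mirror_index(nrow(values)), .mirror_index(ncol(values))])
}

# Initial estimate of the full k-space: acquired lines as measured, missing
# lines filled by conjugate symmetry of the acquired data (exact for
# real-valued objects; the phase projection iterations correct the rest).
.conj_fill <- function(values, scheme) {
  miss <- .unacquired_lines(scheme)
  if (length(miss) == 0L) return(values)
  h <- .conj_mirror(values)
  if (scheme$phase_axis == 1L) values[miss, ] <- h[miss, ]
  else values[, miss] <- h[, miss]
  values
}

#' Data-consistency projection in k-space
#'
#' Replaces the estimate with the measured data on every acquired line and
#' keeps the estimate on the unacquired lines. Idempotent for a fixed
#' estimate off the mask.
#'
#' @param k_corrected Estimated full k-space ([kspace_data()] or complex
#'   matrix).
#' @param k0 The measured masked [kspace_data()] carrying the mask.
#' @param scheme The sampling scheme (defaults to the one carried by `k0`).
#' @return A complex matrix: measured on acquired lines, estimate elsewhere.
#' @export
data_consistency <- function(k_corrected, k0, scheme = NULL) {
  kc <- if (inherits(k_corrected, "kspace_data")) k_corrected$values else k_corrected
  scheme <- scheme %||% k0$scheme
  if (is.null(scheme)) .stopf("no sampling scheme supplied or carried by k0")
  if (!identical(dim(kc), dim(k0$values)))
    .stopf("estimate and measured k-space shapes differ")
  .check_axis(k0, scheme)
  acq <- .acquired_lines(scheme)
  if (scheme$phase_axis == 1L) kc[acq, ] <- k0$values[acq, ]
  else kc[, acq] <- k0$values[, acq]
  kc
}

# Per-line merging weights: 1 deep inside the acquired block, 0 on every
# unacquired line, and a linear ramp of `ramp_lines` lines centred on the
# truncation edge (its acquired half; the unacquired half is clipped to 0 so
# the estimate, not the stored zeros, fills the missing data).
.merge_weights <- function(scheme, ramp_lines) {
  n <- scheme$n_lines
  m <- length(scheme$acquired_indices)
  w <- rep(0, n)
  acq <- .acquired_lines(scheme)
  if (m == n) { w[] <- 1; return(w) }
  if (ramp_lines == 0) { w[acq] <- 1; return(w) }
  if (ceiling(ramp_lines / 2) >= m)
    .stopf("merge ramp (%d lines) is wider than the acquired block (%d lines)",
           ramp_lines, m)
  r <- seq_len(n)
  edge <- if (scheme$side == "late") m + 0.5 else (n - m) + 0.5
  dist_inside <- if (scheme$side == "late") edge - r else r - edge
  wr <- pmin(1, pmax(0, 0.5 + dist_inside / ramp_lines))
  w[acq] <- wr[acq]
  w
}

#' Merging filter for the final POCS pass
#'
#' Blends measured and estimated k-space line by line:
#' `out = w * K0 + (1 - w) * K_corrected`, with `w = 1` deep inside the
#' acquired block, `w = 0` on every unacquired line, and a linear ramp of
#' `ramp_lines` lines centred at the truncation edge. The two weights sum to
#' one on every line; `ramp_lines = 0` reduces to [data_consistency()].
#'
#' @inheritParams data_consistency
#' @param ramp_lines Ramp width in lines.
#' @return A complex matrix.
#' @export
merge_filter <- function(k_corrected, k0, scheme = NULL, ramp_lines = 8L) {
  kc <- if (inherits(k_corrected, "kspace_data")) k_corrected$values else k_corrected
  scheme <- scheme %||% k0$scheme
  if (is.null(scheme)) .stopf("no sampling scheme supplied or carried by k0")
  if (!identical(dim(kc), dim(k0$values)))
    .stopf("estimate and measured k-space shapes differ")
  .check_axis(k0, scheme)
  w <- .merge_weights(scheme, ramp_lines)
  if (scheme$phase_axis == 1L) w * k0$values + (1 - w) * kc
  else sweep(k0$values, 2L, w, `*`) + sweep(kc, 2L, 1 - w, `*`)
}

#' POCS partial-Fourier reconstruction
#'
#' Runs the iterative phase-constrained reconstruction:
#' \enumerate{
#'   \item estimate the low-frequency phase from the windowed symmetric
#'     central band;
#'   \item form the initial full-k-space estimate from the measured data
#'     (unacquired lines filled by conjugate symmetry);
#'   \item repeat `n_iterations` times: inverse transform, project onto the
#'     phase-estimate line, forward transform, then restore the measured
#'     lines — by hard substitution ([data_consistency()]) on every pass but
#'     the last, which uses the [merge_filter()].
#' }
#' With a full sampling scheme there is nothing to estimate and the result
#' equals [recon_full()].
#'
#' @param k_masked Masked [kspace_data()].
#' @param scheme Sampling scheme (defaults to the one carried by `k_masked`).
#' @param config A [recon_config()].
#' @return A list with `image` (magnitude [image_volume()]) and `state`, the
#'   per-iteration trace: `K0`, `K0_central`, `I0_lowres`, `phase_hat`, and
#'   one entry per pass with `K_est` (after consistency/merge), `I_est`,
#'   `I_corrected`, `K_corrected`.
#' @export
recon_pocs <- function(k_masked, scheme = NULL, config = recon_config()) {
  if (!inherits(k_masked, "kspace_data")) .stopf("k must be kspace_data")
  scheme <- scheme %||% k_masked$scheme
  if (is.null(scheme)) .stopf("no sampling scheme supplied or carried by k")
  if (!inherits(config, "recon_config")) .stopf("config must be a recon_config")
  .check_axis(k_masked, scheme)

  phase_hat <- estimate_phase(k_masked, scheme, config$phase_window)
  band <- .band_lines(scheme)
  k0_central <- matrix(0 + 0i, nrow(k_masked$values), ncol(k_masked$values))
  if (scheme$phase_axis == 1L) k0_central[band, ] <- k_masked$values[band, ]
  else k0_central[, band] <- k_masked$values[, band]
  i0_lowres <- image_from_k(k0_central)

  k_est <- .conj_fill(k_masked$values, scheme)
  n_it <- config$n_iterations
  iterations <- vector("list", n_it)
  prev_mag <- NULL
  for (i in seq_len(n_it)) {
    i_est <- image_from_k(k_est)
    i_corr <- project_phase(i_est, phase_hat)
    k_corr <- k_from_image(i_corr)
    final <- i == n_it
    if (!is.null(config$convergence_tol) && !final && !is.null(prev_mag)) {
      rel <- sqrt(sum(Mod(i_est - prev_mag)^2)) /
        max(sqrt(sum(Mod(prev_mag)^2)), .Machine$double.eps)
      if (rel < config$convergence_tol) final <- TRUE
    }
    k_est <- if (final)
      merge_filter(k_corr, k_masked, scheme, config$merge_ramp_lines)
    else
      data_consistency(k_corr, k_masked, scheme)
    iterations[[i]] <- list(iteration = i, K_est = k_est, I_est = i_est,
                            I_corrected = i_corr, K_corrected = k_corr,
                            final = final)
    prev_mag <- i_est
    if (final) { iterations <- iterations[seq_len(i)]; break }
  }
  state <- structure(list(K0 = k_masked, K0_central = k0_central,
                          I0_lowres = i0_lowres, phase_hat = phase_hat,
                          scheme = scheme, config = config,
                          iterations = iterations),
                     class = "pocs_state")
  img <- image_volume(Mod(image_from_k(k_est)), .geom_spacing(k_masked),
                      label = "pocs")
  list(image = img, state = state)
}

#' @export
print.pocs_state <- function(x, ...) {
  cat(sprintf("<pocs_state> %d iteration(s), window=%s, ramp=%d lines\n",
              length(x$iterations), x$config$phase_window,
              x$config$merge_ramp_lines))
  invisible(x)
}
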