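# Digital phantoms standing in for scanner acquisitions: a resolution phantom
# (grid of high-contrast rods of graded radius on a uniform background) and
# liver-like volumes (parenchyma disc, bright tubular vessels, smooth phase).
# All structures are rendered with anti-aliased edges by pixel-centre sampling
# of a 4x supersampled coverage mask, so sub-pixel edge positions are
# reproducible and blur is measurable.

.SUPERSAMPLE <- 4L

# Fractional pixel coverage of a disc, computed on a supersampled subgrid and
# accumulated only over the disc's bounding box. `img` is modified in place
# semantics-wise (returned).
.add_disc_coverage <- function(cov, cy, cx, radius) {
  nr <- nrow(cov); nc <- ncol(cov)
  s <- .SUPERSAMPLE
  r0 <- max(1L, floor(cy - radius - 1)); r1 <- min(nr, ceiling(cy + radius + 1))
  c0 <- max(1L, floor(cx - radius - 1)); c1 <- min(nc, ceiling(cx + radius + 1))
  if (r0 > r1 || c0 > c1) return(cov)
  off <- (seq_len(s) - 0.5) / s - 0.5      # subsample offsets within a pixel
  ys <- as.vector(outer(r0:r1, off, `+`))  # supersampled row coordinates
  xs <- as.vector(outer(c0:c1, off, `+`))
  inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= radius^2
  # collapse the s x s subsamples of each pixel
  dim(inside) <- c(r1 - r0 + 1L, s, c1 - c0 + 1L, s)
  frac <- apply(inside, c(1L, 3L), mean)
  cov[r0:r1, c0:c1] <- pmin(1, cov[r0:r1, c0:c1] + frac)
  cov
}

# Coverage of a tube: all points within `radius` of the segment (y0,x0)-(y1,x1).
.add_tube_coverage <- function(cov, y0, x0, y1, x1, radius) {
  nr <- nrow(cov); nc <- ncol(cov)
  s <- .SUPERSAMPLE
  r0 <- max(1L, floor(min(y0, y1) - radius - 1))
  r1 <- min(nr, ceiling(max(y0, y1) + radius + 1))
  c0 <- max(1L, floor(min(x0, x1) - radius - 1))
  c1 <- min(nc, ceiling(max(x0, x1) + radius + 1))
  if (r0 > r1 || c0 > c1) return(cov)
  off <- (seq_len(s) - 0.5) / s - 0.5
  ys <- as.vector(outer(r0:r1, off, `+`))
  xs <- as.vector(outer(c0:c1, off, `+`))
  dy <- y1 - y0; dx <- x1 - x0
  len2 <- dy^2 + dx^2
  py <- matrix(ys, length(ys), length(xs))
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  tt <- if (len2 == 0) matrix(0, nrow(py), ncol(py)) else
    pmin(1, pmax(0, ((py - y0) * dy + (px - x0) * dx) / len2))
  d2 <- (py - (y0 + tt * dy))^2 + (px - (x0 + tt * dx))^2
  inside <- d2 <= radius^2
  dim(inside) <- c(r1 - r0 + 1L, s, c1 - c0 + 1L, s)
  frac <- apply(inside, c(1L, 3L), mean)
  cov[r0:r1, c0:c1] <- pmax(cov[r0:r1, c0:c1], frac)
  cov
}

#' Resolution-phantom specification
#'
#' Defines the digital analogue of a scanner resolution phantom: rods
#' (columns) of graded radius on a uniform background, including one
#' peripheral rod near the edge of the field of view. The default geometry
#' mirrors the acquisition protocol emulated throughout the package:
#' 144 phase-encode lines by 256 readout samples over a 263 x 350 mm field of
#' view.
#'
#' @param matrix_rows,matrix_cols Even positive integers: phase-encode lines
#'   (rows) and readout samples (columns).
#' @param pixel_spacing_mm (row, column) pixel spacing in mm.
#' @param column_radii_px Graded rod radii in pixels; each radius is rendered
#'   as a vertical triplet of rods. May be empty (uniform phantom).
#' @param column_intensity,background_intensity Non-negative intensities.
#' @param peripheral_radius_px Radius of the extra rod placed near the edge of
#'   the field of view (the "peripheral column" used by the subtraction
#'   analysis).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_rows = 144L, matrix_cols = 256L,
                         pixel_spacing_mm = c(263 / 144, 350 / 256),
                         column_radii_px = c(1.5, 2, 3, 4, 6),
                         column_intensity = 1,
                         background_intensity = 0.3,
                         peripheral_radius_px = 3) {
  if (!.is_count(matrix_rows) || !.is_count(matrix_cols) ||
      matrix_rows %% 2L != 0L || matrix_cols %% 2L != 0L ||
      matrix_rows < 8 || matrix_cols < 8)
    .stopf("matrix dimensions must be even integers >= 8")
  if (length(column_radii_px) > 0 &&
      (any(!is.finite(column_radii_px)) || any(column_radii_px <= 0)))
    .stopf("column_radii_px must be positive")
  if (!is.finite(column_intensity) || column_intensity < 0 ||
      !is.finite(background_intensity) || background_intensity < 0)
    .stopf("intensities must be finite and >= 0")
  structure(list(matrix_rows = as.integer(matrix_rows),
                 matrix_cols = as.integer(matrix_cols),
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 column_radii_px = as.numeric(column_radii_px),
                 column_intensity = column_intensity,
                 background_intensity = background_intensity,
                 peripheral_radius_px = peripheral_radius_px),
            class = "phantom_spec")
}

# Documented rod layout: radius group j is a vertical triplet centred at
# columns spread across the left 3/4 of the FOV; one extra peripheral rod of
# radius `peripheral_radius_px` sits near the right edge at mid-height.
.phantom_rod_table <- function(spec) {
  nr <- spec$matrix_rows; nc <- spec$matrix_cols
  radii <- spec$column_radii_px
  if (length(radii) == 0L && is.na(spec$peripheral_radius_px)) {
    return(data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  rows <- nr * c(1 / 3, 1 / 2, 2 / 3)
  tabs <- lapply(seq_along(radii), function(j) {
    colx <- nc * (0.12 + 0.14 * (j - 1))
    data.frame(row = rows, col = colx, radius = radii[j],
               label = sprintf("rod_r%g_%d", radii[j], seq_along(rows)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (!is.na(spec$peripheral_radius_px)) {
    tab <- rbind(tab, data.frame(
      row = nr / 2, col = nc - 12, radius = spec$peripheral_radius_px,
      label = "peripheral_column", stringsAsFactors = FALSE))
  }
  tab
}

#' Render the resolution phantom
#'
#' Deterministically renders the rods of a [phantom_spec()] onto the uniform
#' background with anti-aliased (4x supersampled) edges. The rod layout is
#' returned in the `rods` field so that ROIs can be placed programmatically;
#' it always includes a rod labelled `"peripheral_column"` near the edge of
#' the field of view unless the spec has no rods at all.
#'
#' @param spec A [phantom_spec()].
#' @return An [image_volume()] with an extra `rods` data frame
#'   (`row`, `col`, `radius`, `label`).
#' @export
make_resolution_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) .stopf("spec must be a phantom_spec")
  nr <- spec$matrix_rows; nc <- spec$matrix_cols
  rods <- .phantom_rod_table(spec)
  if (nrow(rods) > 0) {
    bad <- rods$row - rods$radius < 0.5 | rods$row + rods$radius > nr + 0.5 |
      rods$col - rods$radius < 0.5 | rods$col + rods$radius > nc + 0.5
    if (any(bad))
      .stopf("rod(s) %s extend outside the field of view",
             paste(rods$label[bad], collapse = ", "))
  }
  img <- matrix(spec$background_intensity, nr, nc)
  if (nrow(rods) > 0) {
    cov <- matrix(0, nr, nc)
    for (i in seq_len(nrow(rods)))
      cov <- .add_disc_coverage(cov, rods$row[i], rods$col[i], rods$radius[i])
    img <- img + (spec$column_intensity - spec$background_intensity) * cov
  }
  out <- image_volume(img, spec$pixel_spacing_mm, is_ground_truth = TRUE,
                      label = "resolution_phantom")
  out$rods <- rods
  out
}

#' Liver-like phantom specification
#'
#' Defines the synthetic stand-in for a hepatobiliary-phase liver slice:
#' a uniform parenchyma disc, bright tubular vessels of varying calibre, a
#' smooth (band-limited) spatial phase and complex Gaussian noise. Defaults
#' are chosen so that the conventional fully sampled reconstruction operates
#' at a parenchyma SNR of about 13, with vessel calibres of 4-10 px
#' (roughly 6-15 mm at the default spacing) and a phase map whose spatial
#' frequencies lie far inside the symmetric central band of the default 6/8
#' sampling scheme, so the slowly-varying-phase assumption of the POCS
#' reconstruction holds by construction.
#'
#' @inheritParams phantom_spec
#' @param parenchyma_intensity Parenchyma magnitude (> 0).
#' @param n_vessels Number of vessels (>= 0).
#' @param vessel_radius_range_px Interval of vessel radii in pixels.
#' @param vessel_contrast Vessel minus parenchyma intensity.
#' @param phase_amplitude_rad Peak of the smooth phase map (>= 0, <= pi).
#' @param phase_smoothness_px Minimum period (px) of the phase cosine modes.
#' @param noise_sigma Per-channel complex Gaussian k-space noise SD.
#' @param seed Integer seed making generation a pure function of the spec.
#' @return An object of class `liver_phantom_spec`.
#' @export
liver_phantom_spec <- function(matrix_rows = 144L, matrix_cols = 256L,
                               pixel_spacing_mm = c(263 / 144, 350 / 256),
                               parenchyma_intensity = 1,
                               n_vessels = 12L,
                               vessel_radius_range_px = c(2, 5),
                               vessel_contrast = 0.8,
                               phase_amplitude_rad = 0.5,
                               phase_smoothness_px = 32,
                               noise_sigma = 0.075,
                               seed = 1L) {
  if (!.is_count(matrix_rows) || !.is_count(matrix_cols) ||
      matrix_rows %% 2L != 0L || matrix_cols %% 2L != 0L)
    .stopf("matrix dimensions must be even integers")
  if (!is.finite(parenchyma_intensity) || parenchyma_intensity <= 0)
    .stopf("parenchyma_intensity must be > 0")
  if (!.is_count(n_vessels)) .stopf("n_vessels must be a non-negative integer")
  if (n_vessels > 0 && (length(vessel_radius_range_px) != 2L ||
                        any(!is.finite(vessel_radius_range_px)) ||
                        any(vessel_radius_range_px <= 0) ||
                        diff(vessel_radius_range_px) < 0))
    .stopf("n_vessels > 0 requires a non-empty positive vessel_radius_range_px")
  if (!is.finite(phase_amplitude_rad) || phase_amplitude_rad < 0 ||
      phase_amplitude_rad > pi)
    .stopf("phase_amplitude_rad must be in [0, pi]")
  if (!is.finite(phase_smoothness_px) || phase_smoothness_px <= 0)
    .stopf("phase_smoothness_px must be positive")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    .stopf("noise_sigma must be >= 0")
  structure(list(matrix_rows = as.integer(matrix_rows),
                 matrix_cols = as.integer(matrix_cols),
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 parenchyma_intensity = parenchyma_intensity,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_range_px = as.numeric(vessel_radius_range_px),
                 vessel_contrast = vessel_contrast,
                 phase_amplitude_rad = phase_amplitude_rad,
                 phase_smoothness_px = phase_smoothness_px,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "liver_phantom_spec")
}

# Smooth phase surface: sum of <= 3 cosine modes whose frequencies are whole
# numbers of cycles per field of view (so the map is exactly band-limited,
# with no spectral leakage) and whose periods are >= the smoothness scale;
# rescaled so the peak equals phase_amplitude_rad. Drawn from the current
# RNG stream.
.draw_phase_field <- function(nr, nc, amplitude, smoothness) {
  if (amplitude == 0) return(matrix(0, nr, nc))
  fy_max <- max(1L, floor(nr / smoothness))
  fx_max <- max(1L, floor(nc / smoothness))
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  phi <- matrix(0, nr, nc)
  for (m in seq_len(3L)) {
    repeat {
      fy <- sample(-fy_max:fy_max, 1L)
      fx <- sample(-fx_max:fx_max, 1L)
      if (fy != 0L || fx != 0L) break
    }
    amp <- stats::runif(1, 0.5, 1)
    shift <- stats::runif(1, 0, 2 * pi)
    phi <- phi + amp * cos(2 * pi * (fy * yy / nr + fx * xx / nc) + shift)
  }
  phi * (amplitude / max(abs(phi)))
}

#' Generate a liver-like phantom and its ground-truth phase
#'
#' Renders the parenchyma disc and randomly placed straight tubular vessels
#' (anti-aliased), draws the smooth ground-truth phase map, and records the
#' vessel geometry so that wall ROIs and vessel-avoiding parenchyma ROIs can
#' be placed deterministically. Same seed, same output.
#'
#' @param spec A [liver_phantom_spec()].
#' @return A list with elements `image` (an [image_volume()] carrying extra
#'   fields `vessels` — a data frame `y0,x0,y1,x1,radius` — and `support` —
#'   the parenchyma disc `(row, col, radius)`) and `phase`
#'   (a [phase_field()], provenance `"ground_truth"`).
#' @export
make_liver_phantom <- function(spec = liver_phantom_spec()) {
  if (!inherits(spec, "liver_phantom_spec"))
    .stopf("spec must be a liver_phantom_spec")
  nr <- spec$matrix_rows; nc <- spec$matrix_cols
  sup_r <- 0.42 * min(nr, nc)
  sup_c <- c(nr / 2 + 0.5, nc / 2 + 0.5)
  with_seed(spec$seed, {
    cov_par <- .add_disc_coverage(matrix(0, nr, nc), sup_c[1], sup_c[2], sup_r)
    vessels <- data.frame(y0 = numeric(0), x0 = numeric(0), y1 = numeric(0),
                          x1 = numeric(0), radius = numeric(0))
    cov_ves <- matrix(0, nr, nc)
    if (spec$n_vessels > 0) {
      for (v in seq_len(spec$n_vessels)) {
        for (try in 1:50) {
          rad <- stats::runif(1, spec$vessel_radius_range_px[1],
                              spec$vessel_radius_range_px[2])
          rho <- sup_r * 0.65 * sqrt(stats::runif(1))
          ang <- stats::runif(1, 0, 2 * pi)
          cy <- sup_c[1] + rho * sin(ang); cx <- sup_c[2] + rho * cos(ang)
          dir <- stats::runif(1, 0, pi)
          hl <- stats::runif(1, 0.15, 0.4) * sup_r   # half-length in px
          y0 <- cy - hl * sin(dir); y1 <- cy + hl * sin(dir)
          x0 <- cx - hl * cos(dir); x1 <- cx + hl * cos(dir)
          # centreline (with the tube radius) must stay inside the parenchyma
          lim <- sup_r - rad - 2
          ok <- (y0 - sup_c[1])^2 + (x0 - sup_c[2])^2 <= lim^2 &&
                (y1 - sup_c[1])^2 + (x1 - sup_c[2])^2 <= lim^2
          if (ok) break
        }
        if (!ok) .stopf("could not place vessel %d inside the parenchyma", v)
        vessels[nrow(vessels) + 1L, ] <- c(y0, x0, y1, x1, rad)
        cov_ves <- .add_tube_coverage(cov_ves, y0, x0, y1, x1, rad)
      }
    }
    img <- spec$parenchyma_intensity * cov_par +
      spec$vessel_contrast * pmin(cov_ves, cov_par)
    phi <- .draw_phase_field(nr, nc, spec$phase_amplitude_rad,
                             spec$phase_smoothness_px)
    out <- image_volume(img, spec$pixel_spacing_mm, is_ground_truth = TRUE,
                        label = "liver_phantom")
    out$vessels <- vessels
    out$support <- list(row = sup_c[1], col = sup_c[2], radius = sup_r)
    list(image = out, phase = phase_field(phi, "ground_truth"))
  })
}

#' Vessel-wall sample points for sharpness ROIs
#'
#' Returns, for each vessel, the two wall midpoints (centreline midpoint
#' offset by the vessel radius along the tube normal) together with the wall
#' normal direction. Optionally keeps only walls whose normal has a
#' substantial phase-encode (row) component, which is where partial-Fourier
#' blur along the phase axis can manifest.
#'
#' @param phantom The `image` element returned by [make_liver_phantom()].
#' @param min_normal_row Minimum `|row component|` of the unit wall normal for
#'   a point to be kept (0 keeps all walls).
#' @return Data frame with columns `row`, `col`, `ny`, `nx`, `vessel`.
#' @export
vessel_edge_points <- function(phantom, min_normal_row = 0.6) {
  ves <- phantom$vessels
  if (is.null(ves) || nrow(ves) == 0L)
    .stopf("phantom carries no vessel geometry")
  mid_y <- (ves$y0 + ves$y1) / 2
  mid_x <- (ves$x0 + ves$x1) / 2
  dy <- ves$y1 - ves$y0; dx <- ves$x1 - ves$x0
  len <- sqrt(dy^2 + dx^2)
  ny <- dx / len; nx <- -dy / len            # unit normal to the centreline
  pts <- rbind(
    data.frame(row = mid_y + ves$radius * ny, col = mid_x + ves$radius * nx,
               ny = ny, nx = nx, vessel = seq_len(nrow(ves))),
    data.frame(row = mid_y - ves$radius * ny, col = mid_x - ves$radius * nx,
               ny = -ny, nx = -nx, vessel = seq_len(nrow(ves))))
  pts[abs(pts$ny) >= min_normal_row, , drop = FALSE]
}

#' Generate a cohort of liver phantoms
#'
#' Derives one reproducible seed per subject from the master seed and applies
#' subject-level jitter to the vessel count (+/- 2 vessels) and vessel
#' contrast (+/- 10%), emulating anatomical variation across patients. Each
#' subject's ground truth is rendered once and a nominal fully sampled noisy
#' acquisition is simulated from it.
#'
#' @param n_subjects Number of subjects (default 55).
#' @param base_spec A [liver_phantom_spec()] giving the cohort-level defaults.
#' @param master_seed Integer master seed.
#' @return A list of length `n_subjects`; each element has `image`, `phase`,
#'   `kspace`, `spec` and `subject_seed`.
#' @export
make_cohort <- function(n_subjects = 55L, base_spec = liver_phantom_spec(),
                        master_seed = 1L) {
  if (!.is_count(n_subjects)) .stopf("n_subjects must be a non-negative integer")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects == 0L) return(list())
  seeds <- .derive_seeds(master_seed, 2L * n_subjects)
  subj_seeds <- seeds[seq_len(n_subjects)]
  noise_seeds <- seeds[n_subjects + seq_len(n_subjects)]
  lapply(seq_len(n_subjects), function(i) {
    jit <- with_seed(subj_seeds[i], list(
      dn = sample(-2:2, 1L),
      cmul = stats::runif(1, 0.9, 1.1)))
    spec_i <- base_spec
    spec_i$n_vessels <- max(1L, base_spec$n_vessels + jit$dn)
    spec_i$vessel_contrast <- base_spec$vessel_contrast * jit$cmul
    spec_i$seed <- subj_seeds[i]
    ph <- make_liver_phantom(spec_i)
    k <- simulate_kspace(ph$image, ph$phase, spec_i$noise_sigma, noise_seeds[i])
    list(image = ph$image, phase = ph$phase, kspace = k,
         spec = spec_i, subject_seed = subj_seeds[i])
  })
}
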