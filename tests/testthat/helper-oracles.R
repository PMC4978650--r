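# Shared fixtures (generated in code) and independent oracles.

rel_rmse <- function(a, b) {
  va <- if (is.list(a)) a$values else a
  vb <- if (is.list(b)) b$values else b
  sqrt(mean(Mod(va - vb)^2)) / sqrt(mean(Mod(vb)^2))
}

# Small geometries keep the per-test transforms cheap.
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(matrix_rows = 48L, matrix_cols = 64L,
         column_radii_px = c(1.5, 2.5), peripheral_radius_px = 2),
    list(...))
  do.call(phantom_spec, args)
}

small_liver_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(matrix_rows = 64L, matrix_cols = 64L, n_vessels = 5L,
         vessel_radius_range_px = c(1.5, 3),
         phase_smoothness_px = 16, seed = seed),
    list(...))
  do.call(liver_phantom_spec, args)
}

# Independent brute-force reconstruction for real-valued objects: fill every
# missing line by explicit conjugate symmetry K(-k) = conj(K(k)), element by
# element in centred frequency coordinates, then magnitude-reconstruct.
hermitian_recon_oracle <- function(k_masked, scheme) {
  stopifnot(scheme$phase_axis == 1L)
  v <- k_masked$values
  n <- nrow(v); m <- ncol(v)
  miss0 <- setdiff(0:(n - 1L), scheme$acquired_indices)
  out <- v
  for (i0 in miss0) {
    for (j0 in 0:(m - 1L)) {
      fi <- i0 - n / 2; fj <- j0 - m / 2   # frequency of centred index
      mi <- -fi; mj <- -fj
      if (mi == n / 2) mi <- -n / 2        # Nyquist aliases to itself
      if (mj == m / 2) mj <- -m / 2
      out[i0 + 1L, j0 + 1L] <- Conj(v[mi + n / 2 + 1L, mj + m / 2 + 1L])
    }
  }
  Mod(image_from_k(out))
}

# Enumeration oracle: pixel count of a circle by scanning every pixel centre.
circle_pixel_count_oracle <- function(dims, cy, cx, r) {
  cnt <- 0L
  for (i in seq_len(dims[1L]))
    for (j in seq_len(dims[2L]))
      if ((i - cy)^2 + (j - cx)^2 <= r^2) cnt <- cnt + 1L
  cnt
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# Monte-Carlo permutation p for the Friedman statistic: permute each row's
# observed values independently and compare tie-corrected statistics.
friedman_mc_oracle <- function(x, nrep = 1e5, seed = 1) {
  stat_of <- function(m) {
    rk <- t(apply(m, 1L, rank))
    rj <- colSums(rk)
    n <- nrow(m); k <- ncol(m)
    a <- sum(rk^2); cc <- n * k * (k + 1)^2 / 4
    if (a - cc <= 1e-12) return(0)
    (k - 1) * sum((rj - n * (k + 1) / 2)^2) / (a - cc)
  }
  obs <- stat_of(x)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nrep)) {
    xp <- t(apply(x, 1L, sample))
    if (stat_of(xp) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / nrep
}
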