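# Internal helpers shared across modules.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

#' Quadrant swap placing DC between corner and centre
#'
#' Swaps the quadrants of a matrix so that the DC sample moves between index
#' `[1, 1]` (the convention of [stats::fft()]) and the centred convention with
#' DC at index `floor(N/2) + 1` on each axis. Both dimensions must be even, in
#' which case the operation is an involution (it is its own inverse).
#'
#' @param x A matrix with even dimensions.
#' @return The quadrant-swapped matrix.
#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 2L)
    .stopf("fftshift2() expects a matrix")
  if (any(d %% 2L != 0L))
    .stopf("fftshift2() requires even dimensions, got %d x %d", d[1L], d[2L])
  x[c((d[1L] / 2L + 1L):d[1L], 1L:(d[1L] / 2L)),
    c((d[2L] / 2L + 1L):d[2L], 1L:(d[2L] / 2L)), drop = FALSE]
}

# Run `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 1-based index of the conjugate-mirror line in the DC-centred convention
# (even n): centred index r holds frequency (r-1) - n/2; its negation sits at
# ((n - (r-1)) %% n) + 1. DC (r = n/2+1) and the Nyquist line (r = 1) map to
# themselves.
.mirror_index <- function(n) ((n - (seq_len(n) - 1L)) %% n) + 1L

# Derive `n` child seeds (< 2^31) reproducibly from one master seed.
.derive_seeds <- function(master_seed, n) {
  if (n == 0L) return(integer(0))
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
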