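# Independent brute-force oracles used across the suite. These deliberately
# re-derive set memberships and counts from the raw distance predicates, so
# they share no code with the enumeration routines they check.

brute_von_neumann <- function(center, r, shape) {
  out <- NULL
  for (x in seq_len(shape[1L])) for (y in seq_len(shape[2L])) {
    d <- abs(x - center[1L]) + abs(y - center[2L])
    if (d >= 1 && d <= r) out <- rbind(out, c(x, y))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

brute_moore <- function(center, r, shape) {
  out <- NULL
  for (x in seq_len(shape[1L])) for (y in seq_len(shape[2L])) {
    d <- max(abs(x - center[1L]), abs(y - center[2L]))
    if (d >= 1 && d <= r) out <- rbind(out, c(x, y))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

brute_band_annulus <- function(center, a, b, shape) {
  out <- NULL
  for (x in seq_len(shape[1L])) for (y in seq_len(shape[2L])) {
    d <- max(abs(x - center[1L]), abs(y - center[2L]))
    if (d >= a && d <= b) out <- rbind(out, c(x, y))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

brute_band_corners <- function(center, a, b, shape) {
  out <- NULL
  for (x in seq_len(shape[1L])) for (y in seq_len(shape[2L])) {
    dx <- abs(x - center[1L]); dy <- abs(y - center[2L])
    if (dx >= a && dx <= b && dy >= a && dy <= b) out <- rbind(out, c(x, y))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# membership count of the half-open Chebyshev annulus a < d <= b around an
# interior cell (what the closed-form (2b+1)^d - (2a+1)^d counts)
brute_halfopen_count <- function(a, b, d) {
  grid <- expand.grid(rep(list(seq(-b, b)), d))
  cheb <- apply(abs(as.matrix(grid)), 1, max)
  sum(cheb > a & cheb <= b)
}

# sorted canonical form for set comparison of coordinate matrices
canon <- function(m) {
  if (nrow(m) == 0L) return(m)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

random_mask <- function(shape, p = 0.5) {
  matrix(runif(prod(shape)) < p, shape[1L], shape[2L]) * 1L
}

two_region_scene <- function(seed = 42, shape = c(64L, 64L), noise = 0.05) {
  noisy_shapes(scene_spec(shape,
    list(list(type = "rect", rows = c(16L, 48L), cols = c(16L, 48L))),
    noise = "gaussian", noise_param = noise, seed = seed))
}
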