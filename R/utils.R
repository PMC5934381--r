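# Internal numeric helpers shared across modules.

#' @keywords internal
rms <- function(x) sqrt(mean(x^2))

#' @keywords internal
next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

# dB <-> linear amplitude
amp_to_db <- function(a) 20 * log10(a)
db_to_amp <- function(db) 10^(db / 20)

#' @keywords internal
is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)

#' @keywords internal
is_scalar <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# Run-length segmentation of a logical vector into half-open index runs.
# Returns a matrix with columns start, end (1-based, end inclusive).
logical_runs <- function(mask) {
  stopifnot(is.logical(mask))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Deterministic child seed derivation: one user-facing seed fans out to
# per-stage/per-channel streams.  Kept below 2^31 - 1.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647
}

# Hann window of length n (periodic-symmetric as used for spectral averaging).
hann_window <- function(n) {
  if (n == 1) return(1)
  as.numeric(signal::hanning(n))
}
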