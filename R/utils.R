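# Internal numerical helpers shared across modules.

#' Welch power spectral density estimate
#'
#' Hann-windowed Welch periodogram averaging with 50% overlap. Segments that
#' do not fit completely are dropped; a signal shorter than one segment is an
#' error. Used by the band-power artifact-rejection criterion.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nseg segment length in samples (defaults to `min(length(x), 256)`).
#' @return list with `freq` (Hz) and `power` (one-sided, arbitrary scale).
#' @keywords internal
welch_psd <- function(x, fs, nseg = min(length(x), 256L)) {
  n <- length(x)
  if (n < nseg) stop("signal shorter than the PSD segment length")
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    acc <- acc + abs(stats::fft(seg))^2
  }
  nf <- nseg %/% 2L + 1L
  list(freq = (seq_len(nf) - 1L) * fs / nseg,
       power = acc[seq_len(nf)] / length(starts))
}

#' Band power by trapezoidal integration of a PSD
#' @keywords internal
band_power <- function(psd, lo, hi) {
  idx <- which(psd$freq >= lo & psd$freq <= hi)
  if (length(idx) < 2L) return(sum(psd$power[idx]))
  f <- psd$freq[idx]
  p <- psd$power[idx]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

# Stratified fold assignment: permutes indices within each class and deals
# them round-robin so every fold holds both classes.
stratified_folds <- function(labels, k, seed = NULL) {
  if (k < 2L) stop("k must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < k) stop("class '", lv, "' has fewer members than folds")
    fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
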