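#' Weighted phase lag index between two epoched signals
#'
#' Estimates the weighted phase lag index (wPLI) from the imaginary part
#' of the cross-spectrum pooled over epochs and frequency bins within a
#' band:
#' \deqn{wPLI = | \sum_k Im(S_{xy,k}) | / \sum_k | Im(S_{xy,k}) |}
#' where `S_xy` is the epoch-wise FFT cross-spectrum and `k` ranges over
#' epochs and in-band bins. The statistic lies in `[0, 1]`, is invariant
#' to amplitude rescaling of either channel and to swapping the channels,
#' and is insensitive to zero-lag (volume-conduction-like) coupling. When
#' no imaginary cross-spectral mass exists at all (the 0/0 case, e.g. two
#' identical signals) the value is defined as 0: no lagged synchrony.
#'
#' @param x,y numeric matrices of identical shape, samples x epochs
#'   (each column one epoch). At least 2 epochs.
#' @param sampling_rate sampling rate in Hz.
#' @param band numeric length-2 `(f_low, f_high)` in Hz; must not exceed
#'   the Nyquist frequency.
#' @return A single wPLI value in `[0, 1]`.
#' @examples
#' t <- seq(0, 1, length.out = 201)[-201]
#' x <- replicate(10, sin(2 * pi * 10 * t))
#' y <- replicate(10, sin(2 * pi * 10 * t + pi / 2))
#' compute_wpli(x, y, 200, c(8, 14)) # 1: consistent quarter-cycle lag
#' @export
compute_wpli <- function(x, y, sampling_rate, band) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.matrix(y)) y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shape")
  if (ncol(x) < 2) stop("at least 2 epochs are required")
  if (length(band) != 2 || band[1] >= band[2]) stop("band must be (f_low, f_high)")
  if (band[2] > sampling_rate / 2) stop("band exceeds the Nyquist frequency")
  S <- nrow(x)
  freqs <- (seq_len(S) - 1) * sampling_rate / S
  sel <- freqs >= band[1] & freqs <= band[2] & freqs <= sampling_rate / 2
  if (!any(sel)) stop("no frequency bins fall inside the band")
  cs <- stats::mvfft(x)[sel, , drop = FALSE] *
    Conj(stats::mvfft(y)[sel, , drop = FALSE])
  im <- Im(cs)
  den <- sum(abs(im))
  if (den == 0) return(0)
  abs(sum(im)) / den
}
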