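#' Welch-averaged power spectral density
#'
#' Splits the signal into half-overlapping windows, removes a linear trend
#' from each, applies a Hann taper, and averages the one-sided modified
#' periodograms. Normalisation is such that `sum(psd) * df` approximates the
#' signal variance (Parseval). Written for tachogram spectra: the defaults
#' (window of up to 512 samples at 4 Hz, i.e. 128 s, 50% overlap) trade
#' variance of the estimate against resolution of the low-frequency bands.
#'
#' @param x numeric signal (mean removal is the caller's responsibility;
#'   the per-window linear detrend removes any residual offset).
#' @param fs sampling frequency, Hz.
#' @param window_len window length in samples; capped at `length(x)`.
#' @param overlap fractional overlap between consecutive windows, in [0, 1).
#' @return list with `freq` (Hz, excluding DC), `psd` (power density,
#'   unit^2/Hz), and `df` (frequency bin width, Hz).
#' @export
welch_psd <- function(x, fs, window_len = 512, overlap = 0.5) {
  n <- length(x)
  stopifnot(n >= 8, fs > 0, overlap >= 0, overlap < 1)
  L <- min(window_len, n)
  L <- L - L %% 2L  # even length keeps the Nyquist bin well-defined
  hop <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))  # Hann
  U <- mean(w^2)  # window power normalisation
  tt <- seq_len(L)
  acc <- numeric(L %/% 2L)
  for (s in starts) {
    xi <- x[s:(s + L - 1L)]
    fit <- stats::lm.fit(cbind(1, tt), xi)  # linear detrend
    xi <- fit$residuals * w
    X <- stats::fft(xi)
    P <- Mod(X[2:(L %/% 2L + 1L)])^2 / (fs * L * U)
    P[-(L %/% 2L)] <- 2 * P[-(L %/% 2L)]  # one-sided, except Nyquist
    acc <- acc + P
  }
  list(freq = (1:(L %/% 2L)) * fs / L,
       psd = acc / length(starts),
       df = fs / L)
}
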