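#' Propagation delay from the cross-correlation maximum
#'
#' Mean-removes both series, computes the normalized cross-correlation over
#' lags in `[-max_lag_s, +max_lag_s]` (FFT-based; the normalization divides
#' by the full-series root sums of squares, so the peak value lies in
#' `[-1, 1]` and equals 1 for identical series at zero lag), and returns the
#' lag of the maximum. A positive delay means `sig` lags `ref`. Ties at the
#' maximum are broken toward the smallest absolute lag, then toward the
#' negative lag, so the result is deterministic.
#'
#' @param ref Reference series (e.g. foot acceleration).
#' @param sig Test series (e.g. hip or head acceleration), same length.
#' @param rate_hz Sampling rate, Hz.
#' @param max_lag_s Half-width of the lag search window, s (default 0.5).
#' @param pair,axis Optional labels carried into the result.
#' @return Object of class `perch_delay`: `delay_s`, `peak_corr`,
#'   `lag_samples`, plus labels.
#' @examples
#' x <- sin(2 * pi * 3 * seq(0, 2, by = 1e-3))
#' xcorr_delay(x, c(rep(0, 20), x[1:(length(x) - 20)]), 1000)$delay_s  # 0.02
#' @export
xcorr_delay <- function(ref, sig, rate_hz, max_lag_s = 0.5,
                        pair = NULL, axis = NULL) {
  ref <- as.numeric(ref); sig <- as.numeric(sig)
  N <- length(ref)
  if (length(sig) != N) stop("ref and sig must have equal length")
  L <- as.integer(round(max_lag_s * rate_hz))
  if (L < 1 || L >= N) stop("max_lag_s must cover at least one sample and be ",
                            "shorter than the trace duration")
  r0 <- ref - mean(ref)
  s0 <- sig - mean(sig)
  nr <- sqrt(sum(r0^2)); ns <- sqrt(sum(s0^2))
  if (nr == 0 || ns == 0)
    stop("zero-variance input: cross-correlation undefined")

  nfft <- nextn(N + L, c(2, 3, 5))
  Fr <- fft(c(r0, numeric(nfft - N)))
  Fs <- fft(c(s0, numeric(nfft - N)))
  cc_full <- Re(fft(Fs * Conj(Fr), inverse = TRUE)) / nfft
  # cc_full[1 + k] = sum_t ref[t] * sig[t + k] for k >= 0 (mod nfft)
  lags <- -L:L
  cc <- cc_full[ifelse(lags >= 0, lags + 1L, nfft + 1L + lags)] / (nr * ns)

  cand <- which(cc == max(cc))
  best <- cand[order(abs(lags[cand]), lags[cand])][1]
  structure(list(pair = pair, axis = axis,
                 delay_s = lags[best] / rate_hz,
                 peak_corr = cc[best],
                 lag_samples = lags[best],
                 max_lag_s = L / rate_hz),
            class = "perch_delay")
}

#' @export
print.perch_delay <- function(x, ...) {
  lab <- paste(c(x$pair, x$axis), collapse = ", ")
  cat(sprintf("Cross-correlation delay%s: %.4f s (r = %.3f at lag %d)\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              x$delay_s, x$peak_corr, x$lag_samples))
  invisible(x)
}

#' Per-axis sensing delays of a recording
#'
#' Convenience wrapper applying [xcorr_delay()] with the foot channel as
#' reference against the hip or head channel, per axis.
#'
#' @param recording A `perch_recording`.
#' @param sensor "hip" or "head".
#' @param max_lag_s Lag search half-width, s.
#' @return Named numeric vector of delays (s) for axes x, y, z.
#' @export
sensing_delays <- function(recording, sensor = c("hip", "head"),
                           max_lag_s = 0.5) {
  sensor <- match.arg(sensor)
  sig <- recording[[sensor]]
  vapply(c(x = 1L, y = 2L, z = 3L), function(a)
    xcorr_delay(recording$foot[, a], sig[, a], recording$rate_hz,
                max_lag_s = max_lag_s,
                pair = paste0("foot->", sensor))$delay_s,
    numeric(1))
}
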