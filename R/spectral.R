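#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments of `window_s`
#' seconds with fractional `overlap`, overall mean removed first and each
#' segment demeaned before windowing. One-sided density in units of
#' (input units)^2 / Hz.
#'
#' @param x Numeric vector.
#' @param rate_hz Sampling rate, Hz.
#' @param window_s Segment length in seconds (default 4).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, rate_hz, window_s = 4, overlap = 0.5) {
  x <- as.numeric(x)
  L <- as.integer(round(window_s * rate_hz))
  if (L < 8) stop("window_s too short for the sampling rate")
  if (length(x) < L)
    stop("trace (", length(x), " samples) shorter than one window (", L, ")")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  x <- x - mean(x)
  step <- max(1L, as.integer(floor(L * (1 - overlap))))
  starts <- seq.int(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0 + 0:(L - 1L)]
    X <- fft((seg - mean(seg)) * w)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * U * rate_hz)
  if (nf > 2) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  list(freq = (seq_len(nf) - 1) * rate_hz / L, psd = psd)
}

#' Resonant frequency: the frequency of maximal spectral power
#'
#' Locates the peak of the Welch power spectral density within
#' `[f_min, f_max]`. For a multi-axis trace (matrix input) the per-axis PSDs
#' are summed — total acceleration power — before peak picking. The estimate
#' is invariant to trace scaling and mean offset. A peak-prominence
#' diagnostic (peak power over median in-band power) flags traces with no
#' dominant resonance, e.g. white noise, via `attr(, "no_dominant_peak")`.
#'
#' @param trace Numeric vector or N x k matrix (axes in columns).
#' @param rate_hz Sampling rate, Hz.
#' @param f_min,f_max Search band, Hz (`0 <= f_min < f_max <= rate_hz/2`).
#' @param window_s,overlap Welch settings, see [welch_psd()].
#' @param prominence_min Flag threshold for the peak/median power ratio.
#' @return Peak frequency in Hz, with attributes `prominence` and
#'   `no_dominant_peak`.
#' @export
resonant_frequency <- function(trace, rate_hz, f_min = 0.5, f_max = 50,
                               window_s = 4, overlap = 0.5,
                               prominence_min = 10) {
  if (!(f_min >= 0 && f_min < f_max && f_max <= rate_hz / 2))
    stop("need 0 <= f_min < f_max <= rate_hz / 2")
  trace <- as.matrix(trace)
  ps <- welch_psd(trace[, 1], rate_hz, window_s, overlap)
  psd <- ps$psd
  if (ncol(trace) > 1)
    for (j in 2:ncol(trace))
      psd <- psd + welch_psd(trace[, j], rate_hz, window_s, overlap)$psd
  band <- which(ps$freq >= f_min & ps$freq <= f_max)
  if (!length(band)) stop("empty frequency band")
  pk <- band[which.max(psd[band])]
  prom <- psd[pk] / max(median(psd[band]), .Machine$double.xmin)
  structure(ps$freq[pk], prominence = prom,
            no_dominant_peak = prom < prominence_min)
}

#' Effective stiffness from a resonant frequency
#'
#' The lumped estimator `K = m f^2` with `f` in Hz (units N/m up to the
#' estimator's own convention). Note this is proportional, not equal, to the
#' physical spring constant of a harmonic oscillator, `k = m (2 pi f)^2`; the
#' estimator equals `k / (2 pi)^2`. It is used as a relative measure to
#' compare conditions, where the constant factor cancels.
#'
#' @param m_kg Mass, kg (> 0).
#' @param f_hz Resonant frequency, Hz (>= 0).
#' @return Stiffness `m_kg * f_hz^2`.
#' @examples
#' stiffness_eq1(1, 1)    # 1
#' stiffness_eq1(0.1, 5)  # 2.5
#' @export
stiffness_eq1 <- function(m_kg, f_hz) {
  if (!is.numeric(m_kg) || any(m_kg <= 0)) stop("mass must be positive")
  if (!is.numeric(f_hz) || any(f_hz < 0)) stop("frequency must be non-negative")
  m_kg * f_hz^2
}

#' Bootstrap the effective-stiffness estimate over random segments
#'
#' Draws `n_iter` random (with replacement) contiguous segments of
#' `segment_s` seconds, estimates the head-channel resonant frequency on each
#' and converts it to stiffness with [stiffness_eq1()]. Iterations where the
#' spectral peak search fails are dropped and counted.
#'
#' @param recording A `perch_recording`.
#' @param m_kg Mass used in the stiffness formula; defaults to the recorded
#'   head mass (`meta$params$m_head`).
#' @param n_iter Bootstrap iterations (default 1000).
#' @param segment_s Segment length, s (default 30).
#' @param seed Integer seed.
#' @param f_min,f_max,window_s Spectral settings, see [resonant_frequency()].
#' @return A `perch_boot` object of stiffness values (N/m).
#' @export
stiffness_bootstrap <- function(recording, m_kg = NULL, n_iter = 1000,
                                segment_s = 30, seed = 1L,
                                f_min = 0.5, f_max = 50, window_s = 4) {
  if (!inherits(recording, "perch_recording")) stop("recording must be a perch_recording")
  if (is.null(m_kg)) m_kg <- recording$meta$params$m_head
  if (is.null(m_kg)) stop("m_kg not given and not recorded in meta")
  stat <- function(w)
    stiffness_eq1(m_kg, as.numeric(resonant_frequency(w$head, w$rate_hz,
                                                      f_min, f_max, window_s)))
  bootstrap_windows(recording, stat, n_iter = n_iter, window_s = segment_s,
                    seed = seed, statistic_name = "stiffness_nm")
}
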