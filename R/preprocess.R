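#' Frequency-band registry
#'
#' The frequency intervals used throughout: cortical delta, theta, alpha,
#' beta and gamma bands extracted from the EEG, the respiratory interval
#' `r`, and the cardiac interval `h` centred on the heart's main oscillation
#' mode near 1 Hz (band-filtration of the ECG rather than R-peak detection,
#' so that the phase retains intra-cycle resolution).
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz).
#' @examples
#' band_registry()
#' @export
band_registry <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma", "r", "h"),
    f_lo = c(0.8, 4, 7.5, 14, 22, 0.145, 0.6),
    f_hi = c(4, 7.5, 14, 22, 100, 0.6, 2)
  )
}

get_band <- function(band) {
  if (is.data.frame(band)) {
    stopifnot(all(c("band", "f_lo", "f_hi") %in% names(band)), nrow(band) == 1L)
    return(band)
  }
  reg <- band_registry()
  row <- reg[reg$band == band, ]
  if (nrow(row) != 1L) {
    stopf("Unknown band '%s'; see band_registry().", band)
  }
  row
}

band_centre <- function(band) {
  b <- get_band(band)
  (b$f_lo + b$f_hi) / 2
}

#' Zero-phase FIR band-pass filter
#'
#' Extracts one frequency interval from a signal with a windowed-sinc
#' (Hamming) FIR filter applied forward and backward (`signal::filtfilt`),
#' so no phase lag is introduced. The filter order is tied to the slow edge
#' of the band, `ceil(3 * rate / f_lo)`, capped at 10% of the signal length;
#' forward-backward application doubles the stop-band attenuation.
#'
#' @param x Numeric vector, or a data frame whose column `col` holds the
#'   signal.
#' @param band Band name from [band_registry()], or a one-row data frame
#'   with `band`, `f_lo`, `f_hi`.
#' @param rate Sampling rate (Hz). If `x` is a data frame with a `rate`
#'   attribute this may be omitted.
#' @param col Column to filter when `x` is a data frame.
#' @return The band-limited signal, same length/shape as the input: a
#'   numeric vector for vector input, or the input tibble with the filtered
#'   column for data-frame input.
#' @export
bandpass <- function(x, band, rate = NULL, col = NULL) {
  if (is.data.frame(x)) {
    rate <- rate %||% attr(x, "rate")
    if (is.null(rate)) stopf("Supply `rate` (no rate attribute on `x`).")
    if (is.null(col)) stopf("Supply `col` for data-frame input.")
    x[[col]] <- bandpass(x[[col]], band, rate)
    return(x)
  }
  b <- get_band(band)
  if (rate <= 2 * b$f_hi) {
    stopf("Band %s (%g-%g Hz) is at or above Nyquist for rate %g Hz.",
          b$band, b$f_lo, b$f_hi, rate)
  }
  n_ord <- ceiling(3 * rate / b$f_lo)
  n_ord <- min(n_ord, floor(0.1 * length(x)))
  n_ord <- max(n_ord, 16L)
  if (n_ord %% 2L == 1L) n_ord <- n_ord + 1L  # even order: symmetric, integer delay
  w <- c(b$f_lo, b$f_hi) / (rate / 2)
  flt <- signal::fir1(n_ord, w, type = "pass", window = signal::hamming(n_ord + 1))
  as.numeric(signal::filtfilt(flt, x))
}

#' Protophase from the Hilbert analytic signal
#'
#' Computes the analytic signal of a band-limited input by the FFT method
#' (positive frequencies doubled, negative zeroed) and returns its unwrapped
#' angle — the protophase. The protophase depends on the observable; use
#' [protophase_to_phase()] to obtain the invariant phase. Samples where the
#' analytic amplitude is near zero yield unreliable angles; if more than 1%
#' of samples fall below 1e-3 of the median amplitude a warning is issued.
#'
#' @param x Numeric vector (band-limited signal).
#' @param rate Sampling rate (Hz).
#' @param band Optional band label attached to the result.
#' @return A [phase_series()] with `kind = "protophase"`.
#' @export
hilbert_protophase <- function(x, rate, band = NA_character_) {
  stopifnot(is.numeric(x), length(x) > 3)
  n <- length(x)
  X <- fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  amp <- Mod(z)
  low <- mean(amp < 1e-3 * median(amp))
  if (low > 0.01) {
    warnf("Analytic amplitude near zero for %.1f%% of samples; protophase may be unreliable.",
          100 * low)
  }
  phase_series(unwrap_phase(Arg(z)), rate = rate, band = band,
               kind = "protophase")
}

#' Protophase-to-phase transformation
#'
#' Maps an observable-dependent protophase \eqn{\theta} to the invariant
#' phase \eqn{\phi} whose density on the circle is uniform. The monotone
#' 2\eqn{\pi}-periodic map is built from the Fourier coefficients
#' \eqn{S_n = \langle e^{-in\theta} \rangle} of the wrapped empirical
#' protophase distribution:
#' \deqn{\phi(\theta) = \theta + 2 \sum_{n=1}^{N_F}
#'   \mathrm{Re}\!\left[\frac{S_n}{in}\left(e^{in\theta} - 1\right)\right],}
#' applied sample-wise to the unwrapped protophase. Because the correction is
#' 2\eqn{\pi}-periodic, the total cycle count is preserved exactly.
#'
#' @param theta A [phase_series()] with `kind = "protophase"` (a plain
#'   numeric vector is accepted together with `rate`). Must span at least
#'   10 full cycles for a reliable density estimate.
#' @param n_fourier Number of Fourier harmonics of the empirical density
#'   retained in the map. Default 24.
#' @param rate Sampling rate, only for plain-vector input.
#' @return A [phase_series()] with `kind = "phase"`.
#' @export
protophase_to_phase <- function(theta, n_fourier = 24, rate = NULL) {
  if (is.numeric(theta)) {
    if (is.null(rate)) stopf("Supply `rate` for plain-vector input.")
    theta <- phase_series(theta, rate, kind = "protophase")
  }
  stopifnot(inherits(theta, "phase_series"))
  th <- theta$phi
  n_cycles <- abs(th[length(th)] - th[1]) / (2 * pi)
  if (n_cycles < 10) {
    stopf("Protophase spans only %.1f cycles; at least 10 are required for the density estimate.",
          n_cycles)
  }
  S <- vapply(seq_len(n_fourier), function(n) mean(exp(-1i * n * th)),
              complex(1))
  phi <- th
  for (n in seq_len(n_fourier)) {
    phi <- phi + 2 * Re(S[n] * (exp(1i * n * th) - 1) / (1i * n))
  }
  phase_series(phi, rate = theta$rate, band = theta$band, kind = "phase",
               t0 = theta$t0)
}

#' Resample an unwrapped phase series
#'
#' Linear interpolation of the unwrapped phase onto a new sampling grid.
#' Because the phase is unwrapped, interpolation preserves cycle counts and
#' mean frequency exactly for linear segments.
#'
#' @param phi A [phase_series()].
#' @param out_rate Target rate (Hz). Must be at least 10 times the band's
#'   centre frequency when the band is known.
#' @return A resampled [phase_series()].
#' @export
resample_phase <- function(phi, out_rate) {
  stopifnot(inherits(phi, "phase_series"))
  if (!is.na(phi$band) && phi$band %in% band_registry()$band) {
    fc <- band_centre(phi$band)
    if (out_rate < 10 * fc) {
      stopf("`out_rate` = %g Hz is below 10x the %s-band centre frequency (%g Hz).",
            out_rate, phi$band, fc)
    }
  }
  t_old <- phi$t0 + (seq_along(phi$phi) - 1) / phi$rate
  t_new <- seq(phi$t0, t_old[length(t_old)], by = 1 / out_rate)
  phase_series(approx(t_old, phi$phi, xout = t_new)$y, rate = out_rate,
               band = phi$band, kind = phi$kind, t0 = phi$t0)
}

#' Extract the invariant phase of one band from a raw channel
#'
#' The full per-band preprocessing chain: zero-phase FIR band-pass,
#' Hilbert protophase, protophase-to-phase transformation, and trimming of
#' the filter/Hilbert edge transients (`ceil(2 / f_lo)` seconds at each
#' end).
#'
#' @param x Numeric signal vector, or a channel table (data frame) with
#'   `col` naming the channel.
#' @param band Band name from [band_registry()].
#' @param rate Sampling rate (Hz); taken from `attr(x, "rate")` for
#'   data-frame input when omitted.
#' @param col Channel column for data-frame input.
#' @param n_fourier Harmonics used by [protophase_to_phase()].
#' @param trim Trim edge seconds? Default `TRUE`.
#' @return A [phase_series()] with `kind = "phase"` (edge-trimmed, `t0` set
#'   to the trim offset).
#' @export
extract_phase <- function(x, band, rate = NULL, col = NULL, n_fourier = 24,
                          trim = TRUE) {
  if (is.data.frame(x)) {
    rate <- rate %||% attr(x, "rate")
    if (is.null(col)) stopf("Supply `col` for data-frame input.")
    x <- x[[col]]
  }
  if (is.null(rate)) stopf("Supply `rate`.")
  b <- get_band(band)
  xf <- bandpass(x, band, rate)
  theta <- hilbert_protophase(xf, rate, band = band)
  phi <- protophase_to_phase(theta, n_fourier = n_fourier)
  if (trim) {
    margin <- ceiling(2 / b$f_lo)
    k <- round(margin * rate)
    if (2 * k >= length(phi$phi)) {
      stopf("Signal too short to trim %g s edges for band %s.", margin, band)
    }
    phi <- phase_series(phi$phi[(k + 1):(length(phi$phi) - k)], rate = rate,
                        band = band, kind = "phase", t0 = phi$t0 + k / rate)
  }
  phi
}
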