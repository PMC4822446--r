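#' Phase time series
#'
#' A light container for an unwrapped instantaneous phase trajectory — the
#' fundamental input of the inference stage. Stored as a numeric vector with
#' its sampling rate, start time, band label and kind (`"protophase"` for raw
#' Hilbert angles, `"phase"` for invariant phases).
#'
#' @param phi Numeric vector, unwrapped phase (rad).
#' @param rate Sampling rate (Hz).
#' @param band Band label (e.g. `"alpha"`), or `NA`.
#' @param kind `"phase"` or `"protophase"`.
#' @param t0 Start time (s).
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(phi, rate, band = NA_character_,
                         kind = c("phase", "protophase"), t0 = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(phi) || anyNA(phi) || !all(is.finite(phi))) {
    stopf("`phi` must be finite numeric.")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stopf("`rate` must be a single positive number.")
  }
  structure(
    list(phi = as.numeric(phi), rate = as.numeric(rate),
         band = band, kind = kind, t0 = as.numeric(t0)),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf(
    "<phase_series> %s [%s] n = %d, rate = %g Hz, %.1f s, %.1f cycles\n",
    ifelse(is.na(x$band), "?", x$band), x$kind, length(x$phi), x$rate,
    length(x$phi) / x$rate, (x$phi[length(x$phi)] - x$phi[1]) / (2 * pi)
  ))
  invisible(x)
}

#' @export
length.phase_series <- function(x) length(x$phi)

#' Convert a phase series to a tibble
#' @param x A [phase_series()].
#' @param ... Unused.
#' @return A tibble with columns `time` and `phi`.
#' @export
as_tibble.phase_series <- function(x, ...) {
  tibble::tibble(time = x$t0 + (seq_along(x$phi) - 1) / x$rate, phi = x$phi)
}

ps_duration <- function(x) length(x$phi) / x$rate

ps_mean_freq <- function(x) {
  (x$phi[length(x$phi)] - x$phi[1]) / (2 * pi * (length(x$phi) - 1) / x$rate)
}
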