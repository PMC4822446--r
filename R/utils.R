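#' Wrap phases to [0, 2pi)
#' @param phi Numeric vector of phases (rad).
#' @return Wrapped phases in `[0, 2pi)`.
#' @export
wrap_phase <- function(phi) phi %% (2 * pi)

#' Unwrap a wrapped phase sequence
#'
#' Removes artificial jumps larger than \eqn{\pi} between consecutive samples
#' so the result is a continuous phase trajectory.
#'
#' @param phi Numeric vector of (possibly wrapped) phases (rad).
#' @return Unwrapped phase vector, same length.
#' @export
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  phi - c(0, cumsum(jumps)) * 2 * pi
}

# Circular RMS of a phase error, after removing the circular mean offset.
circ_rms <- function(err) {
  z <- exp(1i * err)
  offset <- Arg(mean(z))
  resid <- Arg(exp(1i * (err - offset)))
  sqrt(mean(resid^2))
}

# Circular mean of angles.
circ_mean <- function(phi) Arg(mean(exp(1i * phi)))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
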