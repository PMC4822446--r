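#' Tidy a posterior into one row per parameter
#'
#' @param x A `posterior` from [infer_window()].
#' @param ... Unused.
#' @return A tibble with one row per inferred parameter: `equation` (target
#'   oscillator label), `k`, `l`, `kind`, `role`, `estimate` and
#'   `std_error` (posterior SD from the covariance diagonal).
#' @export
tidy.posterior <- function(x, ...) {
  basis <- x$basis
  M <- nrow(basis)
  dplyr::bind_rows(lapply(1:2, function(eq) {
    idx <- eq_block(basis, eq)
    tibble::tibble(
      equation = x$labels[eq],
      k = basis$k, l = basis$l, kind = basis$kind, role = basis$role,
      estimate = x$c[idx],
      std_error = sqrt(pmax(0, diag(x$Sigma)[idx]))
    )
  }))
}

#' One-row summary of a posterior
#'
#' @param x A `posterior`.
#' @param ... Unused.
#' @return A one-row tibble: window index, sample count, the two inferred
#'   natural frequencies (rad/s), noise strengths, net coupling strengths in
#'   both directions, convergence status.
#' @export
glance.posterior <- function(x, ...) {
  basis <- x$basis
  const_idx <- which(basis$kind == "constant")
  tibble::tibble(
    window_index = x$window_index,
    n_samples = x$n_samples,
    omega_1 = x$c[eq_block(basis, 1L)][const_idx],
    omega_2 = x$c[eq_block(basis, 2L)][const_idx],
    D_11 = x$D[1, 1], D_22 = x$D[2, 2], D_12 = x$D[1, 2],
    net_21 = coupling_strength(x, direction = c(x$labels[2], x$labels[1])),
    net_12 = coupling_strength(x, direction = c(x$labels[1], x$labels[2])),
    converged = x$converged, iterations = x$iterations
  )
}

#' Tidy a surrogate ensemble
#' @param x A [surrogate_ensemble()].
#' @param ... Unused.
#' @return A tibble with one row per surrogate strength.
#' @export
tidy.surrogate_ensemble <- function(x, ...) {
  tibble::tibble(kind = x$kind, surrogate = seq_along(x$strengths),
                 strength = x$strengths)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
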