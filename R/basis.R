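#' Truncated Fourier basis for coupled phase dynamics
#'
#' Builds the complete order-`K` trigonometric basis used to represent the
#' deterministic part of a pair of coupled phase equations,
#' \deqn{\dot\phi_i = \omega_i + q_i(\phi_i, \phi_j) + \xi_i(t),}
#' where the right-hand side is expanded in Fourier terms
#' \eqn{\sin(k\phi_i + l\phi_j)} and \eqn{\cos(k\phi_i + l\phi_j)} with
#' \eqn{|k|, |l| \le K}. Because \eqn{\sin} and \eqn{\cos} of \eqn{-(k,l)}
#' are linearly dependent on those of \eqn{(k,l)}, exactly one representative
#' per sign pair is enumerated: the one with \eqn{k > 0}, or \eqn{k = 0} and
#' \eqn{l > 0}. The natural frequency \eqn{\omega_i} is carried as the
#' coefficient of the constant term.
#'
#' The ordering is deterministic: the constant term first, then the
#' representative pairs in lexicographic \eqn{(k, l)} order, sin before cos.
#' This fixes the layout of every parameter vector produced by
#' [infer_window()] and consumed by the coupling-analysis functions, so
#' indices are stable across runs and serialisations.
#'
#' Each term is classified by its role in the phase equation of the *target*
#' oscillator (the one whose own phase is \eqn{\phi_i}):
#' \describe{
#'   \item{constant}{\eqn{k = l = 0}; carries \eqn{\omega_i}.}
#'   \item{self}{\eqn{l = 0, k \ne 0}: depends only on the target's own phase.}
#'   \item{direct}{\eqn{k = 0, l \ne 0}: unidirectional driving by the other
#'     oscillator's phase alone.}
#'   \item{indirect}{\eqn{k \ne 0, l \ne 0}: joint (common) dependence on both
#'     phases, including diffusive phase-difference terms.}
#' }
#'
#' @param K Non-negative integer expansion order. `K = 2` (the default)
#'   gives 25 terms.
#'
#' @return A tibble of class `fourier_basis` with one row per basis term and
#'   columns `index`, `k`, `l`, `kind` (`"constant"`, `"sin"` or `"cos"`) and
#'   `role` (`"constant"`, `"self"`, `"direct"`, `"indirect"`). The expansion
#'   order is stored in `attr(, "K")`.
#'
#' @examples
#' b <- fourier_basis(2)
#' nrow(b)           # 25
#' table(b$role)
#' @export
fourier_basis <- function(K = 2) {
  if (length(K) != 1L || !is.finite(K) || K < 0 || K != round(K)) {
    stop("`K` must be a single non-negative integer.", call. = FALSE)
  }
  K <- as.integer(K)
  rows <- list(tibble::tibble(k = 0L, l = 0L, kind = "constant"))
  if (K > 0) {
    pairs <- tidyr::expand_grid(k = 0:K, l = -K:K)
    pairs <- dplyr::filter(
      pairs,
      (.data$k > 0L) | (.data$k == 0L & .data$l > 0L)
    )
    pairs <- dplyr::arrange(pairs, .data$k, .data$l)
    trig <- tidyr::expand_grid(pairs, kind = c("sin", "cos"))
    rows <- c(rows, list(trig))
  }
  terms <- dplyr::bind_rows(rows)
  terms$role <- term_role(terms$k, terms$l)
  terms$index <- seq_len(nrow(terms))
  terms <- terms[, c("index", "k", "l", "kind", "role")]
  attr(terms, "K") <- K
  class(terms) <- c("fourier_basis", class(terms))
  terms
}

term_role <- function(k, l) {
  dplyr::case_when(
    k == 0L & l == 0L ~ "constant",
    l == 0L ~ "self",
    k == 0L ~ "direct",
    TRUE ~ "indirect"
  )
}

basis_dim <- function(basis) nrow(basis)

assert_basis <- function(basis) {
  if (!inherits(basis, "fourier_basis")) {
    stop("`basis` must be created by fourier_basis().", call. = FALSE)
  }
  invisible(basis)
}

#' Evaluate the basis terms at given phases
#'
#' Evaluates every term of a [fourier_basis()] at phase values
#' \eqn{(\phi_i, \phi_j)}, where \eqn{\phi_i} is the target oscillator's own
#' phase. All terms are \eqn{2\pi}-periodic, so any phase branch
#' (wrapped or unwrapped) gives the same result.
#'
#' @param basis A [fourier_basis()].
#' @param phi_i,phi_j Numeric vectors of equal length (or length 1, recycled):
#'   phases in radians.
#'
#' @return For scalar phases, a numeric vector of length `nrow(basis)`;
#'   otherwise a numeric matrix with one row per phase sample and one column
#'   per basis term, in basis order.
#'
#' @examples
#' b <- fourier_basis(1)
#' evaluate_basis(b, 0, 0)         # constant 1, sines 0, cosines 1
#' @export
evaluate_basis <- function(basis, phi_i, phi_j) {
  assert_basis(basis)
  ph <- check_phases(phi_i, phi_j)
  arg <- outer(ph$phi_i, basis$k) + outer(ph$phi_j, basis$l)
  out <- matrix(0, nrow = nrow(arg), ncol = ncol(arg))
  is_sin <- basis$kind == "sin"
  is_cos <- basis$kind == "cos"
  out[, is_sin] <- sin(arg[, is_sin, drop = FALSE])
  out[, is_cos] <- cos(arg[, is_cos, drop = FALSE])
  out[, basis$kind == "constant"] <- 1
  if (nrow(out) == 1L) drop(out) else out
}

#' Evaluate the basis derivative with respect to the target's own phase
#'
#' Term-wise derivative \eqn{\partial \Phi / \partial \phi_i} of the basis of
#' [evaluate_basis()]. This enters the drift-correction sum of the midpoint
#' discretisation used by [infer_window()].
#'
#' @inheritParams evaluate_basis
#' @return Same shape as [evaluate_basis()]; the constant term's derivative
#'   is 0 everywhere.
#' @export
evaluate_basis_dphi <- function(basis, phi_i, phi_j) {
  assert_basis(basis)
  ph <- check_phases(phi_i, phi_j)
  arg <- outer(ph$phi_i, basis$k) + outer(ph$phi_j, basis$l)
  out <- matrix(0, nrow = nrow(arg), ncol = ncol(arg))
  is_sin <- basis$kind == "sin"
  is_cos <- basis$kind == "cos"
  kk <- rep(basis$k, each = nrow(arg))
  out[, is_sin] <- (kk * cos(arg))[, is_sin, drop = FALSE]
  out[, is_cos] <- (-kk * sin(arg))[, is_cos, drop = FALSE]
  if (nrow(out) == 1L) drop(out) else out
}

check_phases <- function(phi_i, phi_j) {
  if (!is.numeric(phi_i) || !is.numeric(phi_j) ||
      anyNA(phi_i) || anyNA(phi_j) ||
      !all(is.finite(phi_i)) || !all(is.finite(phi_j))) {
    stop("Phases must be finite numeric values.", call. = FALSE)
  }
  n <- max(length(phi_i), length(phi_j))
  if (!(length(phi_i) %in% c(1L, n)) || !(length(phi_j) %in% c(1L, n))) {
    stop("`phi_i` and `phi_j` must have equal length (or length 1).",
         call. = FALSE)
  }
  list(phi_i = rep_len(phi_i, n), phi_j = rep_len(phi_j, n))
}

#' Serialise a basis specification to JSON
#'
#' Writes the expansion order and the ordered term list so that result files
#' referencing parameter indices are self-describing.
#'
#' @param basis A [fourier_basis()].
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
basis_to_json <- function(basis, path = NULL) {
  assert_basis(basis)
  obj <- list(
    K = attr(basis, "K"),
    terms = as.data.frame(basis[, c("index", "k", "l", "kind", "role")])
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.fourier_basis <- function(x, ...) {
  cat(sprintf("<fourier_basis> K = %d, %d terms\n", attr(x, "K"), nrow(x)))
  NextMethod()
}

# Indices of the coupling subvector (terms shaping the coupling surface).
coupling_term_idx <- function(basis, component = c("net", "direct", "indirect")) {
  component <- match.arg(component)
  switch(component,
    net = which(basis$l != 0L),
    direct = which(basis$k == 0L & basis$l != 0L),
    indirect = which(basis$k != 0L & basis$l != 0L)
  )
}
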