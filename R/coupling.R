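#' Reconstruct a coupling function on a phase grid
#'
#' Evaluates the inferred coupling function of one direction on a uniform
#' \eqn{2\pi \times 2\pi} grid: the sum of the selected basis terms scaled
#' by their inferred parameters. Components:
#' \describe{
#'   \item{net}{all terms involving the driver's phase (`l != 0`);}
#'   \item{direct}{terms depending on the driver's phase only
#'     (`k = 0, l != 0`);}
#'   \item{indirect}{terms depending jointly on both phases
#'     (`k != 0, l != 0`), including diffusive phase-difference terms.}
#' }
#' The constant and self terms are never included, so component grids have
#' zero mean. By linearity, `net = direct + indirect` elementwise.
#'
#' @param post A `posterior` from [infer_window()], or a parameter vector of
#'   length `nrow(basis)` for one equation (then `basis` must be supplied).
#' @param direction Length-2 character vector `c(from, to)` naming the
#'   driver and target oscillators by the labels carried in the posterior.
#'   Defaults to `c(labels[2], labels[1])` (oscillator 2 driving 1).
#' @param component `"net"`, `"direct"` or `"indirect"`.
#' @param grid_n Grid points per axis (>= 8). Default 100.
#' @param basis Only for vector input: the [fourier_basis()].
#' @return An object of class `coupling_grid`: list with `values`
#'   (`grid_n x grid_n` matrix, rows indexed by the target phase
#'   \eqn{\phi_i}, columns by the driver phase \eqn{\phi_j}), `phi` (the
#'   common axis, in `[0, 2pi)`), `direction` and `component`.
#' @export
coupling_function_grid <- function(post, direction = NULL,
                                   component = c("net", "direct", "indirect"),
                                   grid_n = 100, basis = NULL) {
  component <- match.arg(component)
  if (grid_n < 8) stopf("`grid_n` must be at least 8.")
  cf <- coupling_coeffs_for(post, direction, basis)
  sel <- coupling_term_idx(cf$basis, component)
  phi <- seq(0, 2 * pi, length.out = grid_n + 1)[-(grid_n + 1)]
  gr <- expand.grid(phi_i = phi, phi_j = phi)
  B <- evaluate_basis(cf$basis, gr$phi_i, gr$phi_j)
  vals <- B[, sel, drop = FALSE] %*% cf$coeffs[sel]
  structure(
    list(values = matrix(vals, grid_n, grid_n), phi = phi,
         direction = cf$direction, component = component),
    class = "coupling_grid"
  )
}

# Resolve (coeff vector of target equation, basis, direction) from a
# posterior or a plain coefficient vector.
coupling_coeffs_for <- function(post, direction = NULL, basis = NULL) {
  if (inherits(post, "posterior")) {
    labs <- post$labels
    if (is.null(direction)) direction <- c(labs[2], labs[1])
    if (length(direction) != 2L) stopf("`direction` must be c(from, to).")
    tgt <- match(direction[2], labs)
    src <- match(direction[1], labs)
    if (is.na(tgt) || is.na(src) || tgt == src) {
      stopf("Unknown direction %s -> %s for a posterior over (%s, %s).",
            direction[1], direction[2], labs[1], labs[2])
    }
    list(coeffs = post$c[eq_block(post$basis, tgt)], basis = post$basis,
         direction = direction)
  } else if (is.numeric(post)) {
    if (is.null(basis)) stopf("Supply `basis` for vector input.")
    assert_basis(basis)
    if (length(post) != nrow(basis)) {
      stopf("Coefficient vector length %d does not match basis dim %d.",
            length(post), nrow(basis))
    }
    list(coeffs = post, basis = basis,
         direction = direction %||% c("j", "i"))
  } else {
    stopf("`post` must be a posterior or a numeric coefficient vector.")
  }
}

#' Coupling strength
#'
#' The Euclidean norm of the inferred coupling parameters of one direction.
#' Because the net coupling terms partition exactly into direct
#' (`k = 0, l != 0`) and indirect (`k != 0, l != 0`) subsets,
#' \eqn{\|net\|^2 = \|direct\|^2 + \|indirect\|^2}.
#'
#' @inheritParams coupling_function_grid
#' @return A non-negative scalar (1/s).
#' @export
coupling_strength <- function(post, direction = NULL,
                              component = c("net", "direct", "indirect"),
                              basis = NULL) {
  component <- match.arg(component)
  cf <- coupling_coeffs_for(post, direction, basis)
  sel <- coupling_term_idx(cf$basis, component)
  sqrt(sum(cf$coeffs[sel]^2))
}

#' Similarity of form of two coupling functions
#'
#' Pearson correlation of the coupling-parameter subvectors (all terms with
#' `l != 0`) of two coupling functions on the same basis. It measures
#' similarity of the *forms* of the coupling surfaces irrespective of their
#' amplitude: it is invariant to positive rescaling of either vector, and
#' bounded in \eqn{[-1, 1]}.
#'
#' @param coeffs_a,coeffs_b Coupling-parameter vectors: either full
#'   per-equation coefficient vectors of length `nrow(basis)` (the coupling
#'   subvector is selected internally), or bare coupling subvectors of equal
#'   length >= 2 (used as given).
#' @param basis The common [fourier_basis()] (needed for full-length
#'   vectors; default order-2 basis when lengths match it).
#' @return The correlation, or `NA` (with a message) if either subvector has
#'   zero variance.
#' @export
similarity_rho <- function(coeffs_a, coeffs_b, basis = NULL) {
  if (length(coeffs_a) != length(coeffs_b)) {
    stopf("Coefficient vectors must have equal length.")
  }
  if (is.null(basis) && length(coeffs_a) == 25L) basis <- fourier_basis(2)
  if (!is.null(basis)) {
    assert_basis(basis)
    if (length(coeffs_a) == nrow(basis)) {
      sel <- coupling_term_idx(basis, "net")
      coeffs_a <- coeffs_a[sel]
      coeffs_b <- coeffs_b[sel]
    }
  }
  if (length(coeffs_a) < 2L) stopf("Need at least 2 coupling terms.")
  if (sd(coeffs_a) == 0 || sd(coeffs_b) == 0) {
    message("similarity_rho: zero-variance coefficient vector; returning NA.")
    return(NA_real_)
  }
  cor(coeffs_a, coeffs_b)
}

#' Summarise a posterior sequence for one subject and relationship
#'
#' Aggregates windowed posteriors into per-direction coupling summaries:
#' net/direct/indirect strengths and the coupling-coefficient vector are
#' taken as medians across windows (robust to transient non-convergence),
#' the noise strength as the median diagonal of the inferred noise matrix.
#' The predominant direction is the one with the larger median net strength.
#'
#' @param posteriors A list of `posterior` objects (e.g. from
#'   [infer_sequence()]), or a single posterior.
#' @param subject Optional subject identifier recorded in the output.
#' @return A tibble with one row per direction: `subject`, `from`, `to`,
#'   `net`, `direct`, `indirect` (1/s), `noise_from`, `noise_to`
#'   (rad^2/s), `predominant`, `n_windows`, `prop_converged`, `valid`, and a
#'   list-column `coeffs` holding the median per-equation coefficient vector
#'   of the target (for similarity and grid reconstruction).
#' @export
subject_summary <- function(posteriors, subject = NA_character_) {
  if (inherits(posteriors, "posterior")) posteriors <- list(posteriors)
  stopifnot(length(posteriors) >= 1L,
            all(vapply(posteriors, inherits, logical(1), "posterior")))
  basis <- posteriors[[1]]$basis
  labs <- posteriors[[1]]$labels
  conv <- vapply(posteriors, function(p) isTRUE(p$converged), logical(1))
  valid <- any(conv)
  if (!valid) {
    warnf("subject_summary: no window converged; summary flagged invalid.")
  }
  use <- if (any(conv)) posteriors[conv] else posteriors

  one_direction <- function(tgt) {
    src <- 3L - tgt
    dir <- c(labs[src], labs[tgt])
    cm <- vapply(use, function(p) p$c[eq_block(basis, tgt)],
                 numeric(nrow(basis)))
    coeffs <- apply(matrix(cm, nrow = nrow(basis)), 1, median)
    tibble::tibble(
      subject = subject, from = dir[1], to = dir[2],
      net = coupling_strength(coeffs, component = "net", basis = basis),
      direct = coupling_strength(coeffs, component = "direct", basis = basis),
      indirect = coupling_strength(coeffs, component = "indirect",
                                   basis = basis),
      noise_from = median(vapply(use, function(p) p$D[src, src], numeric(1))),
      noise_to = median(vapply(use, function(p) p$D[tgt, tgt], numeric(1))),
      n_windows = length(posteriors),
      prop_converged = mean(conv),
      valid = valid,
      coeffs = list(coeffs)
    )
  }
  out <- dplyr::bind_rows(one_direction(1L), one_direction(2L))
  out$predominant <- out$net == max(out$net)
  out[, c("subject", "from", "to", "net", "direct", "indirect",
          "noise_from", "noise_to", "predominant", "n_windows",
          "prop_converged", "valid", "coeffs")]
}

#' Average coupling grids across subjects
#'
#' Elementwise mean of coupling-function grids (as used for group-mean
#' coupling surfaces). By linearity this equals the grid of the mean
#' coefficient vector.
#'
#' @param grids A list of `coupling_grid` objects on identical axes,
#'   directions and components.
#' @return A `coupling_grid`.
#' @export
mean_coupling_grid <- function(grids) {
  stopifnot(length(grids) >= 1L,
            all(vapply(grids, inherits, logical(1), "coupling_grid")))
  g0 <- grids[[1]]
  vals <- Reduce(`+`, lapply(grids, `[[`, "values")) / length(grids)
  structure(
    list(values = vals, phi = g0$phi, direction = g0$direction,
         component = g0$component),
    class = "coupling_grid"
  )
}

#' @export
print.coupling_grid <- function(x, ...) {
  cat(sprintf(
    "<coupling_grid> %s: %s -> %s, %d x %d, range [%.3g, %.3g] 1/s\n",
    x$component, x$direction[1], x$direction[2],
    nrow(x$values), ncol(x$values), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Convert a coupling grid to a long tibble
#' @param x A `coupling_grid`.
#' @param ... Unused.
#' @return A tibble with columns `phi_to` (target phase), `phi_from`
#'   (driver phase) and `value` (1/s).
#' @export
as_tibble.coupling_grid <- function(x, ...) {
  tibble::tibble(
    phi_to = rep(x$phi, times = length(x$phi)),
    phi_from = rep(x$phi, each = length(x$phi)),
    value = as.vector(x$values)
  )
}
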