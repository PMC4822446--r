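#' Inference configuration
#'
#' Settings for the dynamical Bayesian inference of the coupled phase model.
#'
#' @param window_s Window length in seconds for [infer_sequence()].
#'   Default 50 s — at least 40 cycles of the slowest cortical rhythm while
#'   leaving room for time variability.
#' @param prop_const Prior-propagation constant (dimensionless diffusion of
#'   the parameters between consecutive windows); 0 means full memory.
#'   Default 0.2.
#' @param max_iter Maximum iterations of the alternating noise/parameter
#'   update. Default 100.
#' @param tol Relative convergence tolerance on the parameter vector and the
#'   noise matrix jointly. Default 1e-6.
#' @param basis A [fourier_basis()]; default order 2.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(window_s = 50, prop_const = 0.2, max_iter = 100,
                             tol = 1e-6, basis = fourier_basis(2)) {
  stopifnot(window_s > 0, prop_const >= 0, max_iter >= 1, tol > 0)
  assert_basis(basis)
  structure(list(window_s = window_s, prop_const = prop_const,
                 max_iter = max_iter, tol = tol, basis = basis),
            class = "inference_config")
}

#' Non-informative prior
#'
#' Zero parameter mean with concentration `eps * I`: numerically safe and
#' effectively flat relative to any data-driven concentration.
#'
#' @param basis A [fourier_basis()].
#' @param eps Prior concentration scale. Default 1e-8.
#' @return A list with `c` (length `2 * nrow(basis)`) and `Xi`.
#' @export
flat_prior <- function(basis, eps = 1e-8) {
  assert_basis(basis)
  M2 <- 2L * nrow(basis)
  list(c = numeric(M2), Xi = diag(eps, M2))
}

new_posterior <- function(c, Xi, Sigma, D, basis, rate, n_samples,
                          labels, window_index = 1L, converged = TRUE,
                          iterations = NA_integer_) {
  structure(
    list(c = c, Xi = Xi, Sigma = Sigma, D = D, basis = basis, rate = rate,
         n_samples = n_samples, labels = labels,
         window_index = window_index, converged = converged,
         iterations = iterations),
    class = "posterior"
  )
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf(
    "<posterior> window %d: %d params (K = %d), N = %d, D = [%.3g, %.3g], %s\n",
    x$window_index, length(x$c), attr(x$basis, "K"), x$n_samples,
    x$D[1, 1], x$D[2, 2],
    if (x$converged) sprintf("converged in %d it.", x$iterations)
    else "NOT converged"
  ))
  invisible(x)
}

# Index block of oscillator eq (1 or 2) in the concatenated parameter vector.
eq_block <- function(basis, eq) {
  M <- nrow(basis)
  (eq - 1L) * M + seq_len(M)
}

#' Bayesian inference of coupled phase dynamics for one window
#'
#' Fits the coupled stochastic phase model to a pair of unwrapped phase
#' series by recursive Bayesian inference. Phase velocities are estimated by
#' two-point finite differences \eqn{(\phi_{n+1} - \phi_n)/h} with the basis
#' evaluated at the midpoint phases (keeping the Stratonovich drift
#' correction consistent), and the posterior is obtained by alternating two
#' closed-form updates until joint convergence of the parameters and the
#' noise matrix:
#' \deqn{D = \frac{h}{N} \sum_n (\dot\phi_n - c\,\Phi_n)(\dot\phi_n - c\,\Phi_n)^T,}
#' \deqn{r_w = (\Xi^{(0)} c^{(0)})_w + h\,\Phi_w(D^{-1}\dot\phi)_n
#'   - \frac{h}{2} \sum_n \frac{\partial \Phi_w}{\partial \phi},\qquad
#'   \Xi_{kw} = \Xi^{(0)}_{kw} + h\,\Phi_k D^{-1} \Phi_w,\qquad
#'   c = \Xi^{-1} r.}
#' Both phase equations are inferred jointly (shared 2x2 noise matrix), so
#' the parameter vector concatenates the two equations' coefficients in
#' basis order.
#'
#' @param phi1,phi2 [phase_series()] objects of equal length and rate
#'   (unwrapped phases).
#' @param prior A list with elements `c` and `Xi` (e.g. [flat_prior()] or
#'   [propagate_prior()] output). Default: flat prior.
#' @param config An [inference_config()].
#' @return A `posterior` object: parameter mean `c`, concentration `Xi`,
#'   covariance `Sigma`, noise matrix `D`, plus bookkeeping fields.
#' @export
infer_window <- function(phi1, phi2, prior = NULL,
                         config = inference_config()) {
  stopifnot(inherits(phi1, "phase_series"), inherits(phi2, "phase_series"))
  if (length(phi1$phi) != length(phi2$phi)) {
    stopf("Phase series must have equal length (%d vs %d).",
          length(phi1$phi), length(phi2$phi))
  }
  if (abs(phi1$rate - phi2$rate) > 1e-9) {
    stopf("Phase series must share one sampling rate.")
  }
  basis <- config$basis
  M <- nrow(basis)
  if (length(phi1$phi) < 10L * M) {
    stopf("Need at least %d samples for a %d-term basis (got %d).",
          10L * M, M, length(phi1$phi))
  }
  if (is.null(prior)) prior <- flat_prior(basis)

  h <- 1 / phi1$rate
  p1 <- phi1$phi; p2 <- phi2$phi
  N <- length(p1) - 1L
  X1 <- diff(p1) / h
  X2 <- diff(p2) / h
  m1 <- (p1[-1] + p1[-length(p1)]) / 2
  m2 <- (p2[-1] + p2[-length(p2)]) / 2

  P1 <- evaluate_basis(basis, m1, m2)
  P2 <- evaluate_basis(basis, m2, m1)
  rc1 <- (h / 2) * colSums(evaluate_basis_dphi(basis, m1, m2))
  rc2 <- (h / 2) * colSums(evaluate_basis_dphi(basis, m2, m1))

  G11 <- crossprod(P1)
  G22 <- crossprod(P2)
  G12 <- crossprod(P1, P2)
  u11 <- crossprod(P1, X1); u12 <- crossprod(P1, X2)
  u21 <- crossprod(P2, X1); u22 <- crossprod(P2, X2)

  Xi0c0 <- prior$Xi %*% prior$c
  i1 <- eq_block(basis, 1L); i2 <- eq_block(basis, 2L)

  cvec <- prior$c
  D <- diag(2)
  Xi <- NULL
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    e1 <- X1 - P1 %*% cvec[i1]
    e2 <- X2 - P2 %*% cvec[i2]
    D_new <- (h / N) * crossprod(cbind(e1, e2))
    D_new <- (D_new + t(D_new)) / 2
    # floor tiny/zero noise (noise-free data) so D stays invertible
    ev <- eigen(D_new, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-12)
    D_new <- ev$vectors %*% diag(ev$values, 2) %*% t(ev$vectors)
    Dinv <- solve(D_new)

    Xi <- prior$Xi
    Xi[i1, i1] <- Xi[i1, i1] + h * Dinv[1, 1] * G11
    Xi[i1, i2] <- Xi[i1, i2] + h * Dinv[1, 2] * G12
    Xi[i2, i1] <- Xi[i2, i1] + h * Dinv[2, 1] * t(G12)
    Xi[i2, i2] <- Xi[i2, i2] + h * Dinv[2, 2] * G22
    r <- as.numeric(Xi0c0)
    r[i1] <- r[i1] + h * (Dinv[1, 1] * u11 + Dinv[1, 2] * u12) - rc1
    r[i2] <- r[i2] + h * (Dinv[2, 1] * u21 + Dinv[2, 2] * u22) - rc2

    c_new <- tryCatch(
      solve(Xi, r),
      error = function(e) {
        warnf("Concentration matrix singular; ridge regularization applied.")
        solve(Xi + diag(1e-8 * mean(diag(Xi)), nrow(Xi)), r)
      }
    )

    dc <- max(abs(c_new - cvec)) / (max(abs(c_new)) + 1e-12)
    dD <- max(abs(D_new - D)) / (max(abs(D_new)) + 1e-12)
    cvec <- as.numeric(c_new)
    D <- D_new
    if (it > 1L && dc < config$tol && dD < config$tol) {
      converged <- TRUE
      break
    }
    if (it >= config$max_iter) break
  }
  if (!converged) {
    warnf("infer_window: not converged after %d iterations (last relative change %.2g).",
          it, max(dc, dD))
  }
  Sigma <- tryCatch(solve(Xi), error = function(e) {
    solve(Xi + diag(1e-8 * mean(diag(Xi)), nrow(Xi)))
  })
  new_posterior(cvec, Xi, Sigma, D, basis, phi1$rate, N,
                labels = c(phi1$band, phi2$band),
                converged = converged, iterations = it)
}

#' Propagate a posterior into the next window's prior
#'
#' Implements the information-propagation step that allows the inference to
#' follow time-varying parameters: the next window's prior keeps the
#' posterior mean, while each parameter's variance is inflated by a
#' diffusion term proportional to its squared magnitude,
#' \deqn{\Sigma^{prior} = \Sigma^{post} + p_w^2\,\mathrm{diag}(c^2).}
#' With `prop_const = 0` the posterior is passed on unchanged (full memory);
#' large values discard accumulated information (each window approaches an
#' independent flat-prior fit).
#'
#' @param post A `posterior` from [infer_window()].
#' @param prop_const Propagation constant \eqn{p_w \ge 0}.
#' @return A list with `c` and `Xi`, usable as `prior` in [infer_window()].
#' @export
propagate_prior <- function(post, prop_const = 0.2) {
  stopifnot(inherits(post, "posterior"), prop_const >= 0)
  Sigma_prior <- post$Sigma + diag(prop_const^2 * post$c^2,
                                   length(post$c))
  Xi_prior <- tryCatch(solve(Sigma_prior), error = function(e) {
    solve(Sigma_prior + diag(1e-12 * mean(diag(Sigma_prior)),
                             nrow(Sigma_prior)))
  })
  list(c = post$c, Xi = Xi_prior)
}

#' Windowed inference over a full recording
#'
#' Splits the pair of phase series into non-overlapping windows of
#' `config$window_s` seconds, infers each window with [infer_window()], and
#' propagates each posterior into the next window's prior via
#' [propagate_prior()]. The first window starts from a flat prior. A
#' trailing partial window is discarded (with a message).
#'
#' @inheritParams infer_window
#' @param config An [inference_config()].
#' @return A list of `posterior` objects, one per full window, with
#'   `window_index` set.
#' @export
infer_sequence <- function(phi1, phi2, config = inference_config()) {
  stopifnot(inherits(phi1, "phase_series"), inherits(phi2, "phase_series"))
  n <- min(length(phi1$phi), length(phi2$phi))
  win_n <- round(config$window_s * phi1$rate)
  n_win <- n %/% win_n
  if (n_win < 2L) {
    stopf("Need at least 2 full windows of %g s (have %.1f s).",
          config$window_s, n / phi1$rate)
  }
  if (n %% win_n != 0L) {
    message(sprintf("Discarding trailing partial window (%.1f s).",
                    (n %% win_n) / phi1$rate))
  }
  prior <- flat_prior(config$basis)
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * win_n + 1L):(w * win_n)
    sub1 <- phase_series(phi1$phi[idx], phi1$rate, band = phi1$band,
                         kind = phi1$kind, t0 = phi1$t0 + (idx[1] - 1) / phi1$rate)
    sub2 <- phase_series(phi2$phi[idx], phi2$rate, band = phi2$band,
                         kind = phi2$kind, t0 = sub1$t0)
    post <- infer_window(sub1, sub2, prior = prior, config = config)
    post$window_index <- w
    out[[w]] <- post
    prior <- propagate_prior(post, config$prop_const)
  }
  out
}
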