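# Shared helpers: small simulation wrappers and independent oracles.

# Circular RMS of a phase error after removing the circular mean offset.
circ_rms <- function(err) {
  z <- exp(1i * err)
  offset <- Arg(mean(z))
  sqrt(mean(Arg(exp(1i * (err - offset)))^2))
}

# Simulate the reference coupled pair: oscillator x at f1 Hz driven by
# a * sin(phi_y) from oscillator y at f2 Hz, equal dynamical noise D.
sim_pair <- function(a = 0.4, D = 0.01, f1 = 1.0, f2 = 0.27,
                     duration = 400, seed = 1, out_rate = NULL) {
  specs <- list(
    oscillator_spec(2 * pi * f1, noise_strength = D, label = "x",
                    couplings = if (a != 0) {
                      coupling_term("y", k = 0, l = 1, kind = "sin",
                                    coeff = a)
                    } else NULL),
    oscillator_spec(2 * pi * f2, noise_strength = D, label = "y")
  )
  simulate_phases(specs, sim_config(duration = duration, seed = seed,
                                    out_rate = out_rate))
}

# Independent enumeration of the order-K basis term list (constant first,
# representatives with k > 0 or (k = 0, l > 0) in lexicographic (k, l)
# order, sin before cos), written without the package's basis code.
enumerate_terms <- function(K) {
  terms <- list(list(k = 0L, l = 0L, kind = "constant"))
  if (K > 0) {
    for (k in 0:K) {
      for (l in -K:K) {
        if (k == 0L && l <= 0L) next
        terms <- c(terms, list(list(k = k, l = l, kind = "sin"),
                               list(k = k, l = l, kind = "cos")))
      }
    }
  }
  terms
}

# Independent ordinary-least-squares fit of finite-difference phase
# velocities on the order-K basis (midpoint evaluation), one equation per
# oscillator. Returns the two coefficient vectors, in basis order.
ols_oracle <- function(phi1, phi2, rate, K = 2) {
  h <- 1 / rate
  v1 <- diff(phi1) / h
  v2 <- diff(phi2) / h
  m1 <- (phi1[-1] + phi1[-length(phi1)]) / 2
  m2 <- (phi2[-1] + phi2[-length(phi2)]) / 2
  design <- function(pi_, pj_) {
    cols <- lapply(enumerate_terms(K), function(tm) {
      arg <- tm$k * pi_ + tm$l * pj_
      switch(tm$kind, constant = rep(1, length(pi_)),
             sin = sin(arg), cos = cos(arg))
    })
    do.call(cbind, cols)
  }
  B1 <- design(m1, m2)
  B2 <- design(m2, m1)
  list(c1 = qr.solve(B1, v1), c2 = qr.solve(B2, v2))
}

# Coefficient estimate of the sin(0*phi_own + 1*phi_other) term of
# equation `eq` from a posterior.
planted_coef <- function(post, eq = 1L) {
  b <- post$basis
  idx <- which(b$k == 0L & b$l == 1L & b$kind == "sin")
  post$c[(eq - 1L) * nrow(b) + idx]
}

# Simulate a piecewise-stationary coupled pair whose driving coefficient
# takes value `a_vec[i]` during segment i, chaining initial phases so the
# trajectory is continuous. Returns the two concatenated phase series.
sim_ramp <- function(a_vec, segment_s, D = 0.01, f1 = 1.0, f2 = 0.27,
                     rate = 40, seed = 1) {
  set.seed(seed)
  phi0 <- runif(2, 0, 2 * pi)
  px <- numeric(0); py <- numeric(0)
  for (i in seq_along(a_vec)) {
    sim <- simulate_phases(
      list(
        oscillator_spec(2 * pi * f1, noise_strength = D, label = "x",
                        couplings = if (a_vec[i] != 0) {
                          coupling_term("y", 0, 1, "sin", a_vec[i])
                        } else NULL),
        oscillator_spec(2 * pi * f2, noise_strength = D, label = "y")
      ),
      sim_config(duration = segment_s, out_rate = rate),
      phi0 = phi0
    )
    nx <- length(sim$phases$x$phi)
    phi0 <- c(sim$phases$x$phi[nx], sim$phases$y$phi[nx])
    drop_first <- if (i == 1L) 0L else 1L
    px <- c(px, sim$phases$x$phi[(1 + drop_first):nx])
    py <- c(py, sim$phases$y$phi[(1 + drop_first):nx])
  }
  list(x = phase_series(px, rate, band = "x"),
       y = phase_series(py, rate, band = "y"))
}
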