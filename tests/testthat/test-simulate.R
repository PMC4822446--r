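test_that("deterministic uncoupled oscillator advances linearly", {
  specs <- list(
    oscillator_spec(2 * pi, label = "x"),
    oscillator_spec(2 * pi * 0.3, label = "y")
  )
  sim <- simulate_phases(specs, sim_config(duration = 20, seed = 1))
  tt <- (seq_along(sim$phases$x$phi) - 1) / sim$phases$x$rate
  expect_equal(sim$phases$x$phi, sim$phases$x$phi[1] + 2 * pi * tt,
               tolerance = 1e-9)
  expect_equal(sim$phases$y$phi, sim$phases$y$phi[1] + 2 * pi * 0.3 * tt,
               tolerance = 1e-9)
})

test_that("phase variance grows linearly with slope D (Brownian scaling)", {
  D <- 0.1
  n_rep <- 500
  dur <- 20
  devs <- matrix(NA_real_, nrow = n_rep * 2, ncol = 2)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    specs <- list(oscillator_spec(2 * pi, noise_strength = D, label = "x"),
                  oscillator_spec(2 * pi, noise_strength = D, label = "y"))
    sim <- simulate_phases(specs, sim_config(duration = dur),
                           phi0 = c(0, 0))
    for (k in 1:2) {
      p <- sim$phases[[k]]
      tt <- (seq_along(p$phi) - 1) / p$rate
      dev <- p$phi - 2 * pi * tt
      half <- length(dev) %/% 2
      devs[(r - 1) * 2 + k, ] <- c(dev[half], dev[length(dev)])
    }
  }
  t_half <- dur / 2
  expect_equal(var(devs[, 1]), D * t_half, tolerance = 0.1)
  expect_equal(var(devs[, 2]), D * dur, tolerance = 0.1)
})

test_that("diffusive coupling above the Adler threshold phase-locks the pair", {
  # phase difference has a stable fixed point iff a > |omega1 - omega2|
  dw <- 2 * pi * 0.1
  specs <- list(
    oscillator_spec(2 * pi * 1.0, label = "x",
                    couplings = coupling_term("y", k = -1, l = 1,
                                              kind = "sin", coeff = 1.5)),
    oscillator_spec(2 * pi * 1.1, label = "y")
  )
  stopifnot(1.5 > dw)
  sim <- simulate_phases(specs, sim_config(duration = 100, seed = 3))
  dphi <- sim$phases$y$phi - sim$phases$x$phi
  expect_lt(max(dphi) - min(dphi), 2 * pi)
})

test_that("simulation is reproducible and trajectories are well-behaved", {
  s1 <- sim_pair(seed = 5)
  s2 <- sim_pair(seed = 5)
  expect_identical(s1$phases$x$phi, s2$phases$x$phi)
  expect_identical(s1$phases$y$phi, s2$phases$y$phi)

  p <- s1$phases$x
  expect_true(all(is.finite(p$phi)))
  # increments bounded: no artificial 2*pi jumps
  dt <- 1 / p$rate
  max_drift <- dt * (2 * pi * 1.0 + 0.4)
  expect_lt(max(abs(diff(p$phi))), max_drift + 6 * sqrt(dt * 0.01) + 1e-9)

  expect_error(
    simulate_phases(
      list(oscillator_spec(2 * pi * 10, label = "x"),
           oscillator_spec(2 * pi, label = "y")),
      sim_config(duration = 10, dt = 0.05)
    ),
    "too large"
  )
})

test_that("rendered channels have the right spectral content", {
  f <- 1.3
  specs <- list(oscillator_spec(2 * pi * f, label = "x"),
                oscillator_spec(2 * pi * 0.4, label = "y"))
  sim <- simulate_phases(specs, sim_config(duration = 60, out_rate = 50,
                                           seed = 2))
  rec <- render_signals(sim$phases, list(a = "x"), out_rate = 50)
  sp <- Mod(fft(rec$a))^2
  freqs <- (seq_along(sp) - 1) * 50 / length(sp)
  half <- freqs <= 25
  peak <- freqs[half][which.max(sp[half])]
  expect_lt(abs(peak - f), 50 / length(sp) + 1e-9)

  # zero amplitude leaves a pure noise channel
  rec0 <- render_signals(sim$phases, list(a = "x"), amplitudes = 0,
                         measurement_noise_sd = 0.5, out_rate = 50)
  expect_equal(sd(rec0$a), 0.5, tolerance = 0.1)

  expect_error(render_signals(sim$phases, list(a = "x"), out_rate = 2),
               "undersampled")
})

test_that("render then preprocess recovers the simulated phase", {
  specs <- list(
    oscillator_spec(2 * pi * 1.5, noise_strength = 0.1, label = "delta"),
    oscillator_spec(2 * pi * 10, noise_strength = 0.1, label = "alpha")
  )
  sim <- simulate_phases(specs, sim_config(duration = 120, out_rate = 300,
                                           seed = 4))
  rec <- render_signals(sim$phases, list(eeg = c("delta", "alpha")),
                        measurement_noise_sd = 0.1, out_rate = 300)
  for (b in c("delta", "alpha")) {
    ph <- extract_phase(rec, b, rate = 300, col = "eeg")
    i0 <- round(ph$t0 * 300)
    truth <- sim$phases[[b]]$phi[(i0 + 1):(i0 + length(ph$phi))]
    expect_lt(circ_rms(ph$phi - truth), 0.1)
  }
})

test_that("cohorts are reproducible, carry ground truth and round-trip to disk", {
  tpl <- tibble::tibble(group = c("A", "S"), from = "delta", to = "alpha",
                        strength = c(0.1, 0.5))
  c1 <- make_cohort(tpl, n_subjects = 2, duration = 30, rate = 200, seed = 7)
  c2 <- make_cohort(tpl, n_subjects = 2, duration = 30, rate = 200, seed = 7)
  expect_identical(c1$recordings, c2$recordings)
  expect_equal(nrow(c1$subjects), 4L)
  expect_false(anyDuplicated(c1$subjects$seed) > 0)

  tr <- c1$truth[["S01"]]
  expect_s3_class(tr$specs[[1]], "oscillator_spec")
  expect_equal(tr$planted$from, "delta")
  expect_true(all(tr$planted$strength >= 0))

  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  back <- read_cohort(dir)
  expect_equal(back$rate, 200)
  expect_equal(sort(names(back$recordings)), sort(names(c1$recordings)))
  expect_equal(back$recordings[["A01"]]$eeg, c1$recordings[["A01"]]$eeg,
               tolerance = 1e-12)

  expect_error(make_cohort(tpl[0, ], n_subjects = 2), "non-empty")
  expect_error(make_cohort(tpl, n_subjects = 1), ">= 2")
})

test_that("planted group differences are recovered; equal groups are not flagged", {
  tpl_diff <- tibble::tibble(group = c("A", "S"), from = "delta",
                             to = "alpha", strength = c(0.1, 0.5))
  tpl_null <- tibble::tibble(group = c("A", "S"), from = "delta",
                             to = "alpha", strength = c(0.3, 0.3))
  run_rep <- function(tpl, seed) {
    coh <- make_cohort(tpl, n_subjects = 5, duration = 100, rate = 200,
                       spread = 0.05, seed = seed)
    strengths <- purrr::map_dfr(names(coh$truth), function(sid) {
      ph <- coh$truth[[sid]]$phases
      pa <- resample_phase(ph$alpha, 107.5)
      pd <- resample_phase(ph$delta, 107.5)
      post <- suppressWarnings(infer_window(pa, pd))
      tibble::tibble(
        group = coh$subjects$group[coh$subjects$subject == sid],
        strength = coupling_strength(post, c("delta", "alpha"))
      )
    })
    group_compare(strengths, pair = c("A", "S"))$significant
  }
  hits_diff <- sum(vapply(1:8, function(s) run_rep(tpl_diff, s), logical(1)))
  hits_null <- sum(vapply(1:8, function(s) run_rep(tpl_null, 100 + s),
                          logical(1)))
  expect_gte(hits_diff, 7)
  expect_lte(hits_null, 2)
})
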