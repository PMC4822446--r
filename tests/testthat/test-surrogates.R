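test_that("cycle-permutation surrogates preserve rhythm statistics", {
  sim <- sim_pair(a = 0, D = 0.05, duration = 200, seed = 41, out_rate = 20)
  p <- sim$phases$y
  surr <- intra_surrogate(p, n = 5, seed = 1)

  for (s in surr) {
    expect_length(s$phi, length(p$phi))
    # multiset of cycle durations preserved (re-detected crossings can
    # shift by one sample at block joins)
    cyc_lens <- function(q) {
      m <- floor((q$phi - q$phi[1]) / (2 * pi))
      tabulate(m[m >= 1 & m <= max(m) - 1])
    }
    expect_lte(max(abs(sort(cyc_lens(s)) - sort(cyc_lens(p)))), 2)
    # wrapped sample distribution preserved exactly (offsets are 2*pi
    # multiples)
    expect_equal(sort(wrap_phase(s$phi)), sort(wrap_phase(p$phi)),
                 tolerance = 1e-9)
    # mean frequency within 1%
    f0 <- (p$phi[length(p$phi)] - p$phi[1])
    fs <- (s$phi[length(s$phi)] - s$phi[1])
    expect_lt(abs(fs - f0) / f0, 0.01)
  }

  # reproducibility under a fixed seed
  s1 <- intra_surrogate(p, n = 3, seed = 9)
  s2 <- intra_surrogate(p, n = 3, seed = 9)
  expect_identical(lapply(s1, `[[`, "phi"), lapply(s2, `[[`, "phi"))

  # degenerate linear phase with commensurate sampling: surrogate == original
  lin <- phase_series(2 * pi * (0:479) / 16, 16)
  slin <- intra_surrogate(lin, n = 2, seed = 2)
  expect_equal(slin[[1]]$phi, lin$phi, tolerance = 1e-9)

  short <- phase_series(2 * pi * seq(0, 5, by = 0.05), 20)
  expect_error(intra_surrogate(short, 2), "20 full cycles")
})

test_that("surrogates destroy genuine coupling", {
  # strongly coupled pair: median surrogate strength well below genuine
  ok <- 0L
  for (s in 1:6) {
    specs <- list(
      oscillator_spec(2 * pi * 1.0, noise_strength = 0.05, label = "x",
                      couplings = coupling_term("y", 0, 1, "sin", 0.5)),
      oscillator_spec(2 * pi * 0.27, noise_strength = 0.1, label = "y")
    )
    sim <- simulate_phases(specs, sim_config(duration = 300, seed = 700 + s,
                                             out_rate = 16))
    genuine <- coupling_strength(
      infer_window(sim$phases$x, sim$phases$y), c("y", "x")
    )
    surr <- intra_surrogate(sim$phases$y, n = 19, seed = s)
    s_str <- vapply(surr, function(sd_) {
      coupling_strength(infer_window(sim$phases$x, sd_), c("y", "x"))
    }, numeric(1))
    ok <- ok + (median(s_str) < 0.5 * genuine)
  }
  expect_gte(ok, 5L)
})

test_that("inter-subject surrogates pair responses with other subjects' drivers", {
  sims <- lapply(1:4, function(s) {
    sim_pair(a = 0, D = 0.05, duration = 100, seed = 800 + s, out_rate = 20)
  })
  resp <- sims[[1]]$phases$x
  pool <- lapply(sims[2:4], function(s) s$phases$y)
  surr <- inter_surrogate(resp, pool, n = 6, seed = 3)
  expect_length(surr, 6L)
  for (s in surr) {
    expect_equal(length(s$driver$phi), length(s$response$phi))
    expect_true(any(vapply(pool, function(d) {
      isTRUE(all.equal(d$phi[seq_along(s$driver$phi)], s$driver$phi))
    }, logical(1))))
  }

  expect_warning(inter_surrogate(resp, pool[1], n = 3, seed = 1),
                 "single subject")
  expect_error(inter_surrogate(resp, c(pool, list(resp)), n = 3),
               "must not appear")
  expect_error(inter_surrogate(resp, list(), n = 3), "non-empty")
})

test_that("intra- and inter-subject surrogate strengths agree under the null", {
  sims <- lapply(1:6, function(s) {
    sim_pair(a = 0, D = 0.05, duration = 200, seed = 900 + s, out_rate = 16)
  })
  agree <- 0L
  for (i in 1:3) {
    resp <- sims[[i]]$phases$x
    intra <- intra_surrogate(sims[[i]]$phases$y, n = 19, seed = i)
    pool <- lapply(sims[-i], function(s) s$phases$y)
    inter <- inter_surrogate(resp, pool, n = 19, seed = i)
    st_intra <- vapply(intra, function(d) {
      n <- min(length(d$phi), length(resp$phi))
      coupling_strength(infer_window(
        phase_series(resp$phi[1:n], resp$rate, band = "x"),
        phase_series(d$phi[1:n], d$rate, band = "y")
      ), c("y", "x"))
    }, numeric(1))
    st_inter <- vapply(inter, function(pr) {
      coupling_strength(infer_window(pr$response, pr$driver),
                        c(pr$driver$band, pr$response$band))
    }, numeric(1))
    p <- wilcox.test(st_intra, st_inter, exact = FALSE)$p.value
    agree <- agree + (p > 0.05)
  }
  expect_gte(agree, 2L)
})

test_that("the mean + 2SD significance rule is calibrated", {
  ens <- surrogate_ensemble(abs(rnorm(50, 0.1, 0.01)), kind = "intra")
  res <- significance_vs_surrogates(2 * max(ens$strengths), ens)
  expect_true(res$significant)
  expect_equal(res$threshold, mean(ens$strengths) + 2 * sd(ens$strengths))

  # genuine drawn from the surrogate distribution itself: flagged at
  # roughly the Gaussian tail rate of the mean + 2SD rule
  set.seed(5)
  hits <- 0L
  for (r in 1:1000) {
    s <- rnorm(100, 0.2, 0.03)
    g <- rnorm(1, 0.2, 0.03)
    hits <- hits + (g > mean(s) + 2 * sd(s))
  }
  expect_gt(hits / 1000, 0.005)
  expect_lt(hits / 1000, 0.05)

  # percentile alternative
  resp <- significance_vs_surrogates(0.3, ens, rule = "percentile")
  expect_equal(resp$rule, "percentile")
  expect_error(surrogate_ensemble(rep(0.1, 10)), "19")
})

test_that("group comparison flags real differences and not identical samples", {
  same <- tibble::tibble(group = rep(c("A", "B"), each = 5),
                         strength = rep(1:5 / 10, 2))
  res <- group_compare(same, pair = c("A", "B"))
  expect_false(res$significant)

  # degenerate all-equal samples
  flat <- tibble::tibble(group = rep(c("A", "B"), each = 3), strength = 1)
  expect_warning(resf <- group_compare(flat, pair = c("A", "B")),
                 "degenerate")
  expect_equal(resf$p_value, 1)

  # N(0,1) vs N(2,1), n = 15: significant in >= 95% of replicates
  set.seed(6)
  hits <- 0L
  for (r in 1:200) {
    df <- tibble::tibble(group = rep(c("A", "B"), each = 15),
                         strength = c(rnorm(15), rnorm(15, 2)))
    hits <- hits + group_compare(df, pair = c("A", "B"))$significant
  }
  expect_gte(hits / 200, 0.95)

  # descriptives are the boxplot statistics
  df <- tibble::tibble(group = rep(c("A", "B"), each = 7),
                       strength = c(1:7, 11:17) / 10)
  d <- group_compare(df, pair = c("A", "B"))$descriptives[[1]]
  expect_equal(d$median, c(0.4, 1.4))
  expect_equal(d$min, c(0.1, 1.1))
  expect_equal(d$max, c(0.7, 1.7))

  # paired variant runs and respects pairing
  dfp <- tibble::tibble(group = rep(c("pre", "post"), each = 10),
                        strength = c(rnorm(10), rnorm(10, 1)))
  resp <- group_compare(dfp, pair = c("pre", "post"), paired = TRUE)
  expect_true(is.finite(resp$p_value))
})
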