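test_that("coupling grids match closed forms and decompose linearly", {
  b <- fourier_basis(2)

  # all-zero coefficients give a flat zero grid
  g0 <- coupling_function_grid(numeric(25), component = "net", grid_n = 32,
                               basis = b)
  expect_true(all(g0$values == 0))

  # single direct term 0.4 sin(phi_j)
  cf <- numeric(25)
  cf[b$k == 0 & b$l == 1 & b$kind == "sin"] <- 0.4
  gnet <- coupling_function_grid(cf, component = "net", grid_n = 64, basis = b)
  gdir <- coupling_function_grid(cf, component = "direct", grid_n = 64,
                                 basis = b)
  gind <- coupling_function_grid(cf, component = "indirect", grid_n = 64,
                                 basis = b)
  expect_equal(max(gnet$values), 0.4, tolerance = 1e-3)
  j_max <- which.max(gnet$values[1, ])
  expect_equal(gnet$phi[j_max], pi / 2, tolerance = 2 * pi / 64 + 1e-9)
  expect_lt(max(apply(gnet$values, 2, sd)), 1e-12)  # constant along phi_i
  expect_equal(gnet$values, gdir$values)
  expect_true(all(gind$values == 0))

  # linearity: net = direct + indirect for random coefficients
  set.seed(21)
  for (r in 1:5) {
    cf <- rnorm(25)
    gn <- coupling_function_grid(cf, component = "net", grid_n = 32, basis = b)
    gd <- coupling_function_grid(cf, component = "direct", grid_n = 32,
                                 basis = b)
    gi <- coupling_function_grid(cf, component = "indirect", grid_n = 32,
                                 basis = b)
    expect_lt(max(abs(gn$values - gd$values - gi$values)), 1e-12)
    expect_lt(abs(mean(gn$values)), 1e-9 * max(abs(gn$values)))
  }

  expect_error(coupling_function_grid(numeric(25), grid_n = 4, basis = b),
               "at least 8")
})

test_that("coupling strength is the Euclidean norm with a Pythagorean split", {
  b <- fourier_basis(2)
  expect_equal(coupling_strength(numeric(25), basis = b), 0)

  # direct coefficients (0.3, 0.4), indirect zero
  cf <- numeric(25)
  cf[b$k == 0 & b$l == 1 & b$kind == "sin"] <- 0.3
  cf[b$k == 0 & b$l == 2 & b$kind == "cos"] <- 0.4
  expect_equal(coupling_strength(cf, component = "direct", basis = b), 0.5)
  expect_equal(coupling_strength(cf, component = "net", basis = b), 0.5)
  expect_equal(coupling_strength(cf, component = "indirect", basis = b), 0)

  # net^2 = direct^2 + indirect^2 for random vectors
  set.seed(22)
  for (r in 1:20) {
    cf <- rnorm(25)
    nn <- coupling_strength(cf, component = "net", basis = b)
    dd <- coupling_strength(cf, component = "direct", basis = b)
    ii <- coupling_strength(cf, component = "indirect", basis = b)
    expect_equal(nn^2, dd^2 + ii^2, tolerance = 1e-12)
  }
})

test_that("grid RMS is coherent with the coefficient norm (Parseval)", {
  b <- fourier_basis(2)
  set.seed(23)
  for (r in 1:5) {
    cf <- numeric(25)
    pick <- sample(which(b$l != 0), 1)
    cf[pick] <- runif(1, 0.2, 1)
    g <- coupling_function_grid(cf, component = "net", grid_n = 128,
                                basis = b)
    expect_equal(sqrt(mean(g$values^2)), abs(cf[pick]) / sqrt(2),
                 tolerance = 1e-3)
  }
})

test_that("similarity rho is a scale-free bounded correlation of coupling terms", {
  b <- fourier_basis(2)
  set.seed(24)
  a <- rnorm(25)
  expect_equal(similarity_rho(a, a), 1)
  expect_equal(similarity_rho(a, 2 * a), 1)

  # disjoint-support sparse vectors: direct formula oracle on the
  # 20-element coupling subvectors
  sel <- which(b$l != 0)
  va <- numeric(25); vb <- numeric(25)
  va[b$k == 0 & b$l == 1 & b$kind == "sin"] <- 1
  vb[b$k == 0 & b$l == 1 & b$kind == "cos"] <- 1
  expect_equal(similarity_rho(va, vb), cor(va[sel], vb[sel]))

  for (r in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    rho <- similarity_rho(x, y)
    expect_true(rho >= -1 && rho <= 1)
    expect_equal(rho, similarity_rho(y, x))
    expect_equal(rho, similarity_rho(3.7 * x, 0.2 * y), tolerance = 1e-12)
  }

  expect_message(rho0 <- similarity_rho(rep(1, 25), a), "zero-variance")
  expect_true(is.na(rho0))
  expect_error(similarity_rho(a, a[1:10]), "equal length")
})

test_that("subject summaries aggregate windows and identify the predominant direction", {
  # single window: summary equals that window's values
  sim <- sim_pair(a = 0.4, D = 0.01, duration = 150, seed = 31)
  post <- infer_window(sim$phases$x, sim$phases$y)
  smry <- subject_summary(post, subject = "s1")
  expect_equal(nrow(smry), 2L)
  row_xy <- smry[smry$from == "y" & smry$to == "x", ]
  expect_equal(row_xy$net, coupling_strength(post, c("y", "x")))
  expect_equal(row_xy$noise_to, post$D[1, 1])
  expect_true(row_xy$predominant)

  # stationary windowed run recovers the planted norm
  sim2 <- sim_pair(a = 0.4, D = 0.01, duration = 400, seed = 32)
  posts <- suppressMessages(infer_sequence(sim2$phases$x, sim2$phases$y,
                                           inference_config(window_s = 100)))
  smry2 <- subject_summary(posts)
  expect_equal(smry2$net[smry2$to == "x"], 0.4, tolerance = 0.05)
  expect_equal(smry2$n_windows[1], 4L)

  # planted 0.4 vs 0.05 asymmetry: predominant direction identified
  hits <- 0L
  for (s in 1:20) {
    specs <- list(
      oscillator_spec(2 * pi, noise_strength = 0.01, label = "x",
                      couplings = coupling_term("y", 0, 1, "sin", 0.4)),
      oscillator_spec(2 * pi * 0.27, noise_strength = 0.01, label = "y",
                      couplings = coupling_term("x", 0, 1, "sin", 0.05))
    )
    sim3 <- simulate_phases(specs, sim_config(duration = 150, seed = 600 + s))
    smry3 <- subject_summary(infer_window(sim3$phases$x, sim3$phases$y))
    hits <- hits + (smry3$to[smry3$predominant][1] == "x")
  }
  expect_gte(hits, 19L)
})

test_that("the group-mean coupling grid equals the grid of mean coefficients", {
  b <- fourier_basis(2)
  set.seed(25)
  cfs <- lapply(1:4, function(i) rnorm(25))
  grids <- lapply(cfs, coupling_function_grid, component = "net",
                  grid_n = 32, basis = b)
  gmean <- mean_coupling_grid(grids)
  gref <- coupling_function_grid(Reduce(`+`, cfs) / 4, component = "net",
                                 grid_n = 32, basis = b)
  expect_equal(gmean$values, gref$values, tolerance = 1e-12)
})
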