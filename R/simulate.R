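#' Oscillator specification for simulation
#'
#' Describes one stochastic phase oscillator: its natural angular frequency,
#' the coupling terms entering its phase equation, and the intensity of the
#' Gaussian white dynamical noise, with autocorrelation
#' \eqn{\langle \xi(t)\xi(\tau) \rangle = \delta(t - \tau) D}. The
#' Euler–Maruyama increment used by [simulate_phases()] is
#' \eqn{\sqrt{dt \cdot D}\, \mathcal N(0,1)}, so the noise matrix estimated
#' by [infer_window()] targets `noise_strength` directly.
#'
#' @param omega Natural angular frequency (rad/s), positive.
#' @param couplings A data frame of coupling terms with columns `source`
#'   (label of the driving oscillator), `k`, `l` (integer multipliers of the
#'   oscillator's own phase and the source phase), `kind` (`"sin"` or
#'   `"cos"`) and `coeff` (1/s). `NULL` for an uncoupled oscillator.
#' @param noise_strength Dynamical noise intensity D (rad^2/s), non-negative.
#' @param label Band label (`"delta"`, `"theta"`, `"alpha"`, `"gamma"`,
#'   `"r"`, `"h"`, ...).
#' @return An object of class `oscillator_spec`.
#' @examples
#' # alpha driven by delta through 0.4 sin(phi_delta):
#' oscillator_spec(2 * pi * 10,
#'   couplings = coupling_term("delta", k = 0, l = 1, kind = "sin", coeff = 0.4),
#'   noise_strength = 0.01, label = "alpha")
#' @export
oscillator_spec <- function(omega, couplings = NULL, noise_strength = 0,
                            label = NA_character_) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0) {
    stopf("`omega` must be a single positive number (rad/s).")
  }
  if (!is.numeric(noise_strength) || length(noise_strength) != 1L ||
      !is.finite(noise_strength) || noise_strength < 0) {
    stopf("`noise_strength` must be a single non-negative number.")
  }
  if (!is.null(couplings)) {
    need <- c("source", "k", "l", "kind", "coeff")
    if (!is.data.frame(couplings) || !all(need %in% names(couplings))) {
      stopf("`couplings` must have columns %s.", paste(need, collapse = ", "))
    }
    if (!all(couplings$kind %in% c("sin", "cos"))) {
      stopf("coupling `kind` must be \"sin\" or \"cos\".")
    }
    couplings <- tibble::as_tibble(couplings)
  }
  structure(
    list(omega = omega, couplings = couplings,
         noise_strength = noise_strength, label = label),
    class = "oscillator_spec"
  )
}

#' @rdname oscillator_spec
#' @param source,k,l,kind,coeff Vectorised fields of one or more coupling
#'   terms; see `couplings` above.
#' @export
coupling_term <- function(source, k, l, kind, coeff) {
  tibble::tibble(source = source, k = as.integer(k), l = as.integer(l),
                 kind = kind, coeff = coeff)
}

#' Simulation configuration
#'
#' @param duration Total simulated time (s).
#' @param dt Integration step (s). Default `NULL` chooses
#'   `1 / (40 * f_max)` where `f_max` is the fastest natural frequency in the
#'   system — 40 integration steps per cycle of the fastest oscillator.
#' @param out_rate Output sampling rate (Hz). Default `NULL` returns the full
#'   integration grid. Otherwise trajectories are subsampled by the nearest
#'   integer step ratio.
#' @param seed Optional RNG seed applied before integration.
#' @return An object of class `sim_config`. The integration scheme is
#'   Euler–Maruyama.
#' @export
sim_config <- function(duration, dt = NULL, out_rate = NULL, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) stopf("`duration` must be > 0.")
  if (!is.null(dt) && (!is.numeric(dt) || dt <= 0)) stopf("`dt` must be > 0.")
  if (!is.null(dt) && duration < 100 * dt) {
    stopf("`duration` must be at least 100 * dt.")
  }
  structure(list(duration = duration, dt = dt, out_rate = out_rate,
                 seed = seed, scheme = "euler-maruyama"),
            class = "sim_config")
}

# Build the C++ term matrix for a list of oscillator_specs.
# Columns: target0, source0, k, l, is_sin, coeff.
build_term_matrix <- function(specs) {
  labels <- vapply(specs, function(s) s$label, character(1))
  rows <- list()
  for (i in seq_along(specs)) {
    cp <- specs[[i]]$couplings
    if (is.null(cp) || nrow(cp) == 0L) next
    src <- match(cp$source, labels)
    if (anyNA(src)) {
      stopf("Unknown coupling source label(s): %s.",
            paste(unique(cp$source[is.na(src)]), collapse = ", "))
    }
    rows[[length(rows) + 1L]] <- cbind(
      i - 1L, src - 1L, cp$k, cp$l, as.integer(cp$kind == "sin"), cp$coeff
    )
  }
  if (length(rows) == 0L) {
    matrix(0, nrow = 0L, ncol = 6L)
  } else {
    do.call(rbind, rows)
  }
}

# Core network integrator shared by simulate_phases() and make_cohort().
simulate_network <- function(specs, config, phi0 = NULL) {
  labels <- vapply(specs, function(s) s$label, character(1))
  omega <- vapply(specs, function(s) s$omega, numeric(1))
  D <- vapply(specs, function(s) s$noise_strength, numeric(1))
  f_max <- max(omega) / (2 * pi)
  dt <- config$dt %||% (1 / (40 * f_max))
  keep <- 1L
  if (!is.null(config$out_rate)) {
    # refine dt to an exact integer subdivision of the output grid
    keep <- max(1L, as.integer(ceiling(1 / (dt * config$out_rate))))
    dt <- 1 / (keep * config$out_rate)
  }
  if (max(omega) * dt > 0.5) {
    stopf(paste0("Integration step dt = %g is too large for the fastest ",
                 "oscillation (dt * omega = %.2f rad > 0.5); decrease `dt`."),
          dt, max(omega) * dt)
  }
  nsteps <- round(config$duration / dt)
  out_rate <- 1 / (dt * keep)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(phi0)) phi0 <- runif(length(specs), 0, 2 * pi)
  terms <- build_term_matrix(specs)
  traj <- .sim_phase_network(phi0, omega, D, terms, dt, nsteps, as.integer(keep))
  phases <- lapply(seq_along(specs), function(i) {
    phase_series(traj[, i], rate = out_rate, band = labels[i], kind = "phase")
  })
  names(phases) <- labels
  list(phases = phases, dt = dt, rate = out_rate, phi0 = phi0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a pair of coupled stochastic phase oscillators
#'
#' Integrates the coupled phase model
#' \deqn{\dot\phi_i = \omega_i + q_i(\phi_i, \phi_j) + \xi_i(t)}
#' by the Euler–Maruyama scheme,
#' \eqn{\phi(t + dt) = \phi(t) + dt\,(\mathrm{drift}) +
#' \sqrt{dt \cdot D}\,\mathcal N(0,1)}, and returns the unwrapped phase
#' trajectories together with the generative ground truth.
#'
#' @param specs A list of two [oscillator_spec()] objects with distinct
#'   labels. Coupling `source` fields must refer to the other oscillator's
#'   label (or their own, for self-terms).
#' @param config A [sim_config()].
#' @param phi0 Optional length-2 vector of initial phases (rad); defaults to
#'   uniform random draws. Passing the final phases of a previous run chains
#'   piecewise-stationary segments into one continuous trajectory.
#' @return A list with elements `phases` (named list of two
#'   [phase_series()]), and `truth` (the specs, integration step, seed and
#'   initial phases).
#' @examples
#' specs <- list(
#'   oscillator_spec(2 * pi * 1.0, noise_strength = 0.01, label = "x",
#'     couplings = coupling_term("y", 0, 1, "sin", 0.4)),
#'   oscillator_spec(2 * pi * 0.27, noise_strength = 0.01, label = "y")
#' )
#' sim <- simulate_phases(specs, sim_config(duration = 60, seed = 1))
#' @export
simulate_phases <- function(specs, config, phi0 = NULL) {
  if (!is.list(specs) || length(specs) != 2L ||
      !all(vapply(specs, inherits, logical(1), "oscillator_spec"))) {
    stopf("`specs` must be a list of two oscillator_spec objects.")
  }
  res <- simulate_network(specs, config, phi0 = phi0)
  list(
    phases = res$phases,
    truth = list(specs = specs, dt = res$dt, rate = res$rate,
                 seed = config$seed, phi0 = res$phi0)
  )
}

#' Render observable signals from phase trajectories
#'
#' Produces physiological-like channels from simulated phases: each channel
#' is \eqn{\sum_b A_b \sin(\phi_b(t))} over its assigned oscillators plus
#' i.i.d. Gaussian measurement noise, sampled at `out_rate`. Channels are
#' built directly on the output time grid from the band-limited phases, so
#' no energy is placed above the output Nyquist frequency.
#'
#' @param phases Named list of [phase_series()] (names are oscillator labels).
#' @param channel_map Named list mapping channel names to oscillator labels,
#'   e.g. `list(eeg = c("delta","alpha"), resp = "r", ecg = "h")`.
#' @param amplitudes Named numeric vector of per-oscillator amplitudes;
#'   unnamed scalar recycles to all oscillators.
#' @param measurement_noise_sd Standard deviation of the additive channel
#'   noise (amplitude units).
#' @param out_rate Output sampling rate (Hz); must be at least 4 times the
#'   highest oscillator frequency.
#' @return A tibble with a `time` column and one column per channel;
#'   the sampling rate is stored in `attr(, "rate")`.
#' @export
render_signals <- function(phases, channel_map, amplitudes = 1,
                           measurement_noise_sd = 0, out_rate = NULL) {
  stopifnot(is.list(phases), length(phases) > 0)
  labels <- names(phases)
  if (is.null(labels) || any(labels == "")) {
    stopf("`phases` must be a named list of phase_series.")
  }
  f <- vapply(phases, ps_mean_freq, numeric(1))
  out_rate <- out_rate %||% phases[[1]]$rate
  if (out_rate < 4 * max(f)) {
    stopf("`out_rate` = %g Hz is below 4x the fastest oscillation (%.3g Hz); output would be undersampled.",
          out_rate, max(f))
  }
  if (length(amplitudes) == 1L && is.null(names(amplitudes))) {
    amplitudes <- stats::setNames(rep(amplitudes, length(labels)), labels)
  }
  dur <- min(vapply(phases, ps_duration, numeric(1)))
  tt <- seq(0, dur - 1 / out_rate, by = 1 / out_rate)
  cols <- list(time = tt)
  for (ch in names(channel_map)) {
    x <- numeric(length(tt))
    for (lab in channel_map[[ch]]) {
      ps <- phases[[lab]]
      if (is.null(ps)) stopf("Channel '%s' references unknown oscillator '%s'.", ch, lab)
      phi_t <- approx(ps$t0 + (seq_along(ps$phi) - 1) / ps$rate, ps$phi,
                      xout = tt, rule = 2)$y
      a <- amplitudes[[lab]] %||% 1
      x <- x + a * sin(phi_t)
    }
    if (measurement_noise_sd > 0) {
      x <- x + rnorm(length(x), 0, measurement_noise_sd)
    }
    cols[[ch]] <- x
  }
  out <- tibble::as_tibble(cols)
  attr(out, "rate") <- out_rate
  out
}

#' Default band oscillators for synthetic cohorts
#'
#' Frequencies sit near the band centres of [band_registry()]; noise
#' strengths (rad^2/s) are chosen so each rhythm shows physiological
#' cycle-to-cycle frequency variability: broadband cortical rhythms wander
#' substantially within their band, respiration has a period CV of roughly
#' 15%, the heartbeat a few percent.
#'
#' @return A tibble with columns `label`, `freq` (Hz) and `noise`
#'   (rad^2/s).
#' @export
default_oscillators <- function() {
  tibble::tibble(
    label = c("delta", "theta", "alpha", "gamma", "r", "h"),
    freq  = c(1.5, 5.5, 10, 40, 0.3, 1.05),
    noise = c(0.3, 0.3, 0.2, 0.5, 0.1, 0.05)
  )
}

#' Generate a synthetic multi-group cohort
#'
#' Builds a cohort of simulated subjects organised into groups (e.g.
#' awake-like, propofol-like, sevoflurane-like), each with six band-limited
#' oscillators — four cortical (delta, theta, alpha, gamma), one respiratory
#' (`r`) and one cardiac (`h`) — coupled according to a per-group strength
#' template. Per-subject coupling coefficients are drawn from a normal
#' distribution around the group mean (truncated at zero), natural
#' frequencies receive a small relative jitter, and every recording carries
#' its complete generative ground truth.
#'
#' Each subject's observables are rendered as three channels: `eeg` (the sum
#' of the four cortical oscillators), `resp` and `ecg`, plus Gaussian
#' measurement noise — the structure the preprocessing stage must
#' disentangle.
#'
#' @param template A data frame with columns `group`, `from`, `to`,
#'   `strength`: the mean coupling strength (1/s) of the direct term
#'   `strength * sin(phi_from)` planted in oscillator `to`'s phase equation,
#'   per group. Groups with no row for a pair get zero coupling.
#' @param n_subjects Subjects per group (>= 2). Scalar or named per group.
#' @param spread Inter-subject standard deviation of the planted strengths.
#' @param duration Recording length (s). Default 1200 (20 min).
#' @param rate Output sampling rate (Hz). Default 300.
#' @param measurement_noise_sd Channel noise SD. Default 0.1.
#' @param freq_jitter Relative SD of per-subject natural-frequency jitter.
#' @param oscillators Oscillator table (`label`, `freq` in Hz, `noise` in
#'   rad^2/s); defaults to [default_oscillators()].
#' @param keep_phases Keep the true phase trajectories (at `rate`) in the
#'   ground truth? Default `TRUE`; set `FALSE` for long recordings to save
#'   memory.
#' @param seed RNG seed; per-subject seeds are derived from it and recorded.
#' @return An object of class `synthetic_cohort`: a list with `subjects`
#'   (tibble: `group`, `subject`, `seed`), `recordings` (named list of
#'   channel tibbles), `truth` (named list: per-subject specs, planted
#'   strengths, and optionally true phases) and `rate`.
#' @examples
#' tpl <- tibble::tibble(
#'   group = c("A", "P", "S"), from = "delta", to = "alpha",
#'   strength = c(0.1, 0.35, 0.6)
#' )
#' coh <- make_cohort(tpl, n_subjects = 2, duration = 30, rate = 200, seed = 1)
#' @export
make_cohort <- function(template, n_subjects = 15, spread = 0.05,
                        duration = 1200, rate = 300,
                        measurement_noise_sd = 0.1, freq_jitter = 0.02,
                        oscillators = default_oscillators(),
                        keep_phases = TRUE, seed = 1) {
  need <- c("group", "from", "to", "strength")
  if (!is.data.frame(template) || nrow(template) == 0L ||
      !all(need %in% names(template))) {
    stopf("`template` must be a non-empty data frame with columns %s.",
          paste(need, collapse = ", "))
  }
  groups <- unique(template$group)
  if (is.null(names(n_subjects))) {
    n_subjects <- stats::setNames(rep(n_subjects[1], length(groups)), groups)
  }
  if (any(n_subjects < 2)) stopf("`n_subjects` must be >= 2 per group.")
  bad <- setdiff(c(template$from, template$to), oscillators$label)
  if (length(bad) > 0) {
    stopf("Unknown oscillator label(s) in template: %s.",
          paste(unique(bad), collapse = ", "))
  }

  set.seed(seed)
  subj_seeds <- sample.int(2^31 - 2, sum(n_subjects[groups]))

  subjects <- list(); recordings <- list(); truth <- list()
  idx <- 0L
  for (g in groups) {
    tpl_g <- template[template$group == g, , drop = FALSE]
    for (s in seq_len(n_subjects[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", g, s)
      sseed <- subj_seeds[idx]
      set.seed(sseed)
      # per-subject planted strengths and frequencies
      strengths <- pmax(0, rnorm(nrow(tpl_g), tpl_g$strength, spread))
      freqs <- oscillators$freq * (1 + rnorm(nrow(oscillators), 0, freq_jitter))
      specs <- lapply(seq_len(nrow(oscillators)), function(i) {
        lab <- oscillators$label[i]
        rows <- which(tpl_g$to == lab)
        cp <- if (length(rows) > 0) {
          coupling_term(tpl_g$from[rows], k = 0, l = 1, kind = "sin",
                        coeff = strengths[rows])
        } else NULL
        oscillator_spec(2 * pi * freqs[i], couplings = cp,
                        noise_strength = oscillators$noise[i], label = lab)
      })
      net <- simulate_network(
        specs, sim_config(duration = duration, out_rate = rate)
      )
      cortical <- intersect(c("delta", "theta", "alpha", "beta", "gamma"),
                            oscillators$label)
      cmap <- list()
      if (length(cortical) > 0) cmap$eeg <- cortical
      if ("r" %in% oscillators$label) cmap$resp <- "r"
      if ("h" %in% oscillators$label) cmap$ecg <- "h"
      rec <- render_signals(
        net$phases, channel_map = cmap, amplitudes = 1,
        measurement_noise_sd = measurement_noise_sd, out_rate = rate
      )
      subjects[[idx]] <- tibble::tibble(group = g, subject = sid, seed = sseed)
      recordings[[sid]] <- rec
      truth[[sid]] <- list(
        specs = specs,
        planted = tibble::tibble(from = tpl_g$from, to = tpl_g$to,
                                 strength = strengths),
        phases = if (keep_phases) net$phases else NULL
      )
    }
  }
  structure(
    list(subjects = dplyr::bind_rows(subjects), recordings = recordings,
         truth = truth, rate = rate, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %g Hz, %.0f s\n",
              nrow(x$subjects),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$rate,
              nrow(x$recordings[[1]]) / x$rate))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One CSV per subject (columns `time`, `eeg`, `resp`, `ecg`) plus a JSON
#' manifest recording groups, seeds, sampling rate and the planted ground
#' truth.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sid in names(cohort$recordings)) {
    f <- file.path(dir, paste0(sid, ".csv"))
    utils::write.csv(cohort$recordings[[sid]], f, row.names = FALSE)
    files[sid] <- basename(f)
  }
  manifest <- list(
    rate = cohort$rate,
    seed = cohort$seed,
    subjects = as.data.frame(dplyr::mutate(cohort$subjects,
                                           file = files[.data$subject])),
    truth = lapply(cohort$truth, function(tr) {
      list(planted = as.data.frame(tr$planted),
           oscillators = lapply(tr$specs, function(sp) {
             list(label = sp$label, omega = sp$omega,
                  noise_strength = sp$noise_strength)
           }))
    })
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing subject CSV files and `manifest.json`.
#' @return A list with `subjects` (tibble), `recordings` (named list of
#'   channel tibbles) and `rate`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stopf("No manifest.json in '%s'.", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  subjects <- tibble::as_tibble(manifest$subjects)
  recordings <- lapply(stats::setNames(subjects$file, subjects$subject),
                       function(f) {
    rec <- tibble::as_tibble(utils::read.csv(file.path(dir, f)))
    attr(rec, "rate") <- manifest$rate
    rec
  })
  list(subjects = subjects, recordings = recordings, rate = manifest$rate)
}
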