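#' Pipeline run configuration
#'
#' Bundles all settings of the end-to-end analysis: which coupling
#' relationships to analyse, how phases are extracted and resampled, the
#' inference, surrogate and statistics settings.
#'
#' @param relationships List of length-2 character vectors `c(from, to)` of
#'   band labels. Default: the six analysed relationships
#'   delta->alpha, theta->gamma, alpha->gamma, r->theta, h->theta, r->h.
#' @param K Fourier expansion order. Default 2.
#' @param window_s Inference window (s). Default 50.
#' @param prop_const Prior-propagation constant. Default 0.2.
#' @param pair_rate_cap Cap (Hz) on the per-pair inference sampling rate;
#'   each pair is resampled to `min(cap, 10 * faster band centre)`.
#'   Default 120.
#' @param n_fourier Harmonics for [protophase_to_phase()]. Default 24.
#' @param n_surrogates Surrogates per relationship. Default 100.
#' @param surrogate_rule `"mean_sd"` or `"percentile"`.
#' @param alpha Significance level for group tests. Default 0.05.
#' @param paired Use paired Wilcoxon for group contrasts? Default `FALSE`.
#' @param channel_map Named list mapping band labels to channel columns.
#' @param seed Seed for surrogate generation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(relationships = list(
                         c("delta", "alpha"), c("theta", "gamma"),
                         c("alpha", "gamma"), c("r", "theta"),
                         c("h", "theta"), c("r", "h")),
                       K = 2, window_s = 50, prop_const = 0.2,
                       pair_rate_cap = 120, n_fourier = 24,
                       n_surrogates = 100,
                       surrogate_rule = c("mean_sd", "percentile"),
                       alpha = 0.05, paired = FALSE,
                       channel_map = list(delta = "eeg", theta = "eeg",
                                          alpha = "eeg", beta = "eeg",
                                          gamma = "eeg", r = "resp",
                                          h = "ecg"),
                       seed = 1) {
  surrogate_rule <- match.arg(surrogate_rule)
  reg <- band_registry()$band
  for (rel in relationships) {
    if (length(rel) != 2L || !all(rel %in% reg)) {
      stopf("Each relationship must be c(from, to) of registered bands; got (%s).",
            paste(rel, collapse = ", "))
    }
  }
  structure(
    list(relationships = relationships, K = K, window_s = window_s,
         prop_const = prop_const, pair_rate_cap = pair_rate_cap,
         n_fourier = n_fourier, n_surrogates = n_surrogates,
         surrogate_rule = surrogate_rule, alpha = alpha, paired = paired,
         channel_map = channel_map, seed = seed),
    class = "run_config"
  )
}

# Interpolate two phase series onto a common time grid at the pair rate.
align_phases <- function(pa, pb, fs = NULL, cap = 120) {
  fc <- max(band_centre(pa$band), band_centre(pb$band))
  fs <- fs %||% min(cap, 10 * fc)
  t_lo <- max(pa$t0, pb$t0)
  t_hi <- min(pa$t0 + ps_duration(pa), pb$t0 + ps_duration(pb)) - 1 / fs
  if (t_hi <= t_lo) stopf("Phase series do not overlap in time.")
  tt <- seq(t_lo, t_hi, by = 1 / fs)
  interp <- function(p) {
    tp <- p$t0 + (seq_along(p$phi) - 1) / p$rate
    phase_series(approx(tp, p$phi, xout = tt, rule = 2)$y, rate = fs,
                 band = p$band, kind = p$kind, t0 = t_lo)
  }
  list(a = interp(pa), b = interp(pb), rate = fs)
}

# Net coupling strength (driver -> response) from one flat-prior fit over
# the whole overlap. Used for surrogate gating: the genuine strength and
# every surrogate strength are computed by this same estimator, so the
# finite-sample inflation of the parameter norm cancels in the comparison.
gate_strength <- function(driver, response, icfg) {
  len <- min(length(driver$phi), length(response$phi))
  d <- phase_series(driver$phi[seq_len(len)], driver$rate,
                    band = driver$band, kind = driver$kind)
  r <- phase_series(response$phi[seq_len(len)], response$rate,
                    band = response$band, kind = response$kind)
  post <- suppressWarnings(infer_window(r, d, config = icfg))
  coupling_strength(post, direction = c(d$band, r$band))
}

#' Analyse one subject's recording
#'
#' Runs the full per-subject pipeline for each configured relationship:
#' band-limited phase extraction from the relevant channels
#' ([extract_phase()]), alignment and resampling of the pair, windowed
#' Bayesian inference ([infer_sequence()], falling back to a single window
#' for short recordings), per-direction summary ([subject_summary()]), and
#' intra-subject surrogate testing of the configured direction's net
#' coupling.
#'
#' @param recording A channel table (data frame with a `time` column and one
#'   column per channel; sampling rate in `attr(, "rate")` or via `rate`).
#' @param config A [run_config()].
#' @param rate Sampling rate (Hz) if not carried by the recording.
#' @param subject Optional subject id recorded in the output.
#' @return A tibble with one row per relationship and direction, as
#'   [subject_summary()], plus `significant`, `threshold` and `status`
#'   columns (surrogate columns filled for the configured from->to
#'   direction). Relationships whose channels are missing are skipped with
#'   a message and reported with `status = "missing-channel"`.
#' @export
run_subject <- function(recording, config = run_config(), rate = NULL,
                        subject = NA_character_) {
  rate <- rate %||% attr(recording, "rate")
  if (is.null(rate)) stopf("Supply `rate` (no rate attribute on recording).")
  icfg <- inference_config(window_s = config$window_s,
                           prop_const = config$prop_const,
                           basis = fourier_basis(config$K))
  phase_cache <- list()
  get_phase <- function(band) {
    if (!is.null(phase_cache[[band]])) return(phase_cache[[band]])
    ch <- config$channel_map[[band]]
    if (is.null(ch) || !(ch %in% names(recording))) return(NULL)
    ph <- extract_phase(recording[[ch]], band, rate = rate,
                        n_fourier = config$n_fourier)
    phase_cache[[band]] <<- ph
    ph
  }

  rows <- list()
  for (rel in config$relationships) {
    from <- rel[1]; to <- rel[2]
    p_from <- get_phase(from); p_to <- get_phase(to)
    if (is.null(p_from) || is.null(p_to)) {
      message(sprintf("Skipping %s->%s: channel missing.", from, to))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subject, from = from, to = to,
        status = "missing-channel"
      )
      next
    }
    al <- align_phases(p_to, p_from, cap = config$pair_rate_cap)
    n_win <- floor(ps_duration(al$a) / config$window_s)
    posteriors <- if (n_win >= 2L) {
      suppressMessages(infer_sequence(al$a, al$b, config = icfg))
    } else {
      list(suppressWarnings(infer_window(al$a, al$b, config = icfg)))
    }
    smry <- subject_summary(posteriors, subject = subject)
    smry$status <- "ok"

    # surrogate gating of the configured direction's net coupling: the
    # genuine and surrogate strengths come from the same full-length
    # flat-prior estimator (see gate_strength)
    if (config$n_surrogates > 0) {
      surr <- intra_surrogate(al$b, n = config$n_surrogates,
                              seed = config$seed)
      strengths <- vapply(surr, gate_strength, numeric(1),
                          response = al$a, icfg = icfg)
      genuine <- gate_strength(al$b, al$a, icfg)
      sig <- significance_vs_surrogates(
        genuine, surrogate_ensemble(strengths, kind = "intra",
                                    seed = config$seed),
        rule = config$surrogate_rule
      )
      smry$significant <- ifelse(smry$from == from & smry$to == to,
                                 sig$significant, NA)
      smry$threshold <- ifelse(smry$from == from & smry$to == to,
                               sig$threshold, NA_real_)
    } else {
      smry$significant <- NA
      smry$threshold <- NA_real_
    }
    rows[[length(rows) + 1L]] <- smry
  }
  dplyr::bind_rows(rows)
}

#' Analyse a cohort
#'
#' Runs [run_subject()] for every recording, then computes the group-level
#' outputs: per-relationship, per-component Wilcoxon comparisons of every
#' group pair; within-group inter-subject similarity-of-form correlations
#' for every component; and per-band noise-strength comparisons. Groups
#' with fewer than 2 valid subjects are excluded from statistics (with a
#' message) but their summaries are kept.
#'
#' @param cohort A [make_cohort()] result, or a list with elements
#'   `subjects` (tibble with `group`, `subject`), `recordings` (named list
#'   of channel tables) and `rate` (e.g. from [read_cohort()]).
#' @param config A [run_config()].
#' @return An object of class `cohort_results`: list with tibbles
#'   `summaries` (per subject x relationship x direction),
#'   `comparisons` (relationship x component x group pair),
#'   `similarity` (within-group subject pairs x component),
#'   `noise` (per subject x band) and `noise_comparisons` (band x group
#'   pair).
#' @export
run_cohort <- function(cohort, config = run_config()) {
  subjects <- cohort$subjects
  if (length(unique(subjects$group)) < 2L) {
    stopf("Cohort must contain at least 2 groups.")
  }
  summaries <- dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject[i]
    out <- run_subject(cohort$recordings[[sid]], config = config,
                       rate = cohort$rate, subject = sid)
    out$group <- subjects$group[i]
    out
  }))

  groups <- unique(subjects$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  ok <- summaries[summaries$status == "ok" & summaries$valid, ]

  comparisons <- list(); similarity <- list()
  for (rel in config$relationships) {
    sub <- ok[ok$from == rel[1] & ok$to == rel[2], ]
    if (nrow(sub) == 0L) next
    for (comp in c("net", "direct", "indirect")) {
      df <- tibble::tibble(group = sub$group, strength = sub[[comp]])
      for (pr in pairs) {
        n_by_g <- table(factor(df$group, levels = pr))
        if (any(n_by_g < 2L)) {
          message(sprintf("Skipping %s-%s (%s->%s %s): <2 valid subjects.",
                          pr[1], pr[2], rel[1], rel[2], comp))
          next
        }
        cmp <- group_compare(df, pair = pr, paired = config$paired,
                             alpha = config$alpha)
        cmp$from <- rel[1]; cmp$to <- rel[2]; cmp$component <- comp
        comparisons[[length(comparisons) + 1L]] <- cmp
      }
    }
    # within-group inter-subject similarity of form
    for (g in groups) {
      sg <- sub[sub$group == g, ]
      if (nrow(sg) < 2L) next
      basis <- fourier_basis(config$K)
      for (comp in c("net", "direct", "indirect")) {
        sel <- coupling_term_idx(basis, comp)
        for (ij in utils::combn(nrow(sg), 2, simplify = FALSE)) {
          rho <- suppressMessages(similarity_rho(
            sg$coeffs[[ij[1]]][sel], sg$coeffs[[ij[2]]][sel]
          ))
          similarity[[length(similarity) + 1L]] <- tibble::tibble(
            group = g, from = rel[1], to = rel[2], component = comp,
            subject_a = sg$subject[ij[1]], subject_b = sg$subject[ij[2]],
            rho = rho
          )
        }
      }
    }
  }

  # per-subject, per-band noise strengths (median over relationships
  # involving the band)
  noise_long <- dplyr::bind_rows(
    dplyr::transmute(ok, group = .data$group, subject = .data$subject,
                     band = .data$from, D = .data$noise_from),
    dplyr::transmute(ok, group = .data$group, subject = .data$subject,
                     band = .data$to, D = .data$noise_to)
  )
  noise <- dplyr::summarise(
    dplyr::group_by(noise_long, .data$group, .data$subject, .data$band),
    D = median(.data$D), .groups = "drop"
  )
  noise_comparisons <- list()
  for (b in unique(noise$band)) {
    df <- noise[noise$band == b, ]
    for (pr in pairs) {
      n_by_g <- table(factor(df$group, levels = pr))
      if (any(n_by_g < 2L)) next
      cmp <- group_compare(df, value = "D", pair = pr,
                           paired = config$paired, alpha = config$alpha)
      cmp$band <- b
      noise_comparisons[[length(noise_comparisons) + 1L]] <- cmp
    }
  }

  structure(
    list(summaries = summaries,
         comparisons = dplyr::bind_rows(comparisons),
         similarity = dplyr::bind_rows(similarity),
         noise = noise,
         noise_comparisons = dplyr::bind_rows(noise_comparisons),
         config = config),
    class = "cohort_results"
  )
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf(
    "<cohort_results> %d subjects, %d relationship summaries, %d group comparisons\n",
    length(unique(x$summaries$subject)), nrow(x$summaries),
    nrow(x$comparisons)
  ))
  if (nrow(x$comparisons) > 0) {
    sig <- x$comparisons[x$comparisons$significant, ]
    cat(sprintf("  significant contrasts (p < %g): %d\n", x$config$alpha,
                nrow(sig)))
  }
  invisible(x)
}

#' Write cohort results as tidy CSV tables
#'
#' @param results A [run_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "cohort_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  smry <- results$summaries
  smry$coeffs <- NULL
  utils::write.csv(smry, file.path(dir, "summaries.csv"), row.names = FALSE)
  cmp <- results$comparisons
  if (nrow(cmp) > 0) cmp$descriptives <- NULL
  utils::write.csv(cmp, file.path(dir, "comparisons.csv"), row.names = FALSE)
  utils::write.csv(results$similarity, file.path(dir, "similarity.csv"),
                   row.names = FALSE)
  utils::write.csv(results$noise, file.path(dir, "noise.csv"),
                   row.names = FALSE)
  ncmp <- results$noise_comparisons
  if (nrow(ncmp) > 0) ncmp$descriptives <- NULL
  utils::write.csv(ncmp, file.path(dir, "noise_comparisons.csv"),
                   row.names = FALSE)
  invisible(dir)
}
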