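#' Intra-subject cycle-permutation surrogates
#'
#' Destroys the temporal alignment of a driver phase with any response while
#' preserving the driver's own rhythm statistics. The unwrapped phase is
#' split into whole cycles at its crossings of successive \eqn{2\pi}
#' boundaries; complete cycles are permuted uniformly at random and rejoined
#' with offsets that are exact multiples of \eqn{2\pi}, so the multiset of
#' cycle durations and the wrapped-phase sample distribution are preserved
#' exactly, and the mean frequency to within a fraction of one cycle.
#'
#' @param phi A [phase_series()] spanning at least 20 full cycles.
#' @param n Number of surrogates.
#' @param seed Optional RNG seed.
#' @return A list of `n` [phase_series()] surrogates.
#' @export
intra_surrogate <- function(phi, n = 100, seed = NULL) {
  stopifnot(inherits(phi, "phase_series"), n >= 1)
  p <- phi$phi
  n_cycles <- (p[length(p)] - p[1]) / (2 * pi)
  if (n_cycles < 20) {
    stopf("Phase spans only %.1f cycles; at least 20 full cycles are required.",
          n_cycles)
  }
  if (!is.null(seed)) set.seed(seed)
  base <- p[1]
  # epsilon guards samples lying exactly on a cycle boundary
  m <- floor((p - base) / (2 * pi) + 1e-9)
  n_full <- max(m)
  # first sample index of each complete cycle 0 .. n_full - 1
  starts <- vapply(0:(n_full - 1L), function(j) which(m >= j)[1], integer(1))
  ends <- c(starts[-1] - 1L, which(m >= n_full)[1] - 1L)
  tail_idx <- if (ends[length(ends)] < length(p)) {
    (ends[length(ends)] + 1L):length(p)
  } else integer(0)

  lapply(seq_len(n), function(s) {
    perm <- sample.int(n_full)
    out <- numeric(0)
    for (pos in seq_len(n_full)) {
      j <- perm[pos]
      blk <- p[starts[j]:ends[j]] + 2 * pi * ((pos - 1L) - (j - 1L))
      out <- c(out, blk)
    }
    if (length(tail_idx) > 0) out <- c(out, p[tail_idx])
    phase_series(out, rate = phi$rate, band = phi$band, kind = phi$kind,
                 t0 = phi$t0)
  })
}

#' Inter-subject surrogates
#'
#' Pairs a response phase with driver phases taken from *other* subjects in
#' the same band, truncated to the common length. Any coupling apparent in
#' such pairs is spurious by construction.
#'
#' @param phi_response The response [phase_series()].
#' @param donor_pool A list of driver [phase_series()] from other subjects
#'   (same band). The response itself must not be in the pool.
#' @param n Number of surrogate pairs; donors are sampled with replacement.
#' @param seed Optional RNG seed.
#' @return A list of `n` lists, each with elements `driver` and `response`
#'   ([phase_series()], equal length).
#' @export
inter_surrogate <- function(phi_response, donor_pool, n = 100, seed = NULL) {
  stopifnot(inherits(phi_response, "phase_series"))
  if (!is.list(donor_pool) || length(donor_pool) == 0L) {
    stopf("`donor_pool` must be a non-empty list of phase_series.")
  }
  if (any(vapply(donor_pool, identical, logical(1), phi_response))) {
    stopf("The response series itself must not appear in `donor_pool`.")
  }
  if (length(donor_pool) == 1L) {
    warnf("Donor pool has a single subject; all %d surrogates use that donor.", n)
  }
  if (!is.null(seed)) set.seed(seed)
  picks <- sample.int(length(donor_pool), n, replace = TRUE)
  lapply(picks, function(i) {
    d <- donor_pool[[i]]
    len <- min(length(d$phi), length(phi_response$phi))
    list(
      driver = phase_series(d$phi[seq_len(len)], d$rate, band = d$band,
                            kind = d$kind),
      response = phase_series(phi_response$phi[seq_len(len)],
                              phi_response$rate, band = phi_response$band,
                              kind = phi_response$kind)
    )
  })
}

#' Surrogate ensemble of coupling strengths
#'
#' @param strengths Non-negative numeric vector of surrogate coupling
#'   strengths (1/s), length >= 19.
#' @param kind `"intra"` or `"inter"`.
#' @param seed Seed used to generate the ensemble (recorded).
#' @return An object of class `surrogate_ensemble`.
#' @export
surrogate_ensemble <- function(strengths, kind = c("intra", "inter"),
                               seed = NA_integer_) {
  kind <- match.arg(kind)
  if (length(strengths) < 19L) {
    stopf("At least 19 surrogate strengths are required (got %d).",
          length(strengths))
  }
  if (any(strengths < 0)) stopf("Surrogate strengths must be non-negative.")
  structure(list(kind = kind, n_surrogates = length(strengths),
                 strengths = as.numeric(strengths), seed = seed),
            class = "surrogate_ensemble")
}

#' Significance of a genuine coupling against surrogates
#'
#' Default rule: significant iff the genuine strength exceeds the surrogate
#' mean plus two surrogate standard deviations. A percentile alternative
#' (`rule = "percentile"`, threshold at the `level` quantile of the
#' surrogate strengths) is also provided.
#'
#' @param genuine Genuine coupling strength (1/s).
#' @param ensemble A [surrogate_ensemble()], or a bare numeric vector of
#'   surrogate strengths.
#' @param rule `"mean_sd"` (default) or `"percentile"`.
#' @param level Quantile for the percentile rule. Default 0.95.
#' @return A one-row tibble: `significant`, `threshold`, `rule`, `kind`,
#'   `n_surrogates`.
#' @export
significance_vs_surrogates <- function(genuine, ensemble,
                                       rule = c("mean_sd", "percentile"),
                                       level = 0.95) {
  rule <- match.arg(rule)
  if (is.numeric(ensemble)) ensemble <- surrogate_ensemble(ensemble)
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  s <- ensemble$strengths
  threshold <- switch(rule,
    mean_sd = mean(s) + 2 * sd(s),
    percentile = as.numeric(quantile(s, level, type = 8))
  )
  tibble::tibble(
    significant = genuine > threshold, threshold = threshold, rule = rule,
    kind = ensemble$kind, n_surrogates = ensemble$n_surrogates
  )
}

#' Rank-based comparison of two groups of coupling strengths
#'
#' Wilcoxon comparison of one pair of groups: unpaired rank-sum for
#' different-subject groups (default) or the paired signed-rank variant for
#' same-subject contrasts. Two-sided, with p < `alpha` flagged significant
#' and no multiplicity correction. Ties are handled by the standard
#' mid-rank (normal approximation) convention.
#'
#' @param data A data frame with one strength value per subject.
#' @param value,group Column names (strings) of the strength values and the
#'   group labels.
#' @param pair Length-2 character vector: the two group labels to compare.
#' @param paired Use the signed-rank variant? Requires equal group sizes in
#'   matching order. Default `FALSE`.
#' @param alpha Significance level. Default 0.05.
#' @return A one-row tibble: `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`, `significant`, plus a list-column `descriptives` holding the
#'   per-group boxplot statistics (median, quartiles, minimum, maximum).
#' @export
group_compare <- function(data, value = "strength", group = "group",
                          pair = NULL, paired = FALSE, alpha = 0.05) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  g <- as.character(data[[group]])
  if (is.null(pair)) pair <- unique(g)[1:2]
  x <- data[[value]][g == pair[1]]
  y <- data[[value]][g == pair[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stopf("Need at least 2 values per group (%s: %d, %s: %d).",
          pair[1], length(x), pair[2], length(y))
  }
  if (paired && length(x) != length(y)) {
    stopf("Paired comparison requires equal group sizes.")
  }
  desc <- dplyr::bind_rows(lapply(pair, function(gg) {
    v <- data[[value]][g == gg]
    qs <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble::tibble(group = gg, n = length(v), min = qs[1], q1 = qs[2],
                   median = qs[3], q3 = qs[4], max = qs[5])
  }))
  degenerate <- (stats::var(c(x, y)) == 0) ||
    (paired && stats::var(x - y) == 0)
  if (degenerate) {
    warnf("group_compare: degenerate all-equal samples; p set to 1.")
    stat <- NA_real_; pval <- 1
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = paired, exact = FALSE, correct = TRUE)
    )
    stat <- unname(wt$statistic); pval <- wt$p.value
  }
  tibble::tibble(
    group1 = pair[1], group2 = pair[2], n1 = length(x), n2 = length(y),
    statistic = stat, p_value = pval, significant = pval < alpha,
    descriptives = list(desc)
  )
}
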