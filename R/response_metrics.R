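#' Stimulus-aligned trial set
#'
#' Per-trial spike times in ms relative to stimulus onset, with the trial
#' window extent recorded so rate estimators can check coverage.
#'
#' @param spikes List of numeric vectors, one per trial (ms; may be empty).
#' @param stimulus_id Stimulus label.
#' @param pre_ms Window extent before onset (ms, positive).
#' @param post_ms Window extent after stimulus offset (ms).
#' @param stim_duration_ms Stimulus duration (ms).
#' @param level Presentation level / attenuation (metadata).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(spikes, stimulus_id = "stim", pre_ms = 1000,
                      post_ms = 500, stim_duration_ms = 3000, level = NA) {
  if (!is.list(spikes) || length(spikes) < 1L) {
    stop("`spikes` must be a non-empty list of per-trial time vectors",
         call. = FALSE)
  }
  lo <- -pre_ms; hi <- stim_duration_ms + post_ms
  spikes <- lapply(spikes, function(s) {
    s <- sort(as.numeric(s))
    if (length(s) && (s[1L] < lo - 1e-9 || s[length(s)] > hi + 1e-9)) {
      stop("spike times outside the trial window", call. = FALSE)
    }
    s
  })
  structure(list(spikes = spikes, stimulus_id = stimulus_id,
                 n_trials = length(spikes), pre_ms = pre_ms,
                 post_ms = post_ms, stim_duration_ms = stim_duration_ms,
                 level = level),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "<trial_set> %s: %d trials, window [%g, %g] ms, %d spikes total\n",
    x$stimulus_id, x$n_trials, -x$pre_ms, x$stim_duration_ms + x$post_ms,
    sum(lengths(x$spikes))))
  invisible(x)
}

#' Peri-stimulus time histogram (1-ms bins)
#'
#' Counts spikes across trials in fixed 1-ms bins aligned to stimulus onset
#' (bin `b` covers `[b, b+1)` ms). The bin sum always equals the number of
#' spikes inside the axis range.
#'
#' @param trials A `trial_set`.
#' @return An object of class `psth`: `counts`, `t` (bin left edges, ms),
#'   `n_trials`, `smoothing_sd` (0 = unsmoothed).
#' @export
compute_psth <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  t0 <- -trials$pre_ms
  t1 <- trials$stim_duration_ms + trials$post_ms
  edges <- seq(floor(t0), ceiling(t1))
  all_t <- unlist(trials$spikes, use.names = FALSE)
  counts <- if (length(all_t)) {
    tabulate(floor(all_t) - edges[1L] + 1L, nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  structure(list(counts = as.numeric(counts),
                 t = edges[-length(edges)],
                 n_trials = trials$n_trials, smoothing_sd = 0),
            class = "psth")
}

#' Gaussian-smoothed PSTH
#'
#' Convolves the 1-ms PSTH with a unit-area Gaussian kernel; used before
#' FWHM and latency extraction, where raw 1-ms bins are too noisy for
#' half-maximum crossings. The kernel SD is recorded on the object.
#'
#' @param psth A `psth`.
#' @param sd_ms Kernel SD in ms (0 returns the input unchanged).
#' @return A smoothed `psth`.
#' @export
smooth_psth <- function(psth, sd_ms = 5) {
  stopifnot(inherits(psth, "psth"))
  if (sd_ms <= 0) return(psth)
  half <- ceiling(4 * sd_ms)
  kern <- stats::dnorm(-half:half, 0, sd_ms)
  kern <- kern / sum(kern)
  n <- length(psth$counts)
  padded <- c(rep(psth$counts[1L], half), psth$counts,
              rep(psth$counts[n], half))
  sm <- stats::filter(padded, kern, sides = 2)
  psth$counts <- as.numeric(sm[(half + 1L):(half + n)])
  psth$smoothing_sd <- sd_ms
  psth
}

#' Spontaneous firing rate from pre-stimulus windows
#'
#' Natural-call mode uses the 800-ms pre-stimulus segment from -1000 to
#' -200 ms (the -1 to -0.2 s stretch of the PSTH); tone mode uses the 100 ms
#' immediately preceding onset. The rate is the total pre-window spike count
#' divided by window length times trial count.
#'
#' @param trials A `trial_set`.
#' @param mode `"natural"` or `"tone"`.
#' @param per_trial If `TRUE`, return the per-trial rates (sp/s) instead of
#'   their pooled mean.
#' @return Spikes/s (scalar, or vector with `per_trial = TRUE`).
#' @export
spontaneous_rate <- function(trials, mode = c("natural", "tone"),
                             per_trial = FALSE) {
  stopifnot(inherits(trials, "trial_set"))
  mode <- match.arg(mode)
  win <- if (mode == "natural") c(-1000, -200) else c(-100, 0)
  need <- -win[1L]
  if (trials$pre_ms < need) {
    stop(sprintf("pre-window of %g ms required for mode '%s' (have %g ms)",
                 need, mode, trials$pre_ms), call. = FALSE)
  }
  w_s <- (win[2L] - win[1L]) / 1000
  rates <- vapply(trials$spikes, function(s) {
    sum(s >= win[1L] & s < win[2L]) / w_s
  }, numeric(1L))
  if (per_trial) rates else mean(rates)
}

#' Per-syllable evoked firing rates
#'
#' For each syllable of the call, counts spikes across trials in a window
#' starting at syllable onset. Window rule `"fixed"` uses a constant 100 ms;
#' `"fig7"` uses 100 ms or the syllable length, whichever is longer (for
#' syllables exceeding 100 ms). Windows that would run into the next
#' syllable are truncated at its onset with a warning. The per-cell summary
#' is the mean rate over syllables.
#'
#' @param trials A `trial_set`.
#' @param call A `call_stimulus` (its syllable annotations define windows).
#' @param window_rule `"fixed"` (constant 100 ms) or `"fig7"`
#'   (`max(100 ms, syllable length)`).
#' @param per_trial If `TRUE`, also return the trials x syllables rate
#'   matrix.
#' @return A list: `per_syllable` (sp/s), `mean` (sp/s), `windows`
#'   (data.frame start/end ms), and optionally `rates_by_trial`.
#' @export
evoked_rate_syllables <- function(trials, call,
                                  window_rule = c("fixed", "fig7"),
                                  per_trial = FALSE) {
  stopifnot(inherits(trials, "trial_set"), inherits(call, "call_stimulus"))
  window_rule <- match.arg(window_rule)
  on_ms <- call$syllables$onset * 1000
  dur_ms <- call$syllables$duration * 1000
  w <- switch(window_rule,
              fixed = rep(100, length(on_ms)),
              fig7 = pmax(100, dur_ms))
  ends <- on_ms + w
  nxt <- c(on_ms[-1L], Inf)
  if (any(ends > nxt + 1e-9)) {
    warning("evoked windows truncated at the next syllable onset")
    ends <- pmin(ends, nxt)
  }
  rate_mat <- vapply(seq_along(on_ms), function(k) {
    vapply(trials$spikes, function(s) {
      sum(s >= on_ms[k] & s < ends[k]) / ((ends[k] - on_ms[k]) / 1000)
    }, numeric(1L))
  }, numeric(trials$n_trials))
  rate_mat <- matrix(rate_mat, nrow = trials$n_trials)
  per_syl <- colMeans(rate_mat)
  out <- list(per_syllable = per_syl, mean = mean(per_syl),
              windows = data.frame(start = on_ms, end = ends))
  if (per_trial) out$rates_by_trial <- rate_mat
  out
}

#' Response window container
#'
#' @param start,end Window bounds, ms (half-open `[start, end)`).
#' @param rule How the window was derived (`"fixed-100"`,
#'   `"syllable-length"`, `"FWHM"`).
#' @return An object of class `response_window`.
#' @export
response_window <- function(start, end, rule = "fixed-100") {
  if (end <= start) stop("`end` must exceed `start`", call. = FALSE)
  structure(list(start = start, end = end, rule = rule),
            class = "response_window")
}

#' Full-width-at-half-maximum response window of a PSTH
#'
#' On the Gaussian-smoothed PSTH restricted to post-onset bins, the window
#' runs from the first bin (from the left) whose height reaches
#' `baseline + (peak - baseline)/2` to just past the last such bin.
#' Baseline is the mean pre-stimulus smoothed bin height. Scale-invariant:
#' rescaling all counts by a positive constant leaves the window unchanged.
#'
#' @param psth A `psth` (raw or already smoothed).
#' @param smoothing_sd Gaussian kernel SD in ms applied before extraction
#'   when the PSTH is unsmoothed (default 5; use 0 for none).
#' @return A `response_window` with `rule = "FWHM"`.
#' @export
fwhm_window <- function(psth, smoothing_sd = 5) {
  stopifnot(inherits(psth, "psth"))
  if (psth$smoothing_sd == 0 && smoothing_sd > 0) {
    psth <- smooth_psth(psth, smoothing_sd)
  }
  pre <- psth$counts[psth$t < 0]
  baseline <- if (length(pre)) mean(pre) else 0
  post_idx <- which(psth$t >= 0)
  if (!length(post_idx)) stop("PSTH has no post-onset bins", call. = FALSE)
  post <- psth$counts[post_idx]
  peak <- max(post)
  if (peak <= baseline + 1e-12) {
    stop("no response: PSTH peak does not exceed baseline", call. = FALSE)
  }
  half <- baseline + (peak - baseline) / 2
  qual <- which(post >= half - 1e-12)
  start <- psth$t[post_idx[qual[1L]]]
  end <- psth$t[post_idx[qual[length(qual)]]] + 1  # half-open, 1-ms bins
  response_window(start, end, rule = "FWHM")
}

#' Per-trial firing rate inside a response window
#'
#' @param trials A `trial_set`.
#' @param window A `response_window`.
#' @return Numeric vector of per-trial rates (sp/s).
#' @export
window_rates <- function(trials, window) {
  stopifnot(inherits(trials, "trial_set"),
            inherits(window, "response_window"))
  w_s <- (window$end - window$start) / 1000
  vapply(trials$spikes, function(s) {
    sum(s >= window$start & s < window$end) / w_s
  }, numeric(1L))
}

#' Significance of a syllable response (Mann-Whitney U)
#'
#' Two-sided rank-sum test of the per-trial firing rates inside the response
#' window against the per-trial spontaneous rates; a syllable is flagged as
#' responded when `p < alpha`.
#'
#' @param trials A `trial_set`.
#' @param window A `response_window` (e.g., per-syllable FWHM).
#' @param spont_rates Per-trial spontaneous rates, sp/s (from
#'   [spontaneous_rate()] with `per_trial = TRUE`).
#' @param alpha Significance level (default 0.05).
#' @return A list: `p`, `flag`, `evoked_rates` (per trial).
#' @export
syllable_significance <- function(trials, window, spont_rates,
                                  alpha = 0.05) {
  if (length(spont_rates) < 2L || trials$n_trials < 2L) {
    stop("at least 2 trials are required", call. = FALSE)
  }
  ev <- window_rates(trials, window)
  p <- if (length(unique(c(ev, spont_rates))) == 1L) {
    1  # every value tied: no evidence either way
  } else {
    suppressWarnings(stats::wilcox.test(ev, spont_rates, exact = FALSE)$p.value)
  }
  list(p = p, flag = is.finite(p) && p < alpha, evoked_rates = ev)
}

#' Per-syllable significance for a whole call
#'
#' Applies [syllable_significance()] to each syllable using its own response
#' window: the FWHM of the syllable's PSTH segment when a clear peak exists,
#' otherwise the syllable's evoked window (window-rule fallback). Returns
#' per-syllable p-values, flags, and their count (`n_responded`).
#'
#' @inheritParams evoked_rate_syllables
#' @param spont_rates Per-trial spontaneous rates (natural mode).
#' @param smoothing_sd PSTH smoothing SD for the segment FWHM (ms).
#' @param alpha Significance level.
#' @return A list: `p` (vector), `flags` (logical vector), `n_responded`.
#' @export
call_significance <- function(trials, call, spont_rates,
                              window_rule = c("fixed", "fig7"),
                              smoothing_sd = 5, alpha = 0.05) {
  window_rule <- match.arg(window_rule)
  ev <- evoked_rate_syllables(trials, call, window_rule)
  psth <- smooth_psth(compute_psth(trials), smoothing_sd)
  ps <- numeric(nrow(ev$windows))
  flags <- logical(nrow(ev$windows))
  for (k in seq_len(nrow(ev$windows))) {
    seg <- ev$windows[k, ]
    win <- tryCatch({
      idx <- psth$t >= seg$start & psth$t < seg$end
      sub <- structure(list(counts = psth$counts[idx], t = psth$t[idx],
                            n_trials = psth$n_trials,
                            smoothing_sd = psth$smoothing_sd),
                       class = "psth")
      # segment-local FWHM, referenced to the whole-PSTH pre-stimulus baseline
      pre <- psth$counts[psth$t < 0]
      baseline <- if (length(pre)) mean(pre) else 0
      peak <- max(sub$counts)
      if (peak <= baseline + 1e-12) stop("flat")
      half <- baseline + (peak - baseline) / 2
      qual <- which(sub$counts >= half - 1e-12)
      response_window(sub$t[qual[1L]], sub$t[qual[length(qual)]] + 1,
                      rule = "FWHM")
    }, error = function(e) {
      response_window(seg$start, seg$end, rule = "fixed-100")
    })
    res <- syllable_significance(trials, win, spont_rates, alpha)
    ps[k] <- res$p
    flags[k] <- res$flag
  }
  list(p = ps, flags = flags, n_responded = sum(flags))
}

#' Frequency response area from tone trials
#'
#' The FRA entry for (frequency, level) is the mean evoked rate inside the
#' cell's response window over that combination's repetitions. The
#' normalized FRA divides by the cell's maximum entry (left undivided, with
#' a flag, when the matrix is all zero).
#'
#' @param tone_trials A list of `trial_set`s, one per frequency x level
#'   combination, each carrying `freq` and `level` metadata in
#'   `stimulus_id`/`level`; alternatively a data.frame-driven interface via
#'   `freqs`/`levels` vectors parallel to the list.
#' @param freqs,levels Numeric vectors parallel to `tone_trials`.
#' @param window A `response_window` (the cell's tone-PSTH FWHM).
#' @return A list: `fra` (levels x freqs matrix, sp/s), `fra_normalized`,
#'   `freqs`, `levels`, `all_zero`.
#' @export
compute_fra <- function(tone_trials, freqs, levels, window) {
  stopifnot(length(tone_trials) == length(freqs),
            length(freqs) == length(levels))
  uf <- sort(unique(freqs)); ul <- sort(unique(levels))
  fra <- matrix(NA_real_, length(ul), length(uf),
                dimnames = list(level = ul, freq = uf))
  for (i in seq_along(tone_trials)) {
    r <- mean(window_rates(tone_trials[[i]], window))
    fra[match(levels[i], ul), match(freqs[i], uf)] <- r
  }
  mx <- max(fra, na.rm = TRUE)
  all_zero <- !is.finite(mx) || mx <= 0
  list(fra = fra,
       fra_normalized = if (all_zero) fra else fra / mx,
       freqs = uf, levels = ul, all_zero = all_zero)
}

#' Tuning parameters: best frequency, characteristic frequency, latency
#'
#' `best_frequency` is the frequency of the global FRA maximum;
#' `characteristic_frequency` maximizes the level-averaged response;
#' `response_latency` is the post-onset peak time of the smoothed PSTH, with
#' an alternative estimate (first crossing of baseline + 2 SD of baseline
#' bins) also returned. Ties resolve to the lowest frequency / earliest
#' time.
#'
#' @param fra Output of [compute_fra()].
#' @return Frequency in Hz.
#' @export
best_frequency <- function(fra) {
  if (fra$all_zero) stop("no response: FRA is all zero", call. = FALSE)
  idx <- which(fra$fra == max(fra$fra, na.rm = TRUE), arr.ind = TRUE)
  min(fra$freqs[idx[, 2L]])
}

#' @rdname best_frequency
#' @export
characteristic_frequency <- function(fra) {
  if (fra$all_zero) stop("no response: FRA is all zero", call. = FALSE)
  avg <- colMeans(fra$fra, na.rm = TRUE)
  fra$freqs[which.max(avg)]  # which.max takes the first (lowest) on ties
}

#' @rdname best_frequency
#' @param psth A `psth`.
#' @param smoothing_sd Kernel SD (ms) applied when the PSTH is unsmoothed.
#' @return `response_latency`: a list with `peak_ms` (PSTH peak time) and
#'   `crossing_ms` (baseline + 2 SD crossing; `NA` if never crossed).
#' @export
response_latency <- function(psth, smoothing_sd = 5) {
  stopifnot(inherits(psth, "psth"))
  if (psth$smoothing_sd == 0 && smoothing_sd > 0) {
    psth <- smooth_psth(psth, smoothing_sd)
  }
  pre <- psth$counts[psth$t < 0]
  post_idx <- which(psth$t >= 0)
  post <- psth$counts[post_idx]
  if (max(post) <= 0) stop("no response: empty post-onset PSTH", call. = FALSE)
  baseline <- if (length(pre)) mean(pre) else 0
  bsd <- if (length(pre) > 1L) stats::sd(pre) else 0
  peak_ms <- psth$t[post_idx[which.max(post)]]
  cross <- which(post > baseline + 2 * bsd)
  list(peak_ms = peak_ms,
       crossing_ms = if (length(cross)) psth$t[post_idx[cross[1L]]] else
         NA_real_)
}

#' Exclude cells with no significant call response
#'
#' A cell is retained iff it has a significant response (flag) to at least
#' one syllable of at least one call; cells with zero flags across the full
#' stimulus set are excluded (the inclusion filter applied before
#' discriminability and decoding analyses).
#'
#' @param flags_by_cell A list (one element per cell) of logical vectors or
#'   lists of per-call flag vectors.
#' @param group Optional group label per cell (for the report).
#' @return A list: `keep` (logical), `report` (excluded ids and per-group
#'   counts).
#' @export
exclude_nonresponsive <- function(flags_by_cell, group = NULL) {
  keep <- vapply(flags_by_cell, function(f) any(unlist(f)), logical(1L))
  excluded <- which(!keep)
  report <- list(
    excluded_ids = excluded,
    n_excluded = length(excluded),
    n_retained = sum(keep)
  )
  if (!is.null(group)) {
    report$by_group <- table(factor(group)[!keep])
  }
  list(keep = keep, report = report)
}

#' Group comparison: Kruskal-Wallis with LSD-gated pairwise rank tests
#'
#' Omnibus Kruskal-Wallis across groups; pairwise two-sided rank-sum
#' (Mann-Whitney) comparisons are reported, unadjusted, only when the
#' omnibus test is significant (the nonparametric analogue of Fisher's
#' protected LSD).
#'
#' @param groups Named list of numeric vectors (>= 2 groups of >= 2 values).
#' @param alpha Omnibus gate (default 0.05).
#' @return A list: `omnibus_p`, `pairwise` (symmetric p matrix or `NULL`
#'   when not gated open).
#' @export
group_comparison <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs >= 2 values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  pairwise <- NULL
  if (is.finite(kw$p.value) && kw$p.value < alpha) {
    k <- length(groups)
    pairwise <- matrix(NA_real_, k, k,
                       dimnames = list(names(groups), names(groups)))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        p <- suppressWarnings(stats::wilcox.test(
          groups[[i]], groups[[j]], exact = FALSE)$p.value)
        pairwise[i, j] <- pairwise[j, i] <- p
      }
    }
  }
  list(omnibus_p = kw$p.value, pairwise = pairwise)
}
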