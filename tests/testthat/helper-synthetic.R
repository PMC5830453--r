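# Shared fixture builders. Everything is generated in code under fixed seeds.

# A call with n evenly spaced syllables of equal duration (s).
make_call <- function(name = "USV", n = 6, syl_dur = 0.08, gap = 0.15,
                      total = 3) {
  onsets <- (seq_len(n) - 1) * (syl_dur + gap)
  call_stimulus(name, syllables(onsets, rep(syl_dur, n)), total)
}

# Per-neuron trials x syllables Poisson count matrices for one class.
make_null_counts <- function(n_neurons, n_trials = 20, n_syl = 2,
                             lambda = 2.5) {
  lapply(seq_len(n_neurons), function(i) {
    matrix(stats::rpois(n_trials * n_syl, lambda), n_trials)
  })
}

# Simulated per-neuron syllable-count matrices for two stimuli given each
# neuron's evoked-rate vectors (a list with elements A and B, sp/s per
# syllable). Rates enter through the package's own spike-train simulator.
counts_from_rates <- function(rate_list, calls, n_trials = 20, seed = 1L) {
  lapply(seq_along(rate_list), function(i) {
    nm <- neuron_model(5, rate_list[[i]], latency_ms = 10,
                       latency_jitter_sd_ms = 2, response_duration_ms = 80)
    out <- lapply(names(calls), function(sid) {
      sched <- build_call_protocol(calls[[sid]], n_trials, 0, isi = 1,
                                   seed = derive_seed(seed, i))
      ts <- simulate_spike_trains(
        nm, sched, calls,
        seed = derive_seed(seed, i * 100L + match(sid, names(calls))))
      syllable_counts(ts, calls[[sid]])
    })
    names(out) <- names(calls)
    out
  })
}

# Brute-force spike detection oracle: naive sample-by-sample scan with the
# same contract (one spike at the extremum of each suprathreshold segment,
# short gaps merged, times rounded to ms, deduplicated). Independent of the
# rle-based implementation.
naive_detect <- function(samples, sample_rate, thr, refractory_ms = 1) {
  gap_limit <- max(1, ceiling(refractory_ms / 1000 * sample_rate) - 1)
  times <- integer(0)
  in_seg <- FALSE
  peak_val <- -Inf
  peak_idx <- NA_integer_
  gap <- 0L
  for (i in seq_along(samples)) {
    if (samples[i] > thr) {
      if (!in_seg) {
        in_seg <- TRUE
        peak_val <- samples[i]
        peak_idx <- i
      } else if (samples[i] > peak_val) {
        peak_val <- samples[i]
        peak_idx <- i
      }
      gap <- 0L
    } else if (in_seg) {
      gap <- gap + 1L
      if (gap > gap_limit || i == length(samples)) {
        times <- c(times, peak_idx)
        in_seg <- FALSE
        gap <- 0L
      }
    }
  }
  if (in_seg) times <- c(times, peak_idx)
  sort(unique(round((times - 1) / sample_rate * 1000)))
}
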