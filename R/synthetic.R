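#' Parametric model of one recorded neuron
#'
#' Generative description used by the simulators: Poisson-like spontaneous
#' firing plus rectangular evoked responses locked to syllable (or tone)
#' onsets. Evoked rates are ADDITIVE: during a response window the
#' instantaneous rate is `spont_rate + evoked`.
#'
#' @param spont_rate Spontaneous rate, spikes/s.
#' @param evoked_rates Named list, one numeric vector per stimulus id with an
#'   additive evoked rate (spikes/s) per syllable; for tones, a single-value
#'   vector per stimulus.
#' @param latency_ms Mean response latency after syllable onset (ms).
#' @param latency_jitter_sd_ms SD of the Gaussian per-trial latency jitter,
#'   truncated at zero (ms).
#' @param response_duration_ms Duration of the rectangular evoked response
#'   window (ms).
#' @param label Population label, `"TRAP"` or `"nonTRAP"`.
#' @return An object of class `neuron_model`.
#' @export
neuron_model <- function(spont_rate, evoked_rates = list(),
                         latency_ms = 15, latency_jitter_sd_ms = 3,
                         response_duration_ms = 100, label = "nonTRAP") {
  if (spont_rate < 0) stop("`spont_rate` must be >= 0", call. = FALSE)
  if (any(unlist(evoked_rates) < 0)) {
    stop("evoked rates must be >= 0", call. = FALSE)
  }
  stopifnot_scalar_pos(response_duration_ms, "response_duration_ms")
  if (latency_jitter_sd_ms < 0) {
    stop("`latency_jitter_sd_ms` must be >= 0", call. = FALSE)
  }
  structure(
    list(spont_rate = spont_rate, evoked_rates = evoked_rates,
         latency_ms = latency_ms,
         latency_jitter_sd_ms = latency_jitter_sd_ms,
         response_duration_ms = response_duration_ms,
         label = match.arg(label, c("TRAP", "nonTRAP"))),
    class = "neuron_model"
  )
}

# Homogeneous Poisson spike times (ms) on [t0, t1) at `rate` spikes/s.
rpoisson_times <- function(rate, t0_ms, t1_ms) {
  if (rate <= 0 || t1_ms <= t0_ms) return(numeric(0))
  n <- stats::rpois(1L, rate * (t1_ms - t0_ms) / 1000)
  sort(stats::runif(n, t0_ms, t1_ms))
}

#' Simulate per-trial spike trains for one neuron
#'
#' Draws spikes from an inhomogeneous Poisson process: a constant
#' spontaneous rate over the whole trial window, plus, for every syllable of
#' the presented stimulus, an additive evoked rate over a rectangular window
#' starting `latency_ms` (with truncated-Gaussian per-trial jitter) after
#' syllable onset. Times are in ms relative to stimulus onset.
#'
#' @param neuron A `neuron_model`.
#' @param schedule A `stim_schedule` (one trial per event).
#' @param calls Named list of `call_stimulus` objects keyed by stimulus id;
#'   events whose id is not found are treated as single-"syllable" stimuli
#'   starting at time 0 with the schedule's event duration.
#' @param seed Integer seed.
#' @param pre_ms,post_ms Trial window extent before onset / after stimulus
#'   offset (ms).
#' @return A `trial_set` (see [trial_set()]); the generated spike times are
#'   the ground truth.
#' @export
simulate_spike_trains <- function(neuron, schedule, calls = list(), seed,
                                  pre_ms = 1000, post_ms = 500) {
  stopifnot(inherits(neuron, "neuron_model"),
            inherits(schedule, "stim_schedule"))
  dur_ms <- schedule$event_duration * 1000
  with_seed(seed, {
    trains <- lapply(seq_len(nrow(schedule$events)), function(i) {
      sid <- schedule$events$stimulus_id[i]
      spk <- rpoisson_times(neuron$spont_rate, -pre_ms, dur_ms + post_ms)
      if (!is.null(calls[[sid]])) {
        onsets <- calls[[sid]]$syllables$onset * 1000
        durs <- calls[[sid]]$syllables$duration * 1000
      } else {
        onsets <- 0
        durs <- dur_ms
      }
      ev <- neuron$evoked_rates[[sid]]
      if (!is.null(ev) && any(ev > 0)) {
        ev <- rep_len(ev, length(onsets))
        for (k in seq_along(onsets)) {
          # per-trial latency: Gaussian around latency_ms, truncated at 0
          start <- onsets[k] + max(0, stats::rnorm(
            1L, neuron$latency_ms, neuron$latency_jitter_sd_ms))
          spk <- c(spk, rpoisson_times(ev[k], start,
                                       start + neuron$response_duration_ms))
        }
        spk <- sort(spk)
      }
      spk
    })
    trial_set(trains,
              stimulus_id = schedule$events$stimulus_id[1L],
              pre_ms = pre_ms, post_ms = post_ms,
              stim_duration_ms = dur_ms,
              level = schedule$events$level[1L])
  })
}

#' Biphasic extracellular spike template
#'
#' A 1-ms-wide biphasic waveform (positive lobe then smaller negative lobe)
#' sampled at `sample_rate`, peak normalized to `amplitude`.
#'
#' @param sample_rate Sampling rate (Hz).
#' @param amplitude Peak amplitude (trace units).
#' @param width_ms Total width (ms); default 1.
#' @return Numeric vector; the maximum is at the template's peak sample.
#' @export
spike_template <- function(sample_rate = 10000, amplitude = 1, width_ms = 1) {
  n <- max(3L, round(width_ms / 1000 * sample_rate))
  t <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * t) * exp(-3 * t)
  amplitude * w / max(w)
}

#' Synthesize a loose-patch voltage trace from spike times
#'
#' The trace is the sum of a spike template centred at each spike time plus
#' white Gaussian noise and an optional slow sinusoidal drift (what a 100-Hz
#' high-pass filter removes). Template peaks align with spike times to
#' within one sample.
#'
#' @param spike_times_ms Spike times (ms from trace start).
#' @param duration_s Trace length (s).
#' @param sample_rate Sampling rate (Hz); default 10 kHz.
#' @param template Spike waveform ([spike_template()] by default).
#' @param noise_sd Gaussian noise SD (trace units).
#' @param drift_amplitude Amplitude of a 1-Hz sinusoidal drift (default 0).
#' @param seed Integer seed.
#' @return A `voltage_trace` (see [voltage_trace()]).
#' @export
synthesize_trace <- function(spike_times_ms, duration_s,
                             sample_rate = 10000,
                             template = spike_template(sample_rate),
                             noise_sd = 0.1, drift_amplitude = 0, seed = 1L) {
  stopifnot_scalar_pos(duration_s, "duration_s")
  if (max(template) <= 0) stop("template peak amplitude must be > 0",
                               call. = FALSE)
  n <- round(duration_s * sample_rate)
  if (length(spike_times_ms) &&
      (any(spike_times_ms < 0) || any(spike_times_ms / 1000 >= duration_s))) {
    stop("spike times fall outside the trace", call. = FALSE)
  }
  peak_off <- which.max(template) - 1L
  x <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  if (drift_amplitude > 0) {
    x <- x + drift_amplitude * sin(2 * pi * 1 * seq_len(n) / sample_rate)
  }
  for (t_ms in spike_times_ms) {
    s0 <- round(t_ms / 1000 * sample_rate) - peak_off
    idx <- seq_along(template) + s0
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + template[keep]
  }
  voltage_trace(x, sample_rate = sample_rate, t0 = 0)
}

#' Simulate a fluorescence micrograph of labeled nuclei
#'
#' Places `n_cells` disc-shaped nuclei in an 8-bit image, applies a linear
#' multiplicative illumination gradient along the image diagonal (corner-to-
#' corner intensity ratio `1 + illumination_gradient`) and per-pixel Poisson
#' noise. A stated fraction of cells is placed touching a neighbour to
#' exercise watershed splitting.
#'
#' @param n_cells Number of nuclei (>= 0).
#' @param size Length-2 integer, image size in pixels (rows, cols).
#' @param cell_radius Nucleus radius (px).
#' @param intensity Disc intensity (0-255), must exceed `background`.
#' @param background Background intensity (0-255).
#' @param illumination_gradient Fractional gradient along the diagonal.
#' @param overlap_fraction Fraction of cells placed touching a neighbour.
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix, 0-255) and `centroids`
#'   (data.frame `x`, `y` in pixel coordinates) as ground truth.
#' @export
simulate_fluorescence_image <- function(n_cells, size = c(256L, 256L),
                                        cell_radius = 6,
                                        intensity = 160, background = 30,
                                        illumination_gradient = 0,
                                        overlap_fraction = 0, seed = 1L) {
  if (intensity <= background) {
    stop("`intensity` must exceed `background`", call. = FALSE)
  }
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  nr <- size[1L]; nc <- size[2L]
  r <- cell_radius
  with_seed(seed, {
    centers <- matrix(numeric(0), ncol = 2L)
    n_touch <- round(n_cells * overlap_fraction)
    margin <- r + 2
    min_sep <- 2 * r + 3   # disjoint cells stay separated
    tries <- 0L
    while (nrow(centers) < n_cells) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_cells)) {
        stop("could not place cells within overlap constraints", call. = FALSE)
      }
      i <- nrow(centers) + 1L
      if (i > n_cells - n_touch && nrow(centers) > 0L) {
        # touching cell: centers 1.7 radii apart (discs overlap by ~30% of r)
        j <- sample.int(nrow(centers), 1L)
        ang <- stats::runif(1L, 0, 2 * pi)
        cand <- centers[j, ] + 1.7 * r * c(cos(ang), sin(ang))
        if (any(cand < margin) || cand[1L] > nr - margin ||
            cand[2L] > nc - margin) next
        others <- if (nrow(centers) > 1L) centers[-j, , drop = FALSE] else
          matrix(numeric(0), ncol = 2L)
        if (nrow(others) && min(sqrt(rowSums(
          (others - matrix(cand, nrow(others), 2L, byrow = TRUE))^2))) <
          min_sep) next
      } else {
        cand <- c(stats::runif(1L, margin, nr - margin),
                  stats::runif(1L, margin, nc - margin))
        if (nrow(centers) && min(sqrt(rowSums(
          (centers - matrix(cand, nrow(centers), 2L, byrow = TRUE))^2))) <
          min_sep) next
      }
      centers <- rbind(centers, cand)
    }
    img <- matrix(background, nr, nc)
    if (n_cells > 0L) {
      rows <- row(img); cols <- col(img)
      for (i in seq_len(nrow(centers))) {
        d2 <- (rows - centers[i, 1L])^2 + (cols - centers[i, 2L])^2
        img[d2 <= r^2] <- intensity
      }
    }
    if (illumination_gradient != 0) {
      t <- (row(img) / nr + col(img) / nc) / 2        # 0..1 along diagonal
      img <- img * (1 + illumination_gradient * t)
    }
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), nr, nc)
    img <- pmin(pmax(img, 0), 255)
    list(image = img,
         centroids = if (nrow(centers)) {
           data.frame(x = centers[, 1L], y = centers[, 2L])
         } else {
           data.frame(x = numeric(0), y = numeric(0))
         })
  })
}

#' Configuration of a simulated two-population recording session
#'
#' @param n_trap,n_nontrap Neurons per population.
#' @param spont_mean,spont_sd Spontaneous-rate distribution (spikes/s).
#' @param evoked_mean_trap,evoked_mean_nontrap Mean additive evoked rate per
#'   syllable (spikes/s) for each population.
#' @param evoked_sd Between-neuron SD of evoked rates.
#' @param seed Master seed; all sub-streams derive from it.
#' @return A `population_config` list.
#' @export
population_config <- function(n_trap = 30, n_nontrap = 30,
                              spont_mean = 5, spont_sd = 2,
                              evoked_mean_trap = 40,
                              evoked_mean_nontrap = 20,
                              evoked_sd = 8, seed = 1L) {
  stopifnot(n_trap >= 1, n_nontrap >= 1, spont_sd >= 0, evoked_sd >= 0)
  structure(list(n_trap = n_trap, n_nontrap = n_nontrap,
                 spont_mean = spont_mean, spont_sd = spont_sd,
                 evoked_mean_trap = evoked_mean_trap,
                 evoked_mean_nontrap = evoked_mean_nontrap,
                 evoked_sd = evoked_sd, seed = as.integer(seed)),
            class = "population_config")
}

#' Draw a heterogeneous population of neuron models
#'
#' Per-neuron spontaneous and per-syllable evoked rates are drawn from
#' truncated (at zero) Gaussians around the population means; the TRAP
#' population differs only in its evoked-rate mean.
#'
#' @param config A [population_config()].
#' @param calls Named list of `call_stimulus` objects; each neuron gets one
#'   evoked-rate vector per call (one entry per syllable).
#' @return A list with elements `TRAP` and `nonTRAP`, each a list of
#'   `neuron_model`s.
#' @export
simulate_population <- function(config, calls) {
  draw <- function(n, mu, sd) pmax(0, stats::rnorm(n, mu, sd))
  make_pop <- function(n, ev_mean, label, seed_off) {
    lapply(seq_len(n), function(i) {
      with_seed(derive_seed(config$seed, seed_off + i), {
        ev <- lapply(calls, function(cl) {
          draw(nrow(cl$syllables), ev_mean, config$evoked_sd)
        })
        names(ev) <- vapply(calls, `[[`, "", "name")
        neuron_model(
          spont_rate = draw(1L, config$spont_mean, config$spont_sd),
          evoked_rates = ev, latency_ms = 10, latency_jitter_sd_ms = 2,
          response_duration_ms = 80, label = label)
      })
    })
  }
  list(TRAP = make_pop(config$n_trap, config$evoked_mean_trap, "TRAP", 0L),
       nonTRAP = make_pop(config$n_nontrap, config$evoked_mean_nontrap,
                          "nonTRAP", 100000L))
}

#' Simulate a full experimental session
#'
#' Generates everything the downstream pipeline consumes: per-neuron,
#' per-stimulus trial sets for both populations (20 trials at the highest
#' intensity per stimulus by default), plus ground truth. Fully reproducible
#' under the config seed.
#'
#' @param config A [population_config()].
#' @param calls Named list of `call_stimulus` objects (the stimulus set).
#' @param n_trials Trials per stimulus per neuron (default 20).
#' @return A list: `neurons` (the models), `trials[[population]][[neuron]]
#'   [[stimulus]]` trial sets, `calls`, `config`.
#' @export
simulate_experiment <- function(config, calls, n_trials = 20) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    names(calls) <- vapply(calls, `[[`, "", "name")
  }
  pops <- simulate_population(config, calls)
  trials <- lapply(names(pops), function(pop) {
    lapply(seq_along(pops[[pop]]), function(i) {
      neuron <- pops[[pop]][[i]]
      out <- lapply(names(calls), function(sid) {
        sched <- build_call_protocol(calls[[sid]], n_trials, 0, isi = 1,
                                     seed = derive_seed(config$seed, 7L))
        simulate_spike_trains(
          neuron, sched, calls,
          seed = derive_seed(config$seed,
                             match(pop, names(pops)) * 1000000L +
                               i * 1000L + match(sid, names(calls))))
      })
      names(out) <- names(calls)
      out
    })
  })
  names(trials) <- names(pops)
  list(neurons = pops, trials = trials, calls = calls, config = config)
}
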