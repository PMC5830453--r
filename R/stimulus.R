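#' Syllable annotation table
#'
#' Builds and validates a syllable annotation: onset and duration (seconds)
#' of each syllable relative to the start of the call. Syllables must be
#' sorted by onset and non-overlapping.
#'
#' @param onset Numeric vector of syllable onsets (s, >= 0).
#' @param duration Numeric vector of syllable durations (s, > 0).
#' @return A `data.frame` with columns `onset` and `duration`.
#' @export
syllables <- function(onset, duration) {
  if (length(onset) != length(duration) || length(onset) < 1L) {
    stop("`onset` and `duration` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(onset)) || any(!is.finite(duration))) {
    stop("syllable onsets and durations must be finite", call. = FALSE)
  }
  if (any(onset < 0)) stop("syllable onsets must be >= 0", call. = FALSE)
  if (any(duration <= 0)) stop("syllable durations must be > 0", call. = FALSE)
  if (is.unsorted(onset, strictly = TRUE)) {
    stop("syllables must be sorted by onset", call. = FALSE)
  }
  ends <- onset + duration
  if (length(onset) > 1L && any(ends[-length(ends)] > onset[-1L] + 1e-12)) {
    stop("syllables must not overlap", call. = FALSE)
  }
  data.frame(onset = as.numeric(onset), duration = as.numeric(duration))
}

#' Construct a natural call stimulus
#'
#' A call stimulus is a named vocalization (e.g., a pup ultrasonic
#' vocalization "USV" or a wriggling call "WC") with syllable annotations,
#' a fixed playback unit duration, and optionally the audio waveform.
#'
#' @param name Stimulus label.
#' @param syl Syllable table from [syllables()].
#' @param total_duration Playback unit length in seconds (default 3 s).
#' @param waveform Optional numeric sample vector.
#' @param sample_rate Waveform sample rate (Hz); required with `waveform`.
#' @return An object of class `call_stimulus`.
#' @export
call_stimulus <- function(name, syl, total_duration = 3,
                          waveform = NULL, sample_rate = NULL) {
  stopifnot_scalar_pos(total_duration, "total_duration")
  if (!is.data.frame(syl) || !all(c("onset", "duration") %in% names(syl))) {
    stop("`syl` must be a syllable table (see syllables())", call. = FALSE)
  }
  syl <- syllables(syl$onset, syl$duration)
  if (any(syl$onset + syl$duration > total_duration + 1e-12)) {
    stop("all syllables must lie within [0, total_duration)", call. = FALSE)
  }
  if (!is.null(waveform)) {
    if (is.null(sample_rate)) {
      stop("`sample_rate` is required when a waveform is supplied",
           call. = FALSE)
    }
    stopifnot_scalar_pos(sample_rate, "sample_rate")
    waveform <- as.numeric(waveform)
  }
  structure(
    list(name = as.character(name), syllables = syl,
         total_duration = total_duration,
         waveform = waveform, sample_rate = sample_rate),
    class = "call_stimulus"
  )
}

#' @export
print.call_stimulus <- function(x, ...) {
  cat(sprintf("<call_stimulus> %s: %d syllables over %.3g s%s\n",
              x$name, nrow(x$syllables), x$total_duration,
              if (is.null(x$waveform)) "" else
                sprintf(", waveform %d samples @ %g Hz",
                        length(x$waveform), x$sample_rate)))
  invisible(x)
}

new_stim_schedule <- function(events, kind, event_duration, isi) {
  if (is.unsorted(events$onset, strictly = TRUE)) {
    stop("schedule onsets must be strictly increasing", call. = FALSE)
  }
  structure(
    list(events = events, kind = kind,
         event_duration = event_duration, isi = isi),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %s: %d events, event duration %g s, ISI %g s (offset-to-onset)\n",
              x$kind, nrow(x$events), x$event_duration, x$isi))
  invisible(x)
}

#' Repeated single-tone (or single-call) playback schedule
#'
#' Tiles `[0, total_time]` with identical stimulus presentations at a fixed
#' period of `tone_duration + isi` (ISI is offset-to-onset). A partial final
#' period is dropped, so the event count is
#' `floor(total_time / (tone_duration + isi))`: a 1-h session of 100-ms tones
#' with 900-ms ISI yields 3600 presentations, and 3-s calls with 1-s ISI
#' yield 900.
#'
#' @param tone_duration Stimulus duration (s).
#' @param isi Inter-stimulus interval, offset to onset (s).
#' @param total_time Session length (s).
#' @param freq Tone frequency (Hz); stored as the stimulus id.
#' @param level Playback level (dB SPL), metadata only.
#' @return A `stim_schedule` whose `events` have columns
#'   `onset`, `stimulus_id`, `level`.
#' @export
build_tone_protocol <- function(tone_duration, isi, total_time,
                                freq = NA_real_, level = NA_real_) {
  stopifnot_scalar_pos(tone_duration, "tone_duration")
  stopifnot_scalar_pos(isi, "isi")
  stopifnot_scalar_pos(total_time, "total_time")
  period <- tone_duration + isi
  n <- floor(total_time / period + 1e-9)
  if (n < 1L) stop("total_time shorter than one stimulus period", call. = FALSE)
  events <- data.frame(
    onset = (seq_len(n) - 1) * period,
    stimulus_id = rep(as.character(if (is.na(freq)) "stim" else freq), n),
    level = rep(as.numeric(level), n)
  )
  new_stim_schedule(events, kind = "tone",
                    event_duration = tone_duration, isi = isi)
}

#' Frequency-response-area (FRA) tone schedule
#'
#' A balanced pseudo-random grid of pure tones: `n_freqs` log-spaced
#' frequencies crossed with a list of sound levels, each combination
#' presented `n_reps` times, in a single seeded shuffle of the full trial
#' list. The standard protocol (30 frequencies from 3-40 kHz, 4 levels,
#' 12 repetitions) yields 1440 trials.
#'
#' @param n_freqs Number of tone frequencies.
#' @param freq_range Length-2 numeric, frequency range in Hz (log-spaced).
#' @param levels Numeric vector of sound levels (dB SPL).
#' @param n_reps Repetitions per frequency x level combination.
#' @param isi Inter-stimulus interval, offset to onset (s).
#' @param tone_duration Tone duration (s); default 0.1.
#' @param seed Integer seed for the trial-order shuffle.
#' @return A `stim_schedule`; `events` has columns
#'   `onset`, `stimulus_id`, `freq`, `level`.
#' @export
build_fra_protocol <- function(n_freqs, freq_range, levels, n_reps, isi,
                               tone_duration = 0.1, seed) {
  stopifnot_scalar_pos(n_freqs, "n_freqs")
  stopifnot_scalar_pos(n_reps, "n_reps")
  stopifnot_scalar_pos(isi, "isi")
  stopifnot_scalar_pos(tone_duration, "tone_duration")
  if (length(levels) < 1L) stop("`levels` must be non-empty", call. = FALSE)
  if (length(freq_range) != 2L || any(freq_range <= 0)) {
    stop("`freq_range` must be two positive frequencies", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  freqs <- if (n_freqs == 1L) freq_range[1L] else
    exp(seq(log(freq_range[1L]), log(freq_range[2L]), length.out = n_freqs))
  grid <- expand.grid(freq = freqs, level = as.numeric(levels),
                      rep = seq_len(n_reps), KEEP.OUT.ATTRS = FALSE)
  ord <- with_seed(seed, sample.int(nrow(grid)))
  grid <- grid[ord, , drop = FALSE]
  n <- nrow(grid)
  events <- data.frame(
    onset = (seq_len(n) - 1) * (tone_duration + isi),
    stimulus_id = sprintf("%.6g Hz @ %g dB", grid$freq, grid$level),
    freq = grid$freq, level = grid$level
  )
  new_stim_schedule(events, kind = "tone",
                    event_duration = tone_duration, isi = isi)
}

#' Natural-call playback schedule over attenuation levels
#'
#' Presents one call `n_reps_per_level` times at each attenuation level
#' (dB below the maximum playback level), in a seeded shuffled order.
#' The standard protocol (20 repetitions at 3 attenuations) yields 60 trials.
#'
#' @param call A `call_stimulus`.
#' @param n_reps_per_level Presentations per attenuation level.
#' @param attenuations Numeric vector of attenuations (dB re: max level).
#' @param isi Inter-stimulus interval, offset to onset (s).
#' @param seed Integer seed for the trial-order shuffle.
#' @return A `stim_schedule`; `events` has columns
#'   `onset`, `stimulus_id`, `level` (attenuation dB).
#' @export
build_call_protocol <- function(call, n_reps_per_level, attenuations, isi,
                                seed = 1L) {
  if (!inherits(call, "call_stimulus")) {
    stop("`call` must be a call_stimulus", call. = FALSE)
  }
  stopifnot_scalar_pos(n_reps_per_level, "n_reps_per_level")
  stopifnot_scalar_pos(isi, "isi")
  if (length(attenuations) < 1L) {
    stop("`attenuations` must be non-empty", call. = FALSE)
  }
  atten <- rep(as.numeric(attenuations), each = n_reps_per_level)
  atten <- with_seed(seed, sample(atten))
  n <- length(atten)
  events <- data.frame(
    onset = (seq_len(n) - 1) * (call$total_duration + isi),
    stimulus_id = rep(call$name, n),
    level = atten
  )
  new_stim_schedule(events, kind = "call",
                    event_duration = call$total_duration, isi = isi)
}

#' Time-reverse the audio inside each syllable window
#'
#' Produces the "flipped" variant of a call: within every annotated syllable
#' window the waveform samples are reversed in place, while samples between
#' syllables and the annotations themselves are unchanged. Windows are
#' half-open `[onset, onset + duration)` in samples. The operation is an
#' involution and preserves total signal energy.
#'
#' @param call A `call_stimulus` with a waveform.
#' @return A `call_stimulus` with the per-syllable-reversed waveform and the
#'   name suffixed `-flip` (a second flip removes the suffix).
#' @export
flip_syllables <- function(call) {
  if (!inherits(call, "call_stimulus")) {
    stop("`call` must be a call_stimulus", call. = FALSE)
  }
  if (is.null(call$waveform)) {
    stop("flip_syllables requires a call with a waveform", call. = FALSE)
  }
  w <- call$waveform
  fs <- call$sample_rate
  for (i in seq_len(nrow(call$syllables))) {
    a <- floor(call$syllables$onset[i] * fs) + 1L
    b <- min(floor((call$syllables$onset[i] + call$syllables$duration[i]) * fs),
             length(w))
    if (b >= a) w[a:b] <- w[b:a]
  }
  out <- call
  out$waveform <- w
  out$name <- if (endsWith(call$name, "-flip")) {
    sub("-flip$", "", call$name)
  } else {
    paste0(call$name, "-flip")
  }
  out
}

#' Write / read a stimulus schedule as CSV
#'
#' The event table is written as plain CSV; schedule-level metadata (kind,
#' event duration, ISI) goes in commented header lines so a single file
#' round-trips.
#'
#' @param schedule A `stim_schedule`.
#' @param path Output CSV path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a `stim_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s event_duration=%.10g isi=%.10g",
                     schedule$kind, schedule$event_duration, schedule$isi),
             con)
  utils::write.csv(schedule$events, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "kind=(\\S+) event_duration=(\\S+) isi=(\\S+)", hdr))[[1L]]
  if (length(m) != 4L) stop("not a schedule CSV: ", path, call. = FALSE)
  events <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  new_stim_schedule(events, kind = m[2L],
                    event_duration = as.numeric(m[3L]),
                    isi = as.numeric(m[4L]))
}

#' Write / read syllable annotations as CSV
#'
#' Columns: `name`, `onset_s`, `duration_s`.
#'
#' @param call A `call_stimulus`.
#' @param path CSV path.
#' @export
write_syllable_csv <- function(call, path) {
  utils::write.csv(
    data.frame(name = call$name,
               onset_s = call$syllables$onset,
               duration_s = call$syllables$duration),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_syllable_csv
#' @param total_duration Playback unit length (s) for the reconstructed call.
#' @export
read_syllable_csv <- function(path, total_duration = 3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  call_stimulus(df$name[1L], syllables(df$onset_s, df$duration_s),
                total_duration = total_duration)
}
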