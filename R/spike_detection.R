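#' Raw voltage trace container
#'
#' @param samples Numeric sample vector (trace units).
#' @param sample_rate Sampling rate (Hz); the acquisition standard here is
#'   10 kHz.
#' @param t0 Time of the first sample on the schedule clock (s).
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, sample_rate = 10000, t0 = 0) {
  stopifnot_scalar_pos(sample_rate, "sample_rate")
  if (!length(samples) || any(!is.finite(samples))) {
    stop("`samples` must be a non-empty finite numeric vector", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate, t0 = t0),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g Hz (%.3g s), t0 = %g s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$t0))
  invisible(x)
}

#' Zero-phase high-pass filter for loose-patch recordings
#'
#' Removes DC and slow drift before spike thresholding. A 2nd-order
#' Butterworth high-pass applied forward and backward (`signal::filtfilt`),
#' giving a zero-phase 4th-order magnitude response: spike peak times are
#' not shifted.
#'
#' @param trace A `voltage_trace`.
#' @param cutoff High-pass cutoff (Hz), default 100; must be below Nyquist.
#' @return The filtered `voltage_trace`.
#' @export
highpass_filter <- function(trace, cutoff = 100) {
  stopifnot(inherits(trace, "voltage_trace"))
  stopifnot_scalar_pos(cutoff, "cutoff")
  nyq <- trace$sample_rate / 2
  if (cutoff >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq),
         call. = FALSE)
  }
  bf <- signal::butter(2, cutoff / nyq, type = "high")
  x <- trace$samples
  # reflect-pad so filter start-up transients fall outside the trace
  pad <- min(length(x) - 1L, ceiling(3 * trace$sample_rate / cutoff))
  xp <- c(2 * x[1L] - rev(x[2L:(pad + 1L)]), x,
          2 * x[length(x)] - rev(x[(length(x) - pad):(length(x) - 1L)]))
  y <- as.numeric(signal::filtfilt(bf, xp))
  out <- trace
  out$samples <- y[(pad + 1L):(pad + length(x))]
  out
}

# Robust noise scale from the rectified trace: median(|x|)/0.6745 estimates
# the Gaussian SD (the standard extracellular-detection estimator, immune to
# the spikes themselves).
robust_sigma <- function(x) stats::median(abs(x)) / 0.6745

#' Threshold-based spike detection
#'
#' Finds contiguous suprathreshold segments of the (polarity-corrected)
#' trace and assigns one spike per segment at its extremum sample, rounded
#' to the nearest millisecond. Segments separated by less than
#' `refractory_ms` of sub-threshold samples are merged, and duplicate
#' millisecond times after rounding are collapsed to one spike.
#'
#' The automatic threshold is `median(|x|) + k * median(|x|)/0.6745` on the
#' rectified filtered trace (default `k = 5`, about 5.7 noise SDs on
#' Gaussian noise). Polarity `"auto"` rectifies toward whichever sign shows
#' the heavier-tailed (larger-kurtosis) excursions, so detection is
#' invariant to the sign convention of the amplifier.
#'
#' @param trace A `voltage_trace` (already high-pass filtered, or set
#'   `apply_filter = TRUE`).
#' @param threshold `"auto"` or a numeric threshold in trace units.
#' @param polarity `"auto"`, `"pos"` or `"neg"`.
#' @param k Multiplier for the automatic threshold.
#' @param refractory_ms Minimum sub-threshold gap between distinct segments.
#' @param apply_filter If `TRUE`, run [highpass_filter()] first.
#' @return A `spike_train`: integer-ms spike times relative to `t0`, sorted,
#'   deduplicated.
#' @export
detect_spikes <- function(trace, threshold = "auto", polarity = "auto",
                          k = 5, refractory_ms = 1, apply_filter = FALSE) {
  stopifnot(inherits(trace, "voltage_trace"))
  x <- trace$samples
  if (!length(x) || all(is.na(x))) {
    stop("trace is empty or all-NA", call. = FALSE)
  }
  if (apply_filter) x <- highpass_filter(trace)$samples
  polarity <- match.arg(polarity, c("auto", "pos", "neg"))
  if (polarity == "auto") {
    # heavier-tailed sign carries the spikes: compare the kurtosis of the
    # positive and negative half-rectified traces (zeros kept, so sparse
    # noiseless traces are handled too)
    kurt_half <- function(v) {
      v <- pmax(v, 0)
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) return(-Inf)
      mean(((v - mean(v)) / s)^4)
    }
    polarity <- if (kurt_half(-x) > kurt_half(x)) "neg" else "pos"
  }
  y <- if (polarity == "neg") -x else x
  thr <- if (identical(threshold, "auto")) {
    stats::median(abs(x)) + k * robust_sigma(x)
  } else {
    as.numeric(threshold)
  }
  above <- y > thr
  if (!any(above)) {
    return(spike_train(numeric(0)))
  }
  # merge segments separated by < refractory_ms of sub-threshold samples
  gap <- max(1L, ceiling(refractory_ms / 1000 * trace$sample_rate) - 1L)
  r <- rle(above)
  short_gap <- !r$values & r$lengths <= gap
  # interior short gaps become suprathreshold
  if (length(r$values) > 2L) {
    interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    r$values[short_gap & interior] <- TRUE
  }
  above <- inverse.rle(r)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- which(r$values)
  peaks <- vapply(seg, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    i0 + which.max(y[i0:i1]) - 1L
  }, integer(1L))
  t_ms <- round((peaks - 1L) / trace$sample_rate * 1000 + trace$t0 * 1000)
  spike_train(unique(sort(t_ms)))
}

#' Spike train container
#'
#' @param times_ms Spike times in integer milliseconds (relative to the
#'   trace/trial clock); sorted and deduplicated on construction.
#' @param neuron_id Optional source neuron identifier.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_ms, neuron_id = NA_character_) {
  times_ms <- sort(unique(as.integer(round(times_ms))))
  structure(list(times = times_ms, neuron_id = neuron_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes%s\n", length(x$times),
              if (is.na(x$neuron_id)) "" else paste0(" (", x$neuron_id, ")")))
  invisible(x)
}

#' Write / read voltage traces as raw float32 + JSON sidecar
#'
#' Samples are stored little-endian 32-bit float; sampling rate and `t0` go
#' in a JSON sidecar at `<path>.json`.
#'
#' @param trace A `voltage_trace`.
#' @param path Binary file path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(sample_rate = trace$sample_rate, t0 = trace$t0,
         n_samples = length(trace$samples), dtype = "float32le"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = meta$n_samples, size = 4L,
               endian = "little")
  voltage_trace(x, sample_rate = meta$sample_rate, t0 = meta$t0)
}

#' Write / read spike tables as CSV
#'
#' Long format with columns `neuron_id`, `trial`, `time_ms`.
#'
#' @param spikes A list of per-trial spike-time vectors, or a `trial_set`.
#' @param neuron_id Identifier written to the table.
#' @param path CSV path.
#' @export
write_spike_csv <- function(spikes, path, neuron_id = "n1") {
  if (inherits(spikes, "trial_set")) spikes <- spikes$spikes
  df <- do.call(rbind, lapply(seq_along(spikes), function(i) {
    if (!length(spikes[[i]])) return(NULL)
    data.frame(neuron_id = neuron_id, trial = i, time_ms = spikes[[i]])
  }))
  if (is.null(df)) {
    df <- data.frame(neuron_id = character(0), trial = integer(0),
                     time_ms = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param n_trials Total number of trials (trailing empty trials are not
#'   representable in the long format).
#' @export
read_spike_csv <- function(path, n_trials = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) && (any(is.na(df$trial)) || any(is.na(df$time_ms)))) {
    bad <- which(is.na(df$trial) | is.na(df$time_ms))[1L]
    stop(sprintf("corrupted spike table %s: row %d", path, bad),
         call. = FALSE)
  }
  n <- if (is.null(n_trials)) max(df$trial, 0L) else n_trials
  lapply(seq_len(n), function(i) sort(df$time_ms[df$trial == i]))
}
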