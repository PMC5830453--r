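# Build a trial_set whose PSTH has exactly `counts[b]` spikes in bin `b`
# (one trial, spikes at bin centres; pre-window bins stay empty).
ts_from_counts <- function(counts, t_first = 0, pre_ms = 200,
                           stim_ms = 200, post_ms = 100) {
  times <- rep(seq_along(counts) - 1 + t_first + 0.5, counts)
  trial_set(list(times), pre_ms = pre_ms, post_ms = post_ms,
            stim_duration_ms = stim_ms)
}

test_that("PSTHs conserve spike counts in 1-ms bins", {
  ts <- trial_set(rep(list(10.4), 60), pre_ms = 100, post_ms = 50,
                  stim_duration_ms = 100)
  psth <- compute_psth(ts)
  expect_equal(psth$counts[psth$t == 10], 60)
  expect_equal(sum(psth$counts), 60)

  empty <- trial_set(rep(list(numeric(0)), 5), pre_ms = 100, post_ms = 0,
                     stim_duration_ms = 100)
  expect_true(all(compute_psth(empty)$counts == 0))

  set.seed(2)
  for (i in 1:20) {
    spikes <- lapply(1:10, function(j) runif(rpois(1, 20), -500, 600))
    rts <- trial_set(spikes, pre_ms = 500, post_ms = 100,
                     stim_duration_ms = 500)
    expect_equal(sum(compute_psth(rts)$counts), sum(lengths(spikes)))
  }
})

test_that("spontaneous rates use the designated pre-stimulus windows", {
  # 4 spikes inside [-1000, -200) ms, one trial -> 5 sp/s
  ts <- trial_set(list(c(-900, -700, -500, -300)), pre_ms = 1000,
                  post_ms = 0, stim_duration_ms = 100)
  expect_equal(spontaneous_rate(ts, "natural"), 5)
  expect_equal(spontaneous_rate(trial_set(list(numeric(0)), pre_ms = 1000),
                                "natural"), 0)
  # tone mode: 2 spikes in the last 100 ms before onset -> 20 sp/s
  ts2 <- trial_set(list(c(-90, -10)), pre_ms = 100, post_ms = 0,
                   stim_duration_ms = 100)
  expect_equal(spontaneous_rate(ts2, "tone"), 20)
  expect_error(spontaneous_rate(ts2, "natural"), "1000 ms")

  # Poisson recovery at 5 sp/s over 60 trials
  nm <- neuron_model(5, list())
  sched <- build_tone_protocol(3, 1, 240)
  sim <- simulate_spike_trains(nm, sched, seed = 19, pre_ms = 1000)
  se <- sqrt(5 / (0.8 * 60))
  expect_lt(abs(spontaneous_rate(sim, "natural") - 5), 3 * se)
})

test_that("evoked windows follow the fixed and syllable-length rules", {
  cl <- call_stimulus("c", syllables(c(0, 0.5), c(0.15, 0.05)), 3)
  # syllable 1 is 150 ms long: fixed rule windows 100 ms, long rule 150 ms
  ts <- trial_set(list(c(seq(5, 145, length.out = 6), 510)), pre_ms = 1000,
                  post_ms = 100, stim_duration_ms = 3000)
  fixed <- evoked_rate_syllables(ts, cl, "fixed")
  expect_equal(fixed$windows$end - fixed$windows$start, c(100, 100))
  fig7 <- evoked_rate_syllables(ts, cl, "fig7")
  expect_equal(fig7$windows$end - fig7$windows$start, c(150, 100))
  # 6 spikes in the 150 ms window, 1 trial -> 40 sp/s
  expect_equal(fig7$per_syllable[1], 40)
  # 5 spikes in 100 ms -> 50 sp/s
  ts5 <- trial_set(list(seq(5, 95, length.out = 5)), pre_ms = 1000,
                   post_ms = 0, stim_duration_ms = 3000)
  expect_equal(evoked_rate_syllables(ts5, cl, "fixed")$per_syllable[1], 50)
  # the cell value is the mean over syllables
  expect_equal(mean(c(10, 20, 30)), 20)
  expect_equal(fig7$mean, mean(fig7$per_syllable))
})

test_that("evoked windows truncate at the next syllable with a warning", {
  cl <- call_stimulus("c", syllables(c(0, 0.08), c(0.05, 0.05)), 3)
  ts <- trial_set(list(c(10, 90)), pre_ms = 100, post_ms = 0,
                  stim_duration_ms = 3000)
  expect_warning(ev <- evoked_rate_syllables(ts, cl, "fixed"), "truncated")
  expect_equal(ev$windows$end[1], 80)
})

test_that("FWHM windows match hand-derived extents", {
  # triangle sampled at bin centres: height 40 - 2|t+0.5-50|, baseline 0;
  # half-max 19.5 is reached on bins 40..59 -> window [40, 60), width 20
  tri <- pmax(0, 40 - 2 * abs((0:199) + 0.5 - 50))
  w <- fwhm_window(compute_psth(ts_from_counts(tri)), smoothing_sd = 0)
  expect_equal(c(w$start, w$end), c(40, 60))

  # rectangular pulse: window = the pulse extent
  rect <- integer(200); rect[21:50] <- 3   # bins 20..49
  wr <- fwhm_window(compute_psth(ts_from_counts(rect)), smoothing_sd = 0)
  expect_equal(c(wr$start, wr$end), c(20, 50))

  # two equal peaks: one window from first left-crossing to last right-crossing
  two <- integer(200); two[11:20] <- 5; two[71:80] <- 5
  w2 <- fwhm_window(compute_psth(ts_from_counts(two)), smoothing_sd = 0)
  expect_equal(c(w2$start, w2$end), c(10, 80))

  # scale invariance: tripling every count leaves the window unchanged
  tri3 <- trial_set(rep(list(rep((0:199) + 0.5, tri)), 3), pre_ms = 200,
                    post_ms = 100, stim_duration_ms = 200)
  w3 <- fwhm_window(compute_psth(tri3), smoothing_sd = 0)
  expect_equal(c(w3$start, w3$end), c(w$start, w$end))

  flat <- trial_set(list(seq(-99.5, 199.5, by = 1)), pre_ms = 100,
                    post_ms = 100, stim_duration_ms = 100)
  expect_error(fwhm_window(compute_psth(flat), smoothing_sd = 0),
               "no response")
})

test_that("syllable significance flags real responses and only those", {
  win <- response_window(0, 100, "FWHM")
  strong <- trial_set(rep(list(seq(5, 95, length.out = 10)), 60),
                      pre_ms = 1000, post_ms = 0, stim_duration_ms = 200)
  res <- syllable_significance(strong, win, rep(0, 60))
  expect_lt(res$p, 0.001)
  expect_true(res$flag)

  same <- trial_set(rep(list(50), 30), pre_ms = 1000, post_ms = 0,
                    stim_duration_ms = 200)
  res2 <- syllable_significance(same, win, rep(10, 30))  # identical rates
  expect_false(res2$flag)

  # n_responded counts flags across a call's syllables
  cl <- make_call("c", 4, syl_dur = 0.08, gap = 0.25)
  nm <- neuron_model(5, list(c = c(60, 0, 60, 0)), latency_ms = 5,
                     latency_jitter_sd_ms = 1, response_duration_ms = 80)
  sched <- build_call_protocol(cl, 40, 0, 1, seed = 2)
  sim <- simulate_spike_trains(nm, sched, list(c = cl), seed = 12)
  sig <- call_significance(sim, cl, spontaneous_rate(sim, "natural",
                                                     per_trial = TRUE))
  expect_equal(sig$n_responded, sum(sig$flags))
  expect_true(sig$flags[1] && sig$flags[3])
})

test_that("FRA construction, normalization and tuning parameters", {
  win <- response_window(0, 100, "FWHM")
  mk_ts <- function(n_spk) {
    trial_set(lapply(1:12, function(i) seq_len(n_spk) * 90 / max(n_spk, 1)),
              pre_ms = 100, post_ms = 0, stim_duration_ms = 100)
  }
  freqs <- rep(c(4000, 12000), each = 2)
  levels <- rep(c(48, 78), 2)
  trials <- list(mk_ts(0), mk_ts(1), mk_ts(2), mk_ts(8))  # max at 12 kHz/78
  fra <- compute_fra(trials, freqs, levels, win)
  expect_equal(max(fra$fra_normalized), 1)
  expect_equal(fra$fra["78", "12000"], 80)  # 8 spikes / 100 ms
  expect_equal(best_frequency(fra), 12000)
  expect_equal(characteristic_frequency(fra), 12000)

  # single nonzero entry -> exactly one 1 in the normalized matrix
  fra1 <- compute_fra(list(mk_ts(0), mk_ts(0), mk_ts(0), mk_ts(3)),
                      freqs, levels, win)
  expect_equal(sum(fra1$fra_normalized == 1), 1)
  # all-zero matrix flagged, not divided
  fra0 <- compute_fra(list(mk_ts(0), mk_ts(0), mk_ts(0), mk_ts(0)),
                      freqs, levels, win)
  expect_true(fra0$all_zero)
  expect_error(best_frequency(fra0), "no response")
})

test_that("BF/CF/latency agree with a brute-force argmax oracle", {
  set.seed(31)
  for (i in 1:200) {
    nf <- sample(3:8, 1); nl <- sample(2:4, 1)
    m <- matrix(rpois(nf * nl, 3), nl, nf)
    freqs <- sort(sample(seq(3000, 40000, by = 500), nf))
    fra <- list(fra = m, fra_normalized = m / max(max(m), 1), freqs = freqs,
                levels = seq_len(nl), all_zero = all(m == 0))
    if (fra$all_zero) next
    # oracle: global argmax (lowest frequency on ties)
    bf_oracle <- min(freqs[unique(which(m == max(m), arr.ind = TRUE)[, 2])])
    cf_oracle <- freqs[which.max(colMeans(m))]
    expect_equal(best_frequency(fra), bf_oracle)
    expect_equal(characteristic_frequency(fra), cf_oracle)
  }
  # latency: PSTH peak bin (earliest on ties), plus the 2-SD crossing variant
  ts <- trial_set(rep(list(c(18.5, 18.2, 40.5)), 20), pre_ms = 100,
                  post_ms = 0, stim_duration_ms = 100)
  lat <- response_latency(compute_psth(ts), smoothing_sd = 0)
  expect_equal(lat$peak_ms, 18)
  expect_equal(lat$crossing_ms, 18)
})

test_that("cells without any significant call response are excluded", {
  flags <- c(
    rep(list(list(a = c(TRUE, FALSE), b = rep(FALSE, 3))), 16),
    rep(list(list(a = rep(FALSE, 2), b = rep(FALSE, 3))), 3),
    rep(list(list(a = c(FALSE, TRUE), b = c(TRUE, TRUE, FALSE))), 16)
  )
  grp <- rep(c("TRAP", "none", "nonTRAP"), c(16, 3, 16))
  res <- exclude_nonresponsive(flags, group = grp)
  expect_equal(res$report$n_retained, 32)
  expect_equal(res$report$n_excluded, 3)
  expect_equal(unname(res$report$by_group["none"]), 3L)
  expect_true(res$keep[1])
  expect_false(res$keep[17])
})

test_that("group comparisons gate pairwise tests on the omnibus", {
  same <- list(a = 1:30 / 10, b = 1:30 / 10, c = 1:30 / 10)
  res <- group_comparison(same)
  expect_gt(res$omnibus_p, 0.9)
  expect_null(res$pairwise)

  set.seed(8)
  shifted <- list(a = rnorm(30), b = rnorm(30, 5))  # 5 SD shift
  res2 <- group_comparison(shifted)
  expect_lt(res2$omnibus_p, 0.001)
  expect_lt(res2$pairwise["a", "b"], 0.001)

  three <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 4))
  res3 <- group_comparison(three)
  expect_lt(res3$pairwise["a", "c"], 0.01)
  expect_lt(res3$pairwise["b", "c"], 0.01)
  expect_gt(res3$pairwise["a", "b"], 0.05)
  expect_error(group_comparison(list(a = 1, b = 1:5)), ">= 2 values")
})
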