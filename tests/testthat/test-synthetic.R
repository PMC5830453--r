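test_that("spontaneous spike counts match the Poisson law", {
  nm <- neuron_model(5, list())
  sched <- build_tone_protocol(1, 1, 120)  # 60 trials
  ts <- simulate_spike_trains(nm, sched, seed = 11, pre_ms = 1000,
                              post_ms = 0)
  # counts over the 1-s pre-window: Poisson(5) per trial, 60 trials
  counts <- vapply(ts$spikes, function(s) sum(s < 0), numeric(1))
  se <- sqrt(5 / 60)
  expect_lt(abs(mean(counts) - 5), 3 * se)
  # window-level invariant: mean within 4*sqrt(lambda*T/N) for lambda*T*N >= 100
  expect_lt(abs(mean(counts) - 5), 4 * sqrt(5 / 60) + 1e-12)
})

test_that("zero rates give empty trains and seeds give reproducibility", {
  nm0 <- neuron_model(0, list())
  sched <- build_tone_protocol(1, 1, 20)
  ts0 <- simulate_spike_trains(nm0, sched, seed = 1)
  expect_true(all(lengths(ts0$spikes) == 0))

  nm <- neuron_model(4, list())
  a <- simulate_spike_trains(nm, sched, seed = 5)
  b <- simulate_spike_trains(nm, sched, seed = 5)
  d <- simulate_spike_trains(nm, sched, seed = 6)
  expect_identical(a$spikes, b$spikes)
  expect_false(identical(a$spikes, d$spikes))
})

test_that("synthesized traces place template peaks at spike times", {
  tr <- synthesize_trace(c(50), 1, 10000, noise_sd = 0, seed = 1)
  expect_equal(which.max(tr$samples), 50 / 1000 * 10000 + 1, tolerance = 1)
  expect_error(synthesize_trace(c(2000), 1, 10000), "outside")
  # pure noise stays below the detection threshold almost everywhere
  tn <- synthesize_trace(numeric(0), 10, 10000, noise_sd = 0.1, seed = 3)
  expect_lte(length(detect_spikes(highpass_filter(tn))$times), 1)
})

test_that("simulated micrographs honour count, gradient and reproducibility", {
  empty <- simulate_fluorescence_image(0, c(64, 64), seed = 1)
  expect_equal(nrow(empty$centroids), 0)
  expect_lt(max(empty$image), 255 * 0.5)

  sim <- simulate_fluorescence_image(20, c(256, 256), 6, 200, 20,
                                     overlap_fraction = 0, seed = 2)
  expect_equal(nrow(sim$centroids), 20)
  lab <- EBImage::bwlabel(EBImage::Image((sim$image > 100) * 1))
  expect_equal(max(lab), 20)  # disjoint by construction

  g <- simulate_fluorescence_image(0, c(200, 200), 6, 160, 100,
                                   illumination_gradient = 0.5, seed = 3)
  ratio <- mean(g$image[190:200, 190:200]) / mean(g$image[1:10, 1:10])
  expect_equal(ratio, 1.5, tolerance = 0.05)

  again <- simulate_fluorescence_image(20, c(256, 256), 6, 200, 20,
                                       overlap_fraction = 0, seed = 2)
  expect_identical(sim$image, again$image)
  expect_error(simulate_fluorescence_image(5, intensity = 30,
                                           background = 40), "exceed")
})

test_that("generated artifacts round-trip losslessly through the writers", {
  tr <- synthesize_trace(c(10, 20, 30), 0.1, 10000, noise_sd = 0.05,
                         seed = 9)
  f <- tempfile()
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$sample_rate, tr$sample_rate)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)  # float32

  spikes <- list(c(1, 5, 900), numeric(0), c(250))
  f2 <- tempfile(fileext = ".csv")
  write_spike_csv(spikes, f2)
  expect_equal(read_spike_csv(f2, n_trials = 3), spikes)

  img <- simulate_fluorescence_image(5, c(64, 64), seed = 4)$image
  f3 <- tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(img / 255), f3, bits.per.sample = 8L)
  back_img <- round(EBImage::imageData(EBImage::readImage(f3)) * 255)
  expect_equal(as.numeric(back_img), as.numeric(img))  # 8-bit exact
})

test_that("a simulated session feeds every downstream stage", {
  calls <- list(A = make_call("A", 3), B = make_call("B", 3))
  cfg <- population_config(n_trap = 3, n_nontrap = 3, seed = 21)
  sess <- simulate_experiment(cfg, calls, n_trials = 8)
  expect_named(sess$trials, c("TRAP", "nonTRAP"))
  ts <- sess$trials$TRAP[[1]]$A
  expect_s3_class(ts, "trial_set")
  expect_equal(ts$n_trials, 8)
  psth <- compute_psth(ts)
  expect_equal(sum(psth$counts), sum(lengths(ts$spikes)))
  # seed change: schedule identical, spikes differ
  sess2 <- simulate_experiment(population_config(n_trap = 3, n_nontrap = 3,
                                                 seed = 22), calls,
                               n_trials = 8)
  expect_false(identical(sess$trials$TRAP[[1]]$A$spikes,
                         sess2$trials$TRAP[[1]]$A$spikes))
})

test_that("a 2x evoked-rate difference is detectable across populations", {
  # power check at n = 30/30: compare per-neuron mean evoked rates
  calls <- list(A = make_call("A", 4))
  cfg <- population_config(n_trap = 30, n_nontrap = 30,
                           evoked_mean_trap = 40, evoked_mean_nontrap = 20,
                           seed = 33)
  sess <- simulate_experiment(cfg, calls, n_trials = 10)
  rate_of <- function(pop) {
    vapply(sess$trials[[pop]], function(nr) {
      evoked_rate_syllables(nr$A, calls$A, "fixed")$mean
    }, numeric(1))
  }
  p <- suppressWarnings(
    stats::wilcox.test(rate_of("TRAP"), rate_of("nonTRAP"))$p.value)
  expect_lt(p, 0.05)
})
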