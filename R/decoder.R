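#' Trials x syllables spike-count matrix for one neuron and stimulus
#'
#' Counts spikes per trial in each syllable's decoding window (100 ms or the
#' syllable length, whichever is longer, following syllable onset).
#'
#' @param trials A `trial_set`.
#' @param call The presented `call_stimulus`.
#' @param n_syllables Use only the first `n_syllables` syllables.
#' @return Integer matrix, `n_trials` x `n_syllables`.
#' @export
syllable_counts <- function(trials, call,
                            n_syllables = nrow(call$syllables)) {
  stopifnot(inherits(trials, "trial_set"), inherits(call, "call_stimulus"))
  n_syllables <- min(n_syllables, nrow(call$syllables))
  on_ms <- call$syllables$onset[seq_len(n_syllables)] * 1000
  dur_ms <- call$syllables$duration[seq_len(n_syllables)] * 1000
  ends <- on_ms + pmax(100, dur_ms)
  m <- vapply(seq_len(n_syllables), function(k) {
    vapply(trials$spikes, function(s) {
      sum(s >= on_ms[k] & s < ends[k])
    }, numeric(1L))
  }, numeric(trials$n_trials))
  matrix(as.integer(m), nrow = trials$n_trials)
}

#' Assemble a pseudo-population feature matrix
#'
#' Rows are pseudo-trials (`n_trials` per class), columns are neuron x
#' syllable spike counts. Because neurons were recorded in separate
#' sessions, each neuron's real trials are assigned to pseudo-trials by an
#' independent seeded permutation, so each real trial is used exactly once
#' per class (column sums are permutation-invariant).
#'
#' @param counts_a,counts_b Lists (one element per neuron) of trials x
#'   syllables count matrices (from [syllable_counts()]) for the two
#'   stimuli/classes.
#' @param n_syllables Number of leading syllable columns to use.
#' @param seed Integer seed for the per-neuron permutations.
#' @return A list of class `feature_matrix`: `x` (2*n_trials x
#'   n_neurons*n_syllables), `y` (factor `"A"`/`"B"`), `n_trials`,
#'   `n_syllables`.
#' @export
build_feature_matrix <- function(counts_a, counts_b, n_syllables, seed) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 1L)
  n_trials <- nrow(counts_a[[1L]])
  ok <- vapply(seq_along(counts_a), function(i) {
    nrow(counts_a[[i]]) == n_trials && nrow(counts_b[[i]]) == n_trials
  }, logical(1L))
  if (!all(ok)) {
    warning(sprintf("%d neuron(s) excluded: trial count != %d",
                    sum(!ok), n_trials))
    counts_a <- counts_a[ok]; counts_b <- counts_b[ok]
  }
  ns <- min(n_syllables, ncol(counts_a[[1L]]))
  with_seed(seed, {
    blocks <- lapply(seq_along(counts_a), function(i) {
      pa <- sample.int(n_trials)
      pb <- sample.int(n_trials)
      rbind(counts_a[[i]][pa, seq_len(ns), drop = FALSE],
            counts_b[[i]][pb, seq_len(ns), drop = FALSE])
    })
    x <- do.call(cbind, blocks)
    structure(list(x = x,
                   y = factor(rep(c("A", "B"), each = n_trials)),
                   n_trials = n_trials, n_syllables = ns),
              class = "feature_matrix")
  })
}

# Standardize columns by training-set statistics; zero-variance columns are
# centred only (they carry no information and must not produce NaN).
standardize_by_train <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sd, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sd, "/"))
}

#' Linear-SVM decoding of a stimulus pair
#'
#' The repeated-split decoding protocol: on each iteration the per-neuron
#' pseudo-trial assignment is refreshed, 18 of the 20 trials per class train
#' a linear-kernel SVM (cost `C`), and the held-out 2 trials per class are
#' scored; the result is the mean accuracy over iterations. Features are
#' standardized per column using training-set statistics only. Every
#' iteration derives its own seed from `(seed, iteration)`, so results are
#' fully reproducible.
#'
#' @param counts_a,counts_b Per-neuron count matrices (see
#'   [build_feature_matrix()]).
#' @param n_syllables Leading syllables used as features.
#' @param n_iterations Number of random splits (default 1000).
#' @param n_test Held-out trials per class per iteration (default 2, i.e.
#'   an 18/2 split of 20 trials).
#' @param cost SVM cost parameter (default 1).
#' @param seed Integer base seed.
#' @return An object of class `decoder_result`: `accuracy` (mean),
#'   `per_iteration`, `n_iterations`, `n_syllables`.
#' @export
decode_pair <- function(counts_a, counts_b, n_syllables,
                        n_iterations = 1000, n_test = 2, cost = 1, seed = 1L) {
  stopifnot(n_iterations >= 1L)
  acc <- numeric(n_iterations)
  n_trials <- nrow(counts_a[[1L]])
  if (n_trials <= n_test) stop("too few trials for the split", call. = FALSE)
  for (it in seq_len(n_iterations)) {
    it_seed <- derive_seed(seed, it)
    fm <- build_feature_matrix(counts_a, counts_b, n_syllables,
                               seed = it_seed)
    sel <- with_seed(derive_seed(it_seed, 1L), {
      c(sample.int(n_trials, n_test),
        n_trials + sample.int(n_trials, n_test))
    })
    train_x <- fm$x[-sel, , drop = FALSE]
    test_x <- fm$x[sel, , drop = FALSE]
    std <- standardize_by_train(train_x, test_x)
    pred <- tryCatch({
      fit <- e1071::svm(std$train, fm$y[-sel], kernel = "linear",
                        cost = cost, scale = FALSE)
      stats::predict(fit, std$test)
    }, error = function(e) {
      # degenerate features: fall back to the majority (tied) class
      factor(rep(levels(fm$y)[1L], length(sel)), levels = levels(fm$y))
    })
    acc[it] <- mean(pred == fm$y[sel])
  }
  structure(list(accuracy = mean(acc), per_iteration = acc,
                 n_iterations = n_iterations, n_syllables = n_syllables,
                 n_train = n_trials - n_test, n_test = n_test),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf(
    "<decoder_result> accuracy %.3f over %d iterations (%d syllables)\n",
    x$accuracy, x$n_iterations, x$n_syllables))
  invisible(x)
}

#' Cumulative-syllable decoding accuracy curves
#'
#' Runs [decode_pair()] for 1 up to `max_syllables` leading syllables for
#' each stimulus pair and each population, and returns tidy per-point
#' accuracies plus TRAP-minus-nonTRAP difference curves. Curves are
#' truncated at a stimulus's own syllable count when shorter.
#'
#' @param populations Named list (e.g., `TRAP`, `nonTRAP`); each element is
#'   a list keyed by stimulus id of per-neuron count-matrix lists (i.e.
#'   `populations[[pop]][[stim]][[neuron]]` is a trials x syllables matrix).
#' @param target_stim The reference stimulus compared against each other.
#' @param comparison_stims Stimulus ids compared with `target_stim`.
#' @param max_syllables Upper syllable count (default 6).
#' @param n_iterations Iterations per classifier.
#' @param seed Integer base seed.
#' @param cost SVM cost.
#' @return A list: `curves` (data.frame population, pair, n_syllables,
#'   accuracy), `difference` (data.frame pair, n_syllables, delta) when both
#'   populations are present.
#' @export
accuracy_curve <- function(populations, target_stim, comparison_stims,
                           max_syllables = 6, n_iterations = 1000,
                           seed = 1L, cost = 1) {
  rows <- list()
  for (pop in names(populations)) {
    for (stim in comparison_stims) {
      ca <- populations[[pop]][[target_stim]]
      cb <- populations[[pop]][[stim]]
      if (is.null(ca) || is.null(cb)) {
        stop(sprintf("population '%s' lacks stimulus data", pop),
             call. = FALSE)
      }
      ns_max <- min(max_syllables, ncol(ca[[1L]]), ncol(cb[[1L]]))
      for (ns in seq_len(ns_max)) {
        res <- decode_pair(ca, cb, ns, n_iterations = n_iterations,
                           cost = cost,
                           seed = derive_seed(seed,
                                              match(pop, names(populations)) *
                                                100000L +
                                                match(stim, comparison_stims) *
                                                100L + ns))
        rows[[length(rows) + 1L]] <- data.frame(
          population = pop, pair = paste(target_stim, "vs", stim),
          n_syllables = ns, accuracy = res$accuracy)
      }
    }
  }
  curves <- do.call(rbind, rows)
  difference <- NULL
  if (all(c("TRAP", "nonTRAP") %in% names(populations))) {
    a <- curves[curves$population == "TRAP", ]
    b <- curves[curves$population == "nonTRAP", ]
    m <- merge(a, b, by = c("pair", "n_syllables"),
               suffixes = c("_trap", "_nontrap"))
    difference <- data.frame(pair = m$pair, n_syllables = m$n_syllables,
                             delta = m$accuracy_trap - m$accuracy_nontrap)
    difference <- difference[order(difference$pair,
                                   difference$n_syllables), ]
  }
  list(curves = curves, difference = difference)
}
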