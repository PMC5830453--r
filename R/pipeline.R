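#' Default pipeline configuration
#'
#' Returns the full nested configuration driving [run_pipeline()]; every
#' stochastic stage draws from sub-seeds derived from the single top-level
#' `seed`. Override any entry by passing a partial list (or YAML file) to
#' [run_pipeline()]; unknown keys are rejected.
#'
#' @param seed Top-level integer seed.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, metrics = TRUE, dprime = TRUE,
                  decode = TRUE, imaging = TRUE),
    population = list(n_trap = 12, n_nontrap = 12, spont_mean = 5,
                      spont_sd = 2, evoked_mean_trap = 40,
                      evoked_mean_nontrap = 20, evoked_sd = 8),
    stimuli = list(n_calls = 3, n_syllables = 6, syllable_duration = 0.08,
                   syllable_gap = 0.25, n_trials = 20),
    metrics = list(window_rule = "fig7", smoothing_sd = 5, alpha = 0.05),
    decoder = list(n_iterations = 100, max_syllables = 6, cost = 1),
    imaging = list(conditions = c("No Stim", "Stim"), n_animals = 3,
                   cells_a1 = c(30, 60), cells_s1 = 30,
                   size = c(256L, 256L), cell_radius = 6, intensity = 160,
                   background = 30, illumination_gradient = 0.3,
                   overlap_fraction = 0.1, threshold = 50, min_area = 20,
                   pixel_size_um = 2, thickness_um = 40, n_sections = 2)
  ), class = "run_config")
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

# Evenly spaced synthetic syllable annotations for a generated call.
make_synthetic_call <- function(name, n_syllables, syllable_duration,
                                syllable_gap, total_duration = 3) {
  onsets <- (seq_len(n_syllables) - 1) * (syllable_duration + syllable_gap)
  call_stimulus(name, syllables(onsets, rep(syllable_duration, n_syllables)),
                total_duration = total_duration)
}

#' Simulate a histology cohort and quantify fold induction
#'
#' Generates per-animal, per-region fluorescence sections with
#' condition-specific true cell numbers, runs the counting pipeline
#' (top-hat + median filter, `>threshold` binarization, watershed), and
#' computes per-animal densities and fold induction relative to the
#' baseline condition.
#'
#' @param cfg The `imaging` sub-list of [default_config()].
#' @param seed Integer seed.
#' @param baseline Baseline condition label.
#' @return A list: `fold` (from [fold_induction()]), `sections`
#'   (per-section data.frame with true and detected counts).
#' @export
simulate_histology <- function(cfg, seed = 1L, baseline = "No Stim") {
  rows <- list(); animals <- list()
  aidx <- 0L
  for (ci in seq_along(cfg$conditions)) {
    for (a in seq_len(cfg$n_animals)) {
      aidx <- aidx + 1L
      dens <- list()
      for (region in c("A1", "S1")) {
        n_true <- if (region == "A1") cfg$cells_a1[ci] else cfg$cells_s1
        counts <- integer(cfg$n_sections)
        areas <- numeric(cfg$n_sections)
        for (s in seq_len(cfg$n_sections)) {
          sim <- simulate_fluorescence_image(
            n_true, size = cfg$size, cell_radius = cfg$cell_radius,
            intensity = cfg$intensity, background = cfg$background,
            illumination_gradient = cfg$illumination_gradient,
            overlap_fraction = cfg$overlap_fraction,
            seed = derive_seed(seed, aidx * 1000L + ci * 100L +
                                 s * 10L + (region == "A1")))
          pre <- preprocess_image(sim$image, cell_radius = cfg$cell_radius)
          seg <- segment_nuclei(pre, threshold = cfg$threshold,
                                min_area = cfg$min_area)
          counts[s] <- seg$count
          areas[s] <- prod(cfg$size)   # whole-frame mask
          rows[[length(rows) + 1L]] <- data.frame(
            animal = aidx, condition = cfg$conditions[ci], region = region,
            section = s, true_cells = n_true, detected = seg$count)
        }
        dens[[region]] <- compute_density(counts, areas, cfg$pixel_size_um,
                                          cfg$thickness_um)$density
      }
      animals[[aidx]] <- data.frame(
        animal = aidx, condition = cfg$conditions[ci],
        density_a1 = dens$A1, density_s1 = dens$S1)
    }
  }
  list(fold = fold_induction(do.call(rbind, animals), baseline = baseline),
       sections = do.call(rbind, rows))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on a fully synthetic
#' session: simulate spike trains for a TRAP and a non-TRAP population,
#' compute response metrics and the inclusion filter, d-prime matrices and
#' their per-pixel group comparison, cumulative-syllable decoding curves,
#' and the histology counting/fold-induction stage. All outputs are plain
#' CSV/JSON under `out_dir`, plus a manifest recording the config and seed;
#' the same config and seed reproduce byte-identical outputs.
#'
#' @param config A partial config list, a YAML file path, or `NULL` for
#'   defaults.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Optional override of the config seed.
#' @return The report bundle (invisibly when writing): a list with
#'   `metrics`, `exclusion`, `dprime`, `decoding`, `histology`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  bundle <- list()

  calls <- lapply(seq_len(cfg$stimuli$n_calls), function(i) {
    make_synthetic_call(paste0("call", i), cfg$stimuli$n_syllables,
                        cfg$stimuli$syllable_duration,
                        cfg$stimuli$syllable_gap)
  })
  names(calls) <- vapply(calls, `[[`, "", "name")

  if (isTRUE(cfg$stages$simulate)) {
    pc <- population_config(
      n_trap = cfg$population$n_trap, n_nontrap = cfg$population$n_nontrap,
      spont_mean = cfg$population$spont_mean,
      spont_sd = cfg$population$spont_sd,
      evoked_mean_trap = cfg$population$evoked_mean_trap,
      evoked_mean_nontrap = cfg$population$evoked_mean_nontrap,
      evoked_sd = cfg$population$evoked_sd, seed = cfg$seed)
    session <- simulate_experiment(pc, calls,
                                   n_trials = cfg$stimuli$n_trials)
    bundle$session <- session
  } else {
    stop("run_pipeline currently requires the simulate stage", call. = FALSE)
  }

  if (isTRUE(cfg$stages$metrics)) {
    met <- list(); flags <- list(); grp <- character(0)
    i_row <- 0L
    for (pop in names(session$trials)) {
      for (i in seq_along(session$trials[[pop]])) {
        i_row <- i_row + 1L
        cell_flags <- list(); rates <- list()
        for (sid in names(calls)) {
          ts <- session$trials[[pop]][[i]][[sid]]
          spont <- spontaneous_rate(ts, "natural", per_trial = TRUE)
          sig <- call_significance(ts, calls[[sid]], spont,
                                   window_rule = cfg$metrics$window_rule,
                                   smoothing_sd = cfg$metrics$smoothing_sd,
                                   alpha = cfg$metrics$alpha)
          ev <- evoked_rate_syllables(ts, calls[[sid]],
                                      window_rule = cfg$metrics$window_rule)
          cell_flags[[sid]] <- sig$flags
          rates[[sid]] <- ev$per_syllable
          met[[length(met) + 1L]] <- data.frame(
            population = pop, neuron = i, stimulus = sid,
            spont_rate = mean(spont), evoked_rate = ev$mean,
            n_responded = sig$n_responded)
        }
        flags[[i_row]] <- cell_flags
        grp[i_row] <- pop
        attr(flags[[i_row]], "rates") <- rates
      }
    }
    bundle$metrics <- do.call(rbind, met)
    bundle$exclusion <- exclude_nonresponsive(flags, group = grp)
    bundle$.rates <- lapply(flags, attr, "rates")
    bundle$.groups <- grp
  }

  if (isTRUE(cfg$stages$dprime)) {
    keep <- bundle$exclusion$keep
    dms <- lapply(c("TRAP", "nonTRAP"), function(pop) {
      sel <- bundle$.groups == pop & keep
      dprime_matrix(bundle$.rates[sel], names(calls), group = pop)
    })
    names(dms) <- c("TRAP", "nonTRAP")
    bundle$dprime <- list(
      matrices = dms,
      comparison = compare_matrices(dms$TRAP, dms$nonTRAP))
  }

  if (isTRUE(cfg$stages$decode)) {
    keep <- bundle$exclusion$keep
    pops <- lapply(c("TRAP", "nonTRAP"), function(pop) {
      idx <- which(bundle$.groups == pop & keep)
      # map retained flat indices back to within-population indices
      within <- idx - min(which(bundle$.groups == pop)) + 1L
      out <- lapply(names(calls), function(sid) {
        lapply(within, function(i) {
          syllable_counts(session$trials[[pop]][[i]][[sid]], calls[[sid]])
        })
      })
      names(out) <- names(calls)
      out
    })
    names(pops) <- c("TRAP", "nonTRAP")
    target <- names(calls)[1L]
    bundle$decoding <- accuracy_curve(
      pops, target, setdiff(names(calls), target),
      max_syllables = cfg$decoder$max_syllables,
      n_iterations = cfg$decoder$n_iterations,
      seed = derive_seed(cfg$seed, 42L), cost = cfg$decoder$cost)
  }

  if (isTRUE(cfg$stages$imaging)) {
    bundle$histology <- simulate_histology(cfg$imaging,
                                           seed = derive_seed(cfg$seed, 99L),
                                           baseline = cfg$imaging$conditions[1L])
  }

  bundle$manifest <- list(
    package = "trapcode",
    version = as.character(utils::packageVersion("trapcode")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "stages")],
    stages = names(which(unlist(cfg$stages)))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bundle$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(bundle$dprime)) {
      utils::write.csv(as.data.frame(bundle$dprime$matrices$TRAP$matrix),
                       file.path(out_dir, "dprime_trap.csv"))
      utils::write.csv(as.data.frame(bundle$dprime$matrices$nonTRAP$matrix),
                       file.path(out_dir, "dprime_nontrap.csv"))
      utils::write.csv(as.data.frame(bundle$dprime$comparison$p),
                       file.path(out_dir, "dprime_pvalues.csv"))
    }
    if (!is.null(bundle$decoding)) {
      utils::write.csv(bundle$decoding$curves,
                       file.path(out_dir, "decoding_curves.csv"),
                       row.names = FALSE)
      if (!is.null(bundle$decoding$difference)) {
        utils::write.csv(bundle$decoding$difference,
                         file.path(out_dir, "decoding_difference.csv"),
                         row.names = FALSE)
      }
    }
    if (!is.null(bundle$histology)) {
      utils::write.csv(bundle$histology$fold$per_animal,
                       file.path(out_dir, "fold_per_animal.csv"),
                       row.names = FALSE)
      utils::write.csv(bundle$histology$fold$per_condition,
                       file.path(out_dir, "fold_per_condition.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(bundle$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}
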