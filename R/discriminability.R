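#' Evoked-rate distribution of one neuron to one stimulus
#'
#' Mean and SD (sample SD, n-1 denominator) of the syllable-wise evoked
#' firing rates, the distribution pair entering the d-prime computation.
#'
#' @param rates Syllable-wise evoked rates (sp/s); or supply `mu`/`sigma`
#'   directly.
#' @param mu,sigma Mean and SD (used when `rates` is missing).
#' @param n Syllable count (inferred from `rates`).
#' @param stimulus,neuron Identifiers.
#' @return An object of class `evoked_distribution`.
#' @export
evoked_distribution <- function(rates = NULL, mu = NULL, sigma = NULL,
                                n = NULL, stimulus = NA, neuron = NA) {
  if (!is.null(rates)) {
    if (length(rates) < 1L) stop("`rates` must be non-empty", call. = FALSE)
    mu <- mean(rates)
    sigma <- if (length(rates) > 1L) stats::sd(rates) else 0
    n <- length(rates)
  }
  if (is.null(mu) || is.null(sigma)) {
    stop("supply `rates` or both `mu` and `sigma`", call. = FALSE)
  }
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, n = if (is.null(n)) NA_integer_ else n,
                 stimulus = stimulus, neuron = neuron),
            class = "evoked_distribution")
}

#' d-prime discriminability between two evoked-rate distributions
#'
#' The difference in means normalized by the root of the mean of the two
#' variances:
#' \deqn{d' = (\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}}
#' Antisymmetric in its arguments; identical distributions give exactly 0.
#' When both SDs are zero the value is 0 if the means agree and undefined
#' (`NA`, excluded from matrix averages) otherwise.
#'
#' @param a,b `evoked_distribution`s from the same neuron.
#' @return A single number (possibly `NA` for the degenerate case).
#' @export
dprime <- function(a, b) {
  stopifnot(inherits(a, "evoked_distribution"),
            inherits(b, "evoked_distribution"))
  denom <- sqrt((a$sigma^2 + b$sigma^2) / 2)
  if (denom == 0) {
    if (a$mu == b$mu) return(0)
    return(NA_real_)
  }
  (a$mu - b$mu) / denom
}

#' @rdname dprime
#' @param rates_a,rates_b Syllable-wise evoked rates for the two stimuli.
#' @export
dprime_from_rates <- function(rates_a, rates_b) {
  dprime(evoked_distribution(rates_a), evoked_distribution(rates_b))
}

#' Stimulus x stimulus d-prime discriminability matrix
#'
#' For each stimulus pair, the pixel is the mean over neurons of the
#' absolute d-prime between the neuron's two evoked-rate distributions
#' (absolute values: the sign depends only on arbitrary stimulus order).
#' Undefined per-neuron values are excluded and counted. The per-neuron
#' signed tensor is retained for the between-group pixel comparison.
#'
#' @param cell_rates A list (one element per neuron) of named lists mapping
#'   stimulus id to the neuron's syllable-wise evoked rates.
#' @param stimuli Character vector of stimulus ids (matrix order).
#' @param group Population label stored on the result.
#' @return An object of class `dprime_matrix`: `matrix` (mean |d'|),
#'   `tensor` (neurons x stimuli x stimuli, signed), `n_undefined`, `group`.
#' @export
dprime_matrix <- function(cell_rates, stimuli, group = NA_character_) {
  n <- length(cell_rates)
  s <- length(stimuli)
  if (n < 1L) stop("no cells supplied", call. = FALSE)
  tensor <- array(NA_real_, c(n, s, s),
                  dimnames = list(NULL, stimuli, stimuli))
  for (c_i in seq_len(n)) {
    dists <- lapply(stimuli, function(sid) {
      r <- cell_rates[[c_i]][[sid]]
      if (is.null(r)) stop(sprintf("cell %d lacks stimulus '%s'", c_i, sid),
                           call. = FALSE)
      evoked_distribution(r, stimulus = sid, neuron = c_i)
    })
    for (i in seq_len(s)) {
      for (j in seq_len(s)) {
        tensor[c_i, i, j] <- if (i == j) 0 else dprime(dists[[i]], dists[[j]])
      }
    }
  }
  m <- apply(abs(tensor), c(2L, 3L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  diag(m) <- 0
  structure(list(matrix = m, tensor = tensor,
                 n_undefined = sum(is.na(tensor)), group = group),
            class = "dprime_matrix")
}

#' @export
print.dprime_matrix <- function(x, ...) {
  cat(sprintf("<dprime_matrix> %s: %d neurons, %d stimuli, %d undefined d'\n",
              if (is.na(x$group)) "(no group)" else x$group,
              dim(x$tensor)[1L], dim(x$tensor)[2L], x$n_undefined))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Per-pixel comparison of two groups' d-prime matrices
#'
#' For every off-diagonal stimulus pair, a two-sided Mann-Whitney test
#' between the two groups' per-neuron |d'| values; pixels with p below
#' `alpha` are flagged. Diagonal pixels (identical stimuli, d' = 0 by
#' construction) are excluded.
#'
#' @param dm_a,dm_b `dprime_matrix` objects for the two groups.
#' @param alpha Significance level for the flag matrix.
#' @return A list: `p` (symmetric matrix, `NA` diagonal), `significant`
#'   (logical matrix).
#' @export
compare_matrices <- function(dm_a, dm_b, alpha = 0.05) {
  stopifnot(inherits(dm_a, "dprime_matrix"), inherits(dm_b, "dprime_matrix"))
  stimuli <- dimnames(dm_a$tensor)[[2L]]
  stopifnot(identical(stimuli, dimnames(dm_b$tensor)[[2L]]))
  s <- length(stimuli)
  p <- matrix(NA_real_, s, s, dimnames = list(stimuli, stimuli))
  for (i in seq_len(s - 1L)) {
    for (j in (i + 1L):s) {
      va <- abs(dm_a$tensor[, i, j]); va <- va[!is.na(va)]
      vb <- abs(dm_b$tensor[, i, j]); vb <- vb[!is.na(vb)]
      if (length(va) < 2L || length(vb) < 2L) next
      pv <- if (length(unique(c(va, vb))) == 1L) 1 else
        suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  list(p = p, significant = !is.na(p) & p < alpha)
}
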