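#' Per-trial cross-correlograms for a list of pairs
#'
#' Computes the normalized cross-correlogram of every pair once so that
#' permutation analyses can reuse them (labels are shuffled, not sequences).
#'
#' @param pairs list of `sequence_pair` objects sharing one duration.
#' @param lag_range_ms maximum absolute lag (default 1000 ms).
#' @return A list with `matrix` (trials x lags) and `lags_ms`.
#' @export
trial_ccgs <- function(pairs, lag_range_ms = 1000) {
  stopifnot(length(pairs) >= 1)
  durs <- vapply(pairs, function(p) p$auditory$duration_ms, numeric(1))
  if (length(unique(durs)) != 1L) stop("all pairs must share duration_ms")
  ccgs <- lapply(pairs, normalized_xcorr, lag_range_ms = lag_range_ms)
  list(matrix = do.call(rbind, lapply(ccgs, `[[`, "values")),
       lags_ms = ccgs[[1]]$lags_ms)
}

#' Gaussian smoothing on the lag grid
#'
#' Convolution with a Gaussian kernel truncated at +/- 4 SD and renormalized
#' at the edges of the grid.
#'
#' @param values values on an equally spaced grid.
#' @param spacing grid spacing (ms).
#' @param sd_ms kernel SD in ms; `0` returns `values` unchanged.
#' @return Smoothed values, same length.
#' @keywords internal
gaussian_smooth <- function(values, spacing, sd_ms) {
  if (sd_ms <= 0) return(values)
  half <- ceiling(4 * sd_ms / spacing)
  w <- dnorm(seq.int(-half, half) * spacing, sd = sd_ms)
  n <- length(values)
  num <- stats::convolve(values, rev(w), type = "open")
  den <- stats::convolve(rep(1, n), rev(w), type = "open")
  (num / den)[(half + 1L):(half + n)]
}

#' Response-conditioned cross-correlogram difference function
#'
#' Per-trial cross-correlograms are averaged within each causality-judgement
#' class; the mean "different source" CCG is subtracted from the mean
#' "common source" CCG and the difference smoothed with a Gaussian kernel
#' (SD 80 ms). Positive values indicate sequence correlations associated
#' with "common source" judgements.
#'
#' @param pairs list of `sequence_pair` objects (or `NULL` if `ccgs` given).
#' @param responses logical/binary vector, `TRUE`/1 = "common source".
#' @param smooth_sd_ms Gaussian kernel SD (default 80 ms).
#' @param lag_range_ms maximum absolute lag (default 1000 ms).
#' @param ccgs optional precomputed [trial_ccgs()] result.
#' @return An object of class `ccg_difference` with `lags_ms`, `diff`
#'   (smoothed), `raw_diff`, `n_common`, `n_different`.
#' @export
ccg_difference <- function(pairs, responses, smooth_sd_ms = 80,
                           lag_range_ms = 1000, ccgs = NULL) {
  if (is.null(ccgs)) ccgs <- trial_ccgs(pairs, lag_range_ms)
  responses <- as.logical(responses)
  stopifnot(length(responses) == nrow(ccgs$matrix))
  if (!any(responses) || all(responses)) {
    stop("degenerate labels: both response classes must be non-empty")
  }
  raw <- colMeans(ccgs$matrix[responses, , drop = FALSE]) -
    colMeans(ccgs$matrix[!responses, , drop = FALSE])
  spacing <- diff(ccgs$lags_ms[1:2])
  structure(
    list(lags_ms = ccgs$lags_ms,
         diff = gaussian_smooth(raw, spacing, smooth_sd_ms),
         raw_diff = raw,
         n_common = sum(responses), n_different = sum(!responses),
         smooth_sd_ms = smooth_sd_ms),
    class = "ccg_difference")
}

#' Permutation null bounds for a CCG difference function
#'
#' Response labels are shuffled `n_perm` times and the smoothed difference
#' function recomputed, giving pointwise `1 - alpha` null bounds. Lags where
#' the observed difference falls outside the bounds are marked significant
#' (`+1` above, `-1` below). Significance is pointwise (uncorrected), so
#' isolated flagged lags may be Type I errors; run-lengths of consecutive
#' significant lags are reported to help judge this.
#'
#' @inheritParams ccg_difference
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed optional RNG seed.
#' @return A `ccg_difference` object with added `lower95`, `upper95`,
#'   `significant` (-1/0/+1 per lag), `n_perm`, and `sig_runs` (run lengths
#'   of consecutive significant lags).
#' @export
permutation_bounds <- function(pairs, responses, n_perm = 1000, alpha = 0.05,
                               seed = NULL, smooth_sd_ms = 80,
                               lag_range_ms = 1000, ccgs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 100) warning("n_perm < 100: permutation bounds are unstable")
  if (is.null(ccgs)) ccgs <- trial_ccgs(pairs, lag_range_ms)
  obs <- ccg_difference(NULL, responses, smooth_sd_ms, lag_range_ms, ccgs)
  responses <- as.logical(responses)
  perm <- matrix(NA_real_, n_perm, length(obs$lags_ms))
  for (b in seq_len(n_perm)) {
    perm[b, ] <- ccg_difference(NULL, sample(responses), smooth_sd_ms,
                                lag_range_ms, ccgs)$diff
  }
  obs$lower95 <- apply(perm, 2, quantile, probs = alpha / 2)
  obs$upper95 <- apply(perm, 2, quantile, probs = 1 - alpha / 2)
  obs$significant <- ifelse(obs$diff > obs$upper95, 1L,
                            ifelse(obs$diff < obs$lower95, -1L, 0L))
  runs <- rle(obs$significant != 0L)
  obs$sig_runs <- runs$lengths[runs$values]
  obs$n_perm <- n_perm
  obs
}

#' @export
print.ccg_difference <- function(x, ...) {
  cat(sprintf(
    "<ccg_difference> %d common vs %d different trials; peak diff %.3f at %.1f ms\n",
    x$n_common, x$n_different, max(x$diff), x$lags_ms[which.max(x$diff)]))
  if (!is.null(x$significant)) {
    cat(sprintf("  %d of %d lags significant (pointwise, %d permutations)\n",
                sum(x$significant != 0L), length(x$significant), x$n_perm))
  }
  invisible(x)
}

#' Write a CCG difference function as delimited text
#'
#' @param x a `ccg_difference` (with or without permutation bounds).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_ccg_difference_csv <- function(x, path) {
  df <- data.frame(lag_ms = x$lags_ms, diff = x$diff)
  if (!is.null(x$significant)) {
    df$lower95 <- x$lower95
    df$upper95 <- x$upper95
    df$sig <- x$significant
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
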