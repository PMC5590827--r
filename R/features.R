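#' Maximum click-flash offset
#'
#' The largest temporal distance between an event in one modality and its
#' nearest event in the other, a causal-inference mismatch cue: a large
#' offset signals a low likelihood of temporal correspondence.
#'
#' Three readings of "maximum offset between any sequential click and flash"
#' are provided:
#' \describe{
#'   \item{`"directional"`}{(default) for each auditory event, the distance
#'     to its nearest visual event; the maximum over auditory events. This
#'     reading reproduces the published simulation statistics for the
#'     frame-triplet generator and is the calibrated default.}
#'   \item{`"symmetric"`}{the Hausdorff distance: nearest-neighbour
#'     distances measured from both modalities, maximum over all events.}
#'   \item{`"sequential"`}{the largest gap between consecutive
#'     opposite-modality events in the merged train.}
#' }
#'
#' @param pair a `sequence_pair` with both trains non-empty.
#' @param mode offset definition (see Details).
#' @return Offset in ms (>= 0).
#' @export
max_click_flash_offset <- function(pair,
                                   mode = c("directional", "symmetric",
                                            "sequential")) {
  mode <- match.arg(mode)
  a <- pair$auditory$onsets_ms
  v <- pair$visual$onsets_ms
  if (length(a) == 0L || length(v) == 0L) {
    stop("undefined feature: both sequences must be non-empty")
  }
  nn <- function(x, y) vapply(x, function(t) min(abs(t - y)), numeric(1))
  switch(mode,
    directional = max(nn(a, v)),
    symmetric = max(nn(a, v), nn(v, a)),
    sequential = {
      t <- c(a, v)
      m <- c(rep.int(1L, length(a)), rep.int(2L, length(v)))
      o <- order(t)
      t <- t[o]; m <- m[o]
      cross <- m[-1L] != m[-length(m)]
      if (!any(cross)) 0 else max(diff(t)[cross])
    })
}

#' Proportion of synchronous click-flash pairs
#'
#' The fraction of events coded to occur at the same time in both
#' modalities: for frame-gridded (triplet) trains, the same frame index;
#' otherwise the same onset time to sub-microsecond precision. The
#' denominator is the per-modality event count (the larger count if they
#' differ, with a warning).
#'
#' @param pair a `sequence_pair` with both trains non-empty.
#' @return A fraction in `[0, 1]`.
#' @export
proportion_synchronous <- function(pair) {
  a <- pair$auditory$onsets_ms
  v <- pair$visual$onsets_ms
  if (length(a) == 0L || length(v) == 0L) {
    stop("undefined feature: both sequences must be non-empty")
  }
  if (length(a) != length(v)) {
    warning("unequal event counts; using the larger as denominator")
  }
  if (pair$algorithm == "triplet") {
    fa <- round(a / pair$auditory$frame_ms)
    fv <- round(v / pair$visual$frame_ms)
  } else {
    fa <- round(a * 1e6)
    fv <- round(v * 1e6)
  }
  length(intersect(fa, fv)) / max(length(a), length(v))
}

#' Binary frame train of an event sequence
#'
#' @param seq an `event_sequence`.
#' @return A 0/1 vector with one element per display frame.
#' @keywords internal
frame_train <- function(seq) {
  n_frames <- as.integer(round(seq$duration_ms / seq$frame_ms))
  train <- numeric(n_frames)
  if (length(seq$onsets_ms)) {
    idx <- pmin(floor(seq$onsets_ms / seq$frame_ms) + 1L, n_frames)
    train[idx] <- 1
  }
  train
}

#' Normalized cross-correlogram of an audiovisual pair
#'
#' For each temporal lag the two binary frame trains are restricted to their
#' overlapping portions, mean-subtracted, scaled to unit norm, and their dot
#' product taken, giving a correlation coefficient in `[-1, 1]` per lag.
#' Positive lag means the auditory train is delayed relative to the visual
#' train. A zero-variance overlap yields a correlation of 0 (neutral).
#'
#' @param pair a `sequence_pair`.
#' @param lag_range_ms maximum absolute lag in ms (default 1000).
#' @return An object of class `ccg` with fields `lags_ms` (symmetric about
#'   0, at frame resolution) and `values`.
#' @export
normalized_xcorr <- function(pair, lag_range_ms = 1000) {
  a <- frame_train(pair$auditory)
  v <- frame_train(pair$visual)
  n <- length(a)
  frame_ms <- pair$auditory$frame_ms
  max_lag <- min(as.integer(floor(lag_range_ms / frame_ms)), n - 2L)
  lags <- seq.int(-max_lag, max_lag)
  values <- vapply(lags, function(m) {
    if (m >= 0L) {
      x <- a[(1L + m):n]; y <- v[1L:(n - m)]
    } else {
      x <- a[1L:(n + m)]; y <- v[(1L - m):n]
    }
    xc <- x - mean(x); yc <- y - mean(y)
    nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
    if (nx == 0 || ny == 0) return(0)
    sum(xc * yc) / (nx * ny)
  }, numeric(1))
  structure(list(lags_ms = lags * frame_ms, values = values,
                 frame_ms = frame_ms),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> %d lags in [%.1f, %.1f] ms; peak r = %.3f at %.1f ms\n",
              length(x$lags_ms), min(x$lags_ms), max(x$lags_ms),
              max(x$values), x$lags_ms[which.max(x$values)]))
  invisible(x)
}

#' Maximum windowed cross-correlation
#'
#' The maximum of the normalized cross-correlogram over lags within
#' `±window_ms`, a pattern-similarity cue tolerant of small audiovisual
#' delays.
#'
#' @param pair a `sequence_pair`.
#' @param window_ms half-width of the lag window (default 200 ms).
#' @param ccg optional precomputed [normalized_xcorr()] result.
#' @return A correlation in `[-1, 1]`.
#' @export
max_windowed_xcorr <- function(pair, window_ms = 200, ccg = NULL) {
  if (is.null(ccg)) ccg <- normalized_xcorr(pair)
  max(ccg$values[abs(ccg$lags_ms) <= window_ms])
}

#' Cue table for a list of sequence pairs
#'
#' Extracts the three temporal causal-inference cues from each pair.
#'
#' @param pairs list of `sequence_pair` objects.
#' @param window_ms lag window for [max_windowed_xcorr()].
#' @param offset_mode offset definition for [max_click_flash_offset()].
#' @return A tibble with columns `pair_id`, `rate_hz`, `prop_sync`,
#'   `max_offset_ms`, `max_xcorr_win`.
#' @export
feature_table <- function(pairs, window_ms = 200, offset_mode = "directional") {
  if (length(pairs) == 0L) {
    return(tibble::tibble(pair_id = integer(0), rate_hz = numeric(0),
                          prop_sync = numeric(0), max_offset_ms = numeric(0),
                          max_xcorr_win = numeric(0)))
  }
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    tibble::tibble(
      pair_id = i,
      rate_hz = p$nominal_rate_hz,
      prop_sync = proportion_synchronous(p),
      max_offset_ms = max_click_flash_offset(p, mode = offset_mode),
      max_xcorr_win = max_windowed_xcorr(p, window_ms = window_ms))
  })
  do.call(rbind, rows)
}

#' Write a cue table as delimited text
#' @param features tibble from [feature_table()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a cue table written by [write_features_csv()]
#' @param path input path.
#' @return A tibble.
#' @export
read_features_csv <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' Write a cross-correlogram as two-column delimited text
#' @param ccg a `ccg` object.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_ccg_csv <- function(ccg, path) {
  write.csv(data.frame(lag_ms = ccg$lags_ms, r = ccg$values), path,
            row.names = FALSE)
  invisible(path)
}
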