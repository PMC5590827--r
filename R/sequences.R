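#' Display frame duration (ms)
#'
#' Event trains live on a 60-Hz frame grid, so one frame lasts 1000/60 ms.
#' @export
FRAME_MS <- 1000 / 60

#' Construct an event sequence
#'
#' An `event_sequence` is one modality's event train: strictly increasing
#' onset times (ms) within `[0, duration_ms)`, the total presentation
#' duration, the frame duration of the display grid, a modality label and
#' the name of the generating algorithm.
#'
#' @param onsets_ms numeric vector of onset times in ms, strictly increasing,
#'   all in `[0, duration_ms)`.
#' @param duration_ms total presentation length in ms.
#' @param modality `"auditory"` or `"visual"`.
#' @param algorithm generating algorithm label (`"triplet"`, `"raposo"`, or
#'   `"manual"` for hand-built trains).
#' @param frame_ms frame duration in ms (default 1000/60).
#' @return An object of class `event_sequence`.
#' @export
event_sequence <- function(onsets_ms, duration_ms,
                           modality = c("auditory", "visual"),
                           algorithm = "manual", frame_ms = FRAME_MS) {
  modality <- match.arg(modality)
  onsets_ms <- as.numeric(onsets_ms)
  if (is.unsorted(onsets_ms, strictly = TRUE)) {
    stop("onsets_ms must be strictly increasing")
  }
  if (length(onsets_ms) && (min(onsets_ms) < 0 || max(onsets_ms) >= duration_ms)) {
    stop("all onsets must lie in [0, duration_ms)")
  }
  structure(
    list(onsets_ms = onsets_ms, duration_ms = duration_ms,
         frame_ms = frame_ms, modality = modality, algorithm = algorithm),
    class = "event_sequence"
  )
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence> %s, %s algorithm: %d events over %g ms\n",
              x$modality, x$algorithm, length(x$onsets_ms), x$duration_ms))
  invisible(x)
}

#' Number of events implied by a rate and duration
#'
#' Round-to-nearest of rate x duration; exact for integer rates at 2 s.
#' @param rate_hz event rate (events/s).
#' @param duration_ms duration (ms).
#' @return integer event count.
#' @export
n_events_for <- function(rate_hz, duration_ms) {
  as.integer(round(rate_hz * duration_ms / 1000))
}

#' Generate an event train with the frame-triplet algorithm
#'
#' Frames of a 60-Hz display are divided into triplets of 3 frames (50 ms).
#' Event-bearing triplets are a uniformly random subset of the triplets (at
#' most one event per triplet). Within an event-bearing triplet the event
#' frame is chosen uniformly from the 3 positions, except that if the
#' preceding triplet bears an event the position is copied from it, which
#' enforces a minimum gap of two blank frames (>= 33 ms) between events.
#'
#' @param rate_hz event rate in events/s (>= 0).
#' @param duration_ms duration in ms; must be a positive multiple of 50.
#' @param modality modality label for the returned sequence.
#' @return An [event_sequence()] with `round(rate_hz * duration_ms / 1000)`
#'   events whose onsets are exact multiples of the frame duration.
#' @examples
#' set.seed(1)
#' s <- generate_triplet_sequence(8, 2000)
#' length(s$onsets_ms)  # 16
#' @export
generate_triplet_sequence <- function(rate_hz, duration_ms = 2000,
                                      modality = "auditory") {
  if (rate_hz < 0) stop("rate_hz must be non-negative")
  if (duration_ms <= 0 || duration_ms %% 50 != 0) {
    stop("duration_ms must be a positive multiple of 50 ms")
  }
  n_triplets <- as.integer(duration_ms / 50)
  n_ev <- n_events_for(rate_hz, duration_ms)
  if (n_ev > n_triplets) {
    stop(sprintf("invalid rate: %d events requested but only %d triplets available",
                 n_ev, n_triplets))
  }
  if (n_ev == 0L) {
    return(event_sequence(numeric(0), duration_ms, modality, "triplet"))
  }
  triplets <- sort(sample.int(n_triplets, n_ev))
  pos <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    if (i > 1L && triplets[i - 1L] == triplets[i] - 1L) {
      pos[i] <- pos[i - 1L]   # preceding triplet bears an event: copy position
    } else {
      pos[i] <- sample.int(3L, 1L)
    }
  }
  frames <- (triplets - 1L) * 3L + (pos - 1L)
  event_sequence(frames * FRAME_MS, duration_ms, modality, "triplet")
}

#' Generate an event train with fixed 60/120-ms inter-event intervals
#'
#' Inter-event intervals are drawn from \{60, 120\} ms only. The integer mix
#' `(n60, n120)` with `n60 + n120 = n_events - 1` is chosen to bring the mean
#' interval as close as possible to `1000 / rate_hz`, and the interval order
#' is uniformly shuffled. The first onset is placed uniformly at random in
#' the leading slack left over after the train span is fixed.
#'
#' @param rate_hz event rate in events/s (> 0). Rates outside
#'   `[1000/120, 1000/60]` use the closest achievable interval mix (all
#'   120-ms or all 60-ms intervals).
#' @param duration_ms duration in ms.
#' @param modality modality label.
#' @param start_ms optional fixed first-onset time (ms); default draws it
#'   uniformly from the available leading slack.
#' @param reserve_ms trailing time (ms) to keep free after the last onset,
#'   used when the whole train will subsequently be shifted.
#' @return An [event_sequence()] whose inter-onset intervals are all 60 or
#'   120 ms.
#' @export
generate_raposo_sequence <- function(rate_hz, duration_ms = 2000,
                                     modality = "auditory",
                                     start_ms = NULL, reserve_ms = 0) {
  if (rate_hz <= 0) stop("rate_hz must be positive")
  n_ev <- n_events_for(rate_hz, duration_ms)
  if (n_ev == 0L) {
    return(event_sequence(numeric(0), duration_ms, modality, "raposo"))
  }
  n_int <- n_ev - 1L
  # span(n60) = 120*n_int - 60*n60; target span leaves one mean interval free
  target <- duration_ms - 1000 / rate_hz
  n60 <- as.integer(round((120 * n_int - target) / 60))
  n60 <- max(0L, min(n_int, n60))
  intervals <- sample(c(rep(60, n60), rep(120, n_int - n60)))
  span <- sum(intervals)
  slack <- duration_ms - span - reserve_ms
  if (slack <= 0) {
    stop("invalid rate: event train does not fit in the requested duration")
  }
  start <- if (is.null(start_ms)) runif(1, 0, slack) else start_ms
  onsets <- start + cumsum(c(0, intervals))
  event_sequence(onsets, duration_ms, modality, "raposo")
}

#' Construct an audiovisual sequence pair
#'
#' @param auditory,visual [event_sequence()] objects sharing `duration_ms`.
#' @param temporal_conflict,spatial_conflict condition flags.
#' @param nominal_rate_hz nominal event rate (events/s).
#' @param algorithm generating algorithm label.
#' @return An object of class `sequence_pair`.
#' @export
sequence_pair <- function(auditory, visual, temporal_conflict = FALSE,
                          spatial_conflict = FALSE, nominal_rate_hz = NA_real_,
                          algorithm = "manual") {
  stopifnot(inherits(auditory, "event_sequence"),
            inherits(visual, "event_sequence"))
  if (auditory$duration_ms != visual$duration_ms) {
    stop("both sequences must share duration_ms")
  }
  structure(
    list(auditory = auditory, visual = visual,
         temporal_conflict = isTRUE(temporal_conflict),
         spatial_conflict = isTRUE(spatial_conflict),
         nominal_rate_hz = nominal_rate_hz, algorithm = algorithm),
    class = "sequence_pair"
  )
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat(sprintf(
    "<sequence_pair> %s algorithm, %g events/s nominal, %g ms%s%s\n",
    x$algorithm, x$nominal_rate_hz, x$auditory$duration_ms,
    if (x$temporal_conflict) ", temporal conflict" else "",
    if (x$spatial_conflict) ", spatial conflict" else ""))
  invisible(x)
}

#' Generate a condition-specific audiovisual sequence pair
#'
#' Without temporal conflict both modalities share a single generated train.
#' With temporal conflict two independent trains are drawn; for the
#' fixed-interval ("raposo") algorithm the visual train is additionally
#' shifted by +20 ms so that no click and flash coincide. Spatial conflict
#' is recorded as metadata only.
#'
#' @param temporal_conflict,spatial_conflict condition flags.
#' @param rate_hz nominal event rate (events/s).
#' @param duration_ms duration in ms.
#' @param algorithm `"triplet"` or `"raposo"`.
#' @param offset_ms inter-modality shift applied to the visual train for
#'   raposo temporal-conflict pairs (default 20 ms).
#' @return A `sequence_pair`.
#' @export
generate_pair <- function(temporal_conflict = FALSE, spatial_conflict = FALSE,
                          rate_hz = 8, duration_ms = 2000,
                          algorithm = c("triplet", "raposo"),
                          offset_ms = 20) {
  algorithm <- match.arg(algorithm)
  gen <- function(modality, ...) {
    if (algorithm == "triplet") {
      generate_triplet_sequence(rate_hz, duration_ms, modality)
    } else {
      generate_raposo_sequence(rate_hz, duration_ms, modality, ...)
    }
  }
  if (!temporal_conflict) {
    a <- gen("auditory")
    v <- a
    v$modality <- "visual"
  } else {
    a <- gen("auditory")
    if (algorithm == "raposo") {
      v <- gen("visual", reserve_ms = offset_ms)
      v$onsets_ms <- v$onsets_ms + offset_ms
    } else {
      v <- gen("visual")
    }
  }
  sequence_pair(a, v, temporal_conflict, spatial_conflict, rate_hz, algorithm)
}

#' Generate a causality-judgement trial pair with the 200-ms rejection filter
#'
#' Candidate pairs whose maximum click-flash offset exceeds `reject_ms` are
#' discarded and regenerated, hiding the rejection loop from the caller.
#' No-conflict pairs always pass (their offset is 0).
#'
#' @param rate_hz nominal rate (8, 10, 12 or 14 events/s in the canonical
#'   design; other values permitted).
#' @param duration_ms duration in ms (default 2000).
#' @param temporal_conflict whether the pair has independent trains.
#' @param reject_ms rejection threshold on the maximum click-flash offset
#'   (default 200 ms).
#' @param max_attempts rejection-loop cap (default 10000).
#' @param offset_mode offset definition passed to [max_click_flash_offset()].
#' @return A `sequence_pair` whose maximum click-flash offset is
#'   `<= reject_ms`, with the number of attempts in attribute `"attempts"`.
#' @export
generate_exp2_trial <- function(rate_hz, duration_ms = 2000,
                                temporal_conflict = TRUE, reject_ms = 200,
                                max_attempts = 10000,
                                offset_mode = "directional") {
  for (attempt in seq_len(max_attempts)) {
    pair <- generate_pair(temporal_conflict, FALSE, rate_hz, duration_ms,
                          algorithm = "triplet")
    if (!temporal_conflict ||
        max_click_flash_offset(pair, mode = offset_mode) <= reject_ms) {
      attr(pair, "attempts") <- attempt
      return(pair)
    }
  }
  stop(sprintf("rejection failure: no pair with max offset <= %g ms in %d attempts",
               reject_ms, max_attempts))
}

#' Jitter a comparison-stimulus duration
#'
#' Draws a duration uniformly from the 11-value grid
#' `base_ms + {-250, -200, ..., +250}` ms (steps of 3 frames = 50 ms),
#' used to dissociate event counting from rate estimation.
#'
#' @param base_ms base duration (default 2000 ms).
#' @param step_ms jitter step (default 50 ms).
#' @param max_jitter_ms maximum absolute jitter (default 250 ms).
#' @return A single jittered duration in ms.
#' @export
jitter_duration <- function(base_ms = 2000, step_ms = 50, max_jitter_ms = 250) {
  k <- as.integer(max_jitter_ms / step_ms)
  base_ms + step_ms * sample(seq.int(-k, k), 1L)
}

#' Serialize a sequence pair to a compact JSON descriptor
#'
#' @param pair a `sequence_pair`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_pair_json <- function(pair, path = NULL) {
  x <- list(algorithm = pair$algorithm, rate_hz = pair$nominal_rate_hz,
            duration_ms = pair$auditory$duration_ms,
            temporal_conflict = pair$temporal_conflict,
            spatial_conflict = pair$spatial_conflict,
            auditory_onsets_ms = pair$auditory$onsets_ms,
            visual_onsets_ms = pair$visual$onsets_ms)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Read a sequence pair from its JSON descriptor
#'
#' @param path file path or JSON string produced by [write_pair_json()].
#' @return A `sequence_pair`.
#' @export
read_pair_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  a <- event_sequence(x$auditory_onsets_ms, x$duration_ms, "auditory", x$algorithm)
  v <- event_sequence(x$visual_onsets_ms, x$duration_ms, "visual", x$algorithm)
  sequence_pair(a, v, x$temporal_conflict, x$spatial_conflict,
                x$rate_hz, x$algorithm)
}

#' Write an event sequence as two-column delimited text
#'
#' Columns are `onset_ms` and `modality`.
#' @param seq an `event_sequence` or a `sequence_pair` (both modalities).
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_sequence_tsv <- function(seq, path) {
  if (inherits(seq, "sequence_pair")) {
    df <- rbind(
      data.frame(onset_ms = seq$auditory$onsets_ms, modality = "auditory"),
      data.frame(onset_ms = seq$visual$onsets_ms, modality = "visual"))
  } else {
    df <- data.frame(onset_ms = seq$onsets_ms, modality = seq$modality)
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
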