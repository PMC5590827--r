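#' Specify a synthetic rate-discrimination observer
#'
#' The observer forms a noisy internal rate estimate per modality,
#' `r_m ~ N(rate + mu_m, sigma_m^2)`, optionally mixes in a count-based
#' estimate (`counting_weight`), combines the modalities according to its
#' strategy, and responds "faster" when the combined estimate exceeds the
#' standard rate.
#'
#' @param sigma_a,sigma_v unisensory rate-noise SDs (events/s), > 0.
#' @param mu_a,mu_v unisensory biases (events/s).
#' @param strategy `"optimal"` (reliability-weighted combination),
#'   `"best-cue"` (lower-sigma modality only), or `"fixed-sigma"` (a
#'   multisensory noise level set directly by `sigma_av`).
#' @param sigma_av multisensory SD for `strategy = "fixed-sigma"`.
#' @param counting_weight fraction in `[0, 1]` mixing a count-based estimate
#'   (`count / standard duration`) into the decision variable; positive
#'   values make judgements duration-dependent, producing a negative
#'   PSE-vs-jitter slope.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(sigma_a, sigma_v, mu_a = 0, mu_v = 0,
                          strategy = c("optimal", "best-cue", "fixed-sigma"),
                          sigma_av = NULL, counting_weight = 0) {
  strategy <- match.arg(strategy)
  stopifnot(sigma_a > 0, sigma_v > 0,
            counting_weight >= 0, counting_weight <= 1)
  if (strategy == "fixed-sigma" && is.null(sigma_av)) {
    stop("fixed-sigma strategy requires sigma_av")
  }
  structure(list(sigma_a = sigma_a, sigma_v = sigma_v, mu_a = mu_a,
                 mu_v = mu_v, strategy = strategy, sigma_av = sigma_av,
                 counting_weight = counting_weight),
            class = "observer_spec")
}

#' Simulate a rate-discrimination dataset
#'
#' Generates comparison-to-standard rate-discrimination trials for a list of
#' synthetic observers under a method-of-constant-stimuli design: for every
#' observer x condition x modality x stimulus level x repeat, the comparison
#' duration is jittered on the 50-ms grid, internal estimates are drawn per
#' modality, combined per the observer's strategy, and the binary
#' "comparison faster" response recorded. Trials are shuffled within each
#' observer x condition session and the previous comparison trial's modality
#' recorded for the attention-switch analysis.
#'
#' @param observers list of [observer_spec()] objects (one per subject).
#' @param conditions condition labels (metadata only; default the four
#'   spatiotemporal-conflict conditions).
#' @param rate_diffs stimulus grid of comparison-minus-standard rate
#'   differences (events/s).
#' @param n_per_cell repeats per observer x condition x modality x level.
#' @param standard_rate standard rate (default 8 events/s).
#' @param base_duration_ms comparison base duration before jitter.
#' @param seed optional RNG seed.
#' @return A tibble with columns `subject`, `condition`, `modality`
#'   (`"A"`, `"V"`, `"AV"`), `rate_diff`, `duration_jitter_ms`,
#'   `response_faster`, `prev_modality`.
#' @export
simulate_exp1_dataset <- function(observers,
                                  conditions = c("no-conflict", "temporal",
                                                 "spatial", "spatiotemporal"),
                                  rate_diffs = c(-6, -4, -3, -2, -1, -0.5,
                                                 0.5, 1, 2, 3, 4, 6),
                                  n_per_cell = 10, standard_rate = 8,
                                  base_duration_ms = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(observers) >= 1,
            all(vapply(observers, inherits, logical(1), "observer_spec")))

  estimate <- function(obs, modality, rate, duration_ms) {
    w <- obs$counting_weight
    count_rate <- round(rate * duration_ms / 1000) /
      (base_duration_ms / 1000)
    signal <- (1 - w) * rate + w * count_rate
    draw <- function(mu, sg) rnorm(1, signal + mu, sg)
    switch(modality,
      A = draw(obs$mu_a, obs$sigma_a),
      V = draw(obs$mu_v, obs$sigma_v),
      AV = switch(obs$strategy,
        "optimal" = {
          wa <- 1 / obs$sigma_a^2
          wv <- 1 / obs$sigma_v^2
          (wa * draw(obs$mu_a, obs$sigma_a) +
             wv * draw(obs$mu_v, obs$sigma_v)) / (wa + wv)
        },
        "best-cue" = if (obs$sigma_a <= obs$sigma_v)
          draw(obs$mu_a, obs$sigma_a) else draw(obs$mu_v, obs$sigma_v),
        "fixed-sigma" = draw(0, obs$sigma_av)))
  }

  out <- list()
  for (s in seq_along(observers)) {
    obs <- observers[[s]]
    for (cond in conditions) {
      cells <- expand.grid(modality = c("A", "V", "AV"),
                           rate_diff = rate_diffs,
                           rep = seq_len(n_per_cell),
                           stringsAsFactors = FALSE)
      cells <- cells[sample.int(nrow(cells)), ]   # interleave the session
      jit <- vapply(seq_len(nrow(cells)), function(i)
        jitter_duration(base_duration_ms), numeric(1)) - base_duration_ms
      est <- vapply(seq_len(nrow(cells)), function(i)
        estimate(obs, cells$modality[i],
                 standard_rate + cells$rate_diff[i],
                 base_duration_ms + jit[i]), numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        subject = s,
        condition = cond,
        modality = cells$modality,
        rate_diff = cells$rate_diff,
        duration_jitter_ms = jit,
        response_faster = as.integer(est > standard_rate),
        prev_modality = c(NA_character_, cells$modality[-nrow(cells)]))
    }
  }
  do.call(rbind, out)
}

#' Specify a synthetic causality-judgement observer
#'
#' The generative twin of the causal-judgement model: on temporal-conflict
#' trials the probability of a "common source" response is
#' `plogis(b0 + b_sync * prop_sync + b_off * offset_s
#'  + b_int * prop_sync * offset_s + u_subject)` with
#' `u_subject ~ N(0, random_intercept_sd^2)`; on no-conflict trials the
#' observer responds "common" with probability `sync_response_rate`.
#'
#' @param beta named numeric vector with elements `intercept`, `sync`,
#'   `offset` (per second), `interaction`.
#' @param random_intercept_sd SD of the per-subject random intercept
#'   (log-odds).
#' @param sync_response_rate probability of "common" on no-conflict trials.
#' @return An object of class `causal_observer_spec`.
#' @export
causal_observer_spec <- function(beta = c(intercept = 1.76, sync = 0,
                                          offset = -17, interaction = 0),
                                 random_intercept_sd = 0.5,
                                 sync_response_rate = 0.971) {
  stopifnot(all(c("intercept", "sync", "offset", "interaction") %in%
                  names(beta)),
            random_intercept_sd >= 0,
            sync_response_rate >= 0, sync_response_rate <= 1)
  structure(list(beta = beta, random_intercept_sd = random_intercept_sd,
                 sync_response_rate = sync_response_rate),
            class = "causal_observer_spec")
}

#' Simulate a causality-judgement dataset
#'
#' Generates the canonical causality-judgement design: per subject and
#' session, for each rate in `rates`, `n_conflict` temporal-conflict trials
#' (triplet algorithm, 200-ms rejection filter) and `n_noconflict`
#' no-conflict trials, in randomized order. Temporal cues are extracted per
#' trial and binary "common source" responses drawn from the observer's
#' logistic model with per-subject random intercepts.
#'
#' @param spec a [causal_observer_spec()].
#' @param n_subjects number of subjects (default 10).
#' @param n_sessions sessions per subject (default 2).
#' @param rates sequence rates in events/s (default `c(8, 10, 12, 14)`).
#' @param n_conflict temporal-conflict trials per rate per session
#'   (default 75).
#' @param n_noconflict no-conflict trials per rate per session (default 15).
#' @param duration_ms sequence duration (default 2000 ms).
#' @param reject_ms rejection threshold on the maximum click-flash offset
#'   (default 200 ms).
#' @param keep_pairs retain the generated `sequence_pair` objects (default
#'   `TRUE`; set `FALSE` to save memory in large simulations).
#' @param seed optional RNG seed.
#' @return A list with `trials` (tibble: `subject`, `session`, `rate_hz`,
#'   `temporal_conflict`, `prop_sync`, `max_offset_ms`, `max_offset_s`,
#'   `response_common`) and `pairs` (list of `sequence_pair`, or `NULL`).
#' @export
simulate_exp2_dataset <- function(spec, n_subjects = 10, n_sessions = 2,
                                  rates = c(8, 10, 12, 14), n_conflict = 75,
                                  n_noconflict = 15, duration_ms = 2000,
                                  reject_ms = 200, keep_pairs = TRUE,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "causal_observer_spec"))
  b <- spec$beta
  u <- rnorm(n_subjects, 0, spec$random_intercept_sd)

  rows <- list()
  pairs <- if (keep_pairs) list() else NULL
  for (s in seq_len(n_subjects)) {
    for (sess in seq_len(n_sessions)) {
      design <- do.call(rbind, lapply(rates, function(r) {
        data.frame(rate_hz = r,
                   temporal_conflict = rep(c(TRUE, FALSE),
                                           c(n_conflict, n_noconflict)))
      }))
      design <- design[sample.int(nrow(design)), ]
      for (i in seq_len(nrow(design))) {
        conflict <- design$temporal_conflict[i]
        pair <- generate_exp2_trial(design$rate_hz[i], duration_ms,
                                    temporal_conflict = conflict,
                                    reject_ms = reject_ms)
        sync <- proportion_synchronous(pair)
        off <- max_click_flash_offset(pair)
        if (conflict) {
          eta <- b["intercept"] + b["sync"] * sync +
            b["offset"] * off / 1000 +
            b["interaction"] * sync * off / 1000 + u[s]
          resp <- rbinom(1, 1, plogis(unname(eta)))
        } else {
          resp <- rbinom(1, 1, spec$sync_response_rate)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = s, session = sess, rate_hz = design$rate_hz[i],
          temporal_conflict = conflict, prop_sync = sync,
          max_offset_ms = off, max_offset_s = off / 1000,
          response_common = resp)
        if (keep_pairs) pairs[[length(pairs) + 1L]] <- pair
      }
    }
  }
  list(trials = do.call(rbind, rows), pairs = pairs,
       random_intercepts = u)
}
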