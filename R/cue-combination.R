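#' Best-cue prediction from two unisensory posteriors
#'
#' Under the best-cue strategy the observer uses only the more reliable
#' modality, so the predicted multisensory threshold satisfies
#' `sigma_best^2 = min(sigma_A^2, sigma_V^2)`. The modality is selected by
#' the posterior-mean sigma (ties broken toward auditory), and the predicted
#' PSE is that modality's fitted PSE.
#'
#' @param post_a,post_v `psychometric_posterior` objects for the auditory
#'   and visual conditions.
#' @return A list with `modality` (`"auditory"` or `"visual"`),
#'   `sigma_samples` (the selected posterior's sigma draws), `sigma_hat`,
#'   `ci95`, `mu_best`, and `tie` (logical).
#' @export
predict_best_cue <- function(post_a, post_v) {
  tie <- isTRUE(all.equal(post_a$sigma_hat, post_v$sigma_hat))
  sel_a <- post_a$sigma_hat <= post_v$sigma_hat
  sel <- if (sel_a) post_a else post_v
  list(modality = if (sel_a) "auditory" else "visual",
       sigma_samples = sel$sigma_samples,
       sigma_hat = sel$sigma_hat,
       ci95 = unname(sel$ci95[2, ]),
       mu_best = sel$mu_hat,
       tie = tie)
}

#' Optimal-integration prediction from two unisensory posteriors
#'
#' Under optimal (reliability-weighted) cue integration the predicted
#' multisensory threshold obeys
#' `1 / sigma_opt^2 = 1 / sigma_A^2 + 1 / sigma_V^2`. The posterior of
#' `sigma_opt` is propagated by taking independent draws from the two
#' unisensory sigma posteriors and applying the formula pairwise.
#'
#' @param post_a,post_v `psychometric_posterior` objects.
#' @param n_draws number of propagated draws (default 2000).
#' @param seed optional RNG seed for the resampling.
#' @return A list with `sigma_samples` (the propagated draws), `sigma_hat`
#'   (posterior mean), `ci95` (central 95% interval), and `source_draws`
#'   (the paired unisensory draws each propagated value came from).
#' @export
predict_optimal <- function(post_a, post_v, n_draws = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sa <- sample(post_a$sigma_samples, n_draws, replace = TRUE)
  sv <- sample(post_v$sigma_samples, n_draws, replace = TRUE)
  s_opt <- 1 / sqrt(1 / sa^2 + 1 / sv^2)
  list(sigma_samples = s_opt,
       sigma_hat = mean(s_opt),
       ci95 = unname(quantile(s_opt, c(0.025, 0.975))),
       source_draws = list(sigma_a = sa, sigma_v = sv))
}

#' Combined integration prediction
#'
#' Convenience wrapper bundling [predict_best_cue()] and [predict_optimal()]
#' for one subject-condition pairing.
#'
#' @inheritParams predict_optimal
#' @return A list of class `integration_prediction` with elements `best`,
#'   `optimal`, and the two source posteriors.
#' @export
integration_prediction <- function(post_a, post_v, n_draws = 2000, seed = NULL) {
  structure(
    list(best = predict_best_cue(post_a, post_v),
         optimal = predict_optimal(post_a, post_v, n_draws, seed),
         post_a = post_a, post_v = post_v),
    class = "integration_prediction")
}

ci_overlap <- function(ci1, ci2) ci1[1] <= ci2[2] && ci2[1] <= ci1[2]

#' Classify observed multisensory behaviour against the predictions
#'
#' Compares the 95% credible interval of the observed multisensory threshold
#' with the predicted optimal and best-cue intervals:
#' \describe{
#'   \item{optimal}{observed CI overlaps the optimal-prediction CI;}
#'   \item{enhancement}{observed CI lies entirely below the best-cue CI
#'     (better than the best single cue, but not optimal);}
#'   \item{worse-than-best}{observed CI lies entirely above the best-cue CI;}
#'   \item{best-cue}{observed CI overlaps the best-cue CI but not the
#'     optimal CI;}
#'   \item{suboptimal}{otherwise (between the two predictions).}
#' }
#'
#' @param post_av `psychometric_posterior` for the multisensory condition.
#' @param prediction an [integration_prediction()].
#' @return A single classification label.
#' @export
classify_integration <- function(post_av, prediction) {
  av <- unname(post_av$ci95[2, ])
  opt <- prediction$optimal$ci95
  best <- prediction$best$ci95
  if (ci_overlap(av, opt)) return("optimal")
  if (av[2] < best[1]) return("enhancement")
  if (av[1] > best[2]) return("worse-than-best")
  if (ci_overlap(av, best)) return("best-cue")
  "suboptimal"
}

#' Paired comparison of auditory and visual thresholds
#'
#' Standard paired t-test on matched threshold point estimates, used to
#' verify that neither modality dominates overall (a prerequisite for a
#' meaningful best-cue vs optimal comparison).
#'
#' @param sigma_a,sigma_v equal-length vectors of paired threshold
#'   estimates.
#' @return A list with `t`, `df`, `p`, and `mean_diff`.
#' @export
compare_unisensory <- function(sigma_a, sigma_v) {
  stopifnot(length(sigma_a) == length(sigma_v))
  if (length(sigma_a) < 2) stop("need at least 2 paired thresholds")
  d <- sigma_a - sigma_v
  if (sd(d) == 0) {
    # identical paired differences: t is 0 for zero difference, infinite otherwise
    t_val <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_val, df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0, mean_diff = mean(d)))
  }
  tt <- t.test(sigma_a, sigma_v, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}
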