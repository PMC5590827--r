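# Build a sequence pair from 0-based frame indices (triplet-style grid).
make_frame_pair <- function(a_frames, v_frames, n_frames = 120,
                            algorithm = "triplet", rate_hz = NA_real_,
                            temporal_conflict = TRUE) {
  dur <- n_frames * FRAME_MS
  a <- event_sequence(a_frames * FRAME_MS, dur, "auditory", algorithm)
  v <- event_sequence(v_frames * FRAME_MS, dur, "visual", algorithm)
  sequence_pair(a, v, temporal_conflict = temporal_conflict,
                nominal_rate_hz = rate_hz, algorithm = algorithm)
}

# A psychometric-posterior stand-in with known draws, for cue-combination
# logic that only consumes samples and summaries.
make_posterior <- function(mu_samples, sigma_samples) {
  structure(
    list(mu_samples = mu_samples, sigma_samples = sigma_samples,
         mu_hat = mean(mu_samples), sigma_hat = mean(sigma_samples),
         ci95 = rbind(mu = quantile(mu_samples, c(0.025, 0.975), names = FALSE),
                      sigma = quantile(sigma_samples, c(0.025, 0.975),
                                       names = FALSE)),
         n_trials = length(mu_samples), degenerate = FALSE),
    class = "psychometric_posterior")
}

# Binary responses from a cumulative-Gaussian observer.
simulate_psych_responses <- function(x, mu, sigma) {
  rbinom(length(x), 1, pnorm((x - mu) / sigma))
}

# Fast psychometric-fit settings for tests that need many fits.
fast_fit <- function(x, response, ...) {
  fit_psychometric(x, response, n_samples = 1000, burn_in = 1000, thin = 2, ...)
}
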