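test_that("psychometric MCMC recovers generating parameters", {
  set.seed(41)
  x <- rep(c(-6, -4, -2, -1, 1, 2, 4, 6), each = 75)
  resp <- simulate_psych_responses(x, mu = 0.5, sigma = 2)
  fit <- fit_psychometric(x, resp, seed = 141)
  expect_lt(abs(fit$mu_hat - 0.5), 0.4)
  expect_lt(abs(fit$sigma_hat - 2), 0.5)
  # CIs bracket the posterior means and draws respect the prior support
  expect_true(fit$ci95[1, 1] < fit$mu_hat && fit$mu_hat < fit$ci95[1, 2])
  expect_true(fit$ci95[2, 1] < fit$sigma_hat && fit$sigma_hat < fit$ci95[2, 2])
  expect_true(all(fit$mu_samples > -7 & fit$mu_samples < 7))
  expect_true(all(fit$sigma_samples > exp(-2.3) & fit$sigma_samples < exp(1.6)))
  expect_true(all(fit$rhat < 1.2))
  expect_length(fit$mu_samples, 2000)
})

test_that("step-like data drive sigma to the lower prior bound", {
  x <- rep(c(-4, -2, -1, 1, 2, 4), each = 20)
  resp <- as.integer(x > 0)
  fit <- fit_psychometric(x, resp, seed = 142)
  expect_lt(fit$sigma_hat, 0.3)
  expect_lt(quantile(fit$sigma_samples, 0.5), 2 * exp(-2.3))
})

test_that("degenerate and underdetermined inputs are flagged", {
  x <- rep(c(-2, 2), each = 10)
  expect_warning(fit_psychometric(x, rep(1, 20), n_samples = 200,
                                  burn_in = 200, thin = 1, seed = 1),
                 "fit-degenerate")
  expect_error(fit_psychometric(rep(1, 10), rbinom(10, 1, 0.5)),
               "distinct stimulus levels")
})

test_that("MCMC draws are seed-reproducible", {
  x <- rep(c(-4, -1, 1, 4), each = 25)
  set.seed(43)
  resp <- simulate_psych_responses(x, 0, 2)
  f1 <- fast_fit(x, resp, seed = 7)
  f2 <- fast_fit(x, resp, seed = 7)
  expect_identical(f1$mu_samples, f2$mu_samples)
  expect_identical(f1$sigma_samples, f2$sigma_samples)
})

test_that("the z-transform standardizes stimulus levels cell by cell", {
  fits <- list("1|c|A" = list(mu_hat = 2, sigma_hat = 3))
  trials <- tibble::tibble(subject = 1, condition = "c", modality = "A",
                           rate_diff = c(2, 5, -1))
  z <- z_transform(trials, fits)
  expect_equal(z$z, c(0, 1, -1))
  trials$condition <- "missing"
  expect_error(z_transform(trials, fits), "no psychometric fit")
})

test_that("refitting pooled z-scored trials gives mu 0, sigma 1", {
  set.seed(44)
  cells <- list(list(mu = 1, sigma = 1.5), list(mu = -0.5, sigma = 3))
  trials <- do.call(rbind, lapply(seq_along(cells), function(i) {
    x <- rep(c(-6, -4, -2, -1, 1, 2, 4, 6), each = 180)
    tibble::tibble(subject = i, condition = "c", modality = "A",
                   rate_diff = x,
                   response_faster = simulate_psych_responses(
                     x, cells[[i]]$mu, cells[[i]]$sigma))
  }))
  fits <- fit_psychometric_cells(trials, n_samples = 1000, burn_in = 1000,
                                 thin = 2, seed = 144)
  z <- z_transform(trials, fits)
  pooled <- fast_fit(z$z, z$response_faster, seed = 145)
  expect_lt(abs(pooled$mu_hat), 0.1)
  expect_lt(abs(pooled$sigma_hat - 1), 0.1)
})

test_that("attention-switch split partitions the classifiable trials", {
  set.seed(45)
  n <- 1200
  z <- rep(c(-2, -1, 1, 2), n / 4)
  trials <- tibble::tibble(
    modality = sample(c("A", "V", "AV"), n, replace = TRUE),
    prev_modality = c(NA, sample(c("A", "V", "AV"), n - 1, replace = TRUE)),
    z = z,
    response_faster = simulate_psych_responses(z, 0, 1))
  out <- split_fit_switch(trials, n_samples = 500, burn_in = 500, thin = 1,
                          seed = 46)
  expect_equal(sum(out$n), sum(!is.na(trials$prev_modality)))
  # no switch effect in the generator: CIs overlap
  expect_true(out$stay$ci95[2, 1] <= out$switch$ci95[2, 2] &&
                out$switch$ci95[2, 1] <= out$stay$ci95[2, 2])
})

test_that("a switch cost in the generator separates the split thresholds", {
  set.seed(46)
  n <- 12000
  z <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
  modality <- sample(c("A", "V"), n, replace = TRUE)
  prev <- c(NA, modality[-n])
  stay <- !is.na(prev) & prev == modality
  sigma <- ifelse(stay, 1, 1.5)
  trials <- tibble::tibble(
    modality = modality, prev_modality = prev, z = z,
    response_faster = rbinom(n, 1, pnorm(z / sigma)))
  out <- split_fit_switch(trials, n_samples = 1000, burn_in = 1000, thin = 1,
                          seed = 47)
  expect_lt(out$stay$ci95[2, 2], out$switch$ci95[2, 1])
})

test_that("duration splits separate counting from rate observers", {
  set.seed(47)
  run_observer <- function(w) {
    obs <- observer_spec(sigma_a = 1.5, sigma_v = 1.5, strategy = "optimal",
                         counting_weight = w)
    trials <- simulate_exp1_dataset(list(obs), conditions = "no-conflict",
                                    n_per_cell = 40, seed = 500 + w * 10)
    fits <- fit_psychometric_cells(trials, n_samples = 800, burn_in = 800,
                                   thin = 1, seed = 48)
    z <- z_transform(trials, fits)
    split_fit_duration(z, n_samples = 500, burn_in = 500, thin = 1, seed = 49)
  }
  counting <- run_observer(1)
  # two-group split excludes |jitter| < 100 trials
  expect_lt(counting$regression$slope_ci90[2], 0)
  expect_equal(nrow(counting$pse_by_jitter), 11)

  rate_based <- run_observer(0)
  ci <- rate_based$regression$slope_ci90
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("the duration split omits small-jitter trials", {
  set.seed(48)
  z <- rep(c(-2, 2), 550)
  trials <- tibble::tibble(
    z = z,
    duration_jitter_ms = rep(seq(-250, 250, by = 50), 100),
    response_faster = simulate_psych_responses(z, 0, 1))
  out <- split_fit_duration(trials, n_samples = 300, burn_in = 300, thin = 1,
                            seed = 50)
  kept <- sum(abs(trials$duration_jitter_ms) >= 100)
  expect_equal(out$short$n_trials + out$long$n_trials, kept)
})

test_that("the causal split separates integrated from segregated trials", {
  set.seed(49)
  n <- 6000
  z <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
  off <- runif(n, 0, 300)
  sigma <- ifelse(off <= 103, 1, 2)
  trials <- tibble::tibble(z = z, response_faster = rbinom(n, 1, pnorm(z / sigma)))
  out <- split_fit_causal(trials, off, boundary_ms = 103,
                          n_samples = 800, burn_in = 800, thin = 1, seed = 51)
  expect_equal(sum(out$n), n)
  expect_lt(out$common$ci95[2, 2], out$separate$ci95[2, 1])
  expect_error(split_fit_causal(trials, off, boundary_ms = -1), "empty common")
})
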