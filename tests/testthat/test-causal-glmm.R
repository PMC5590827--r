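# shared fixture: one conflict-trial feature design reused across blocks
glmm_design <- local({
  set.seed(81)
  sim <- simulate_exp2_dataset(
    causal_observer_spec(random_intercept_sd = 0.5),
    n_subjects = 6, n_sessions = 1, n_conflict = 40, n_noconflict = 0,
    keep_pairs = FALSE, seed = 810)
  sim$trials[sim$trials$temporal_conflict, ]
})

redraw_responses <- function(design, beta, re_sd, seed) {
  set.seed(seed)
  u <- rnorm(length(unique(design$subject)), 0, re_sd)
  eta <- beta["intercept"] + beta["sync"] * design$prop_sync +
    beta["offset"] * design$max_offset_s +
    beta["interaction"] * design$prop_sync * design$max_offset_s +
    u[design$subject]
  design$response_common <- rbinom(nrow(design), 1, plogis(eta))
  design
}

test_that("with no random-effect variance the GLMM matches plain logistic regression", {
  beta <- c(intercept = 1.76, sync = 0, offset = -17, interaction = 0)
  tbl <- redraw_responses(glmm_design, beta, re_sd = 0, seed = 482)
  fit <- suppressMessages(fit_causal_glmm(tbl))
  oracle <- stats::glm(response_common ~ prop_sync * max_offset_s,
                       data = tbl, family = binomial)
  expect_lt(abs(fit$beta_intercept - coef(oracle)[["(Intercept)"]]), 1e-3)
  expect_lt(abs(fit$beta_offset - coef(oracle)[["max_offset_s"]]), 1e-3)
  expect_lt(abs(fit$beta_sync - coef(oracle)[["prop_sync"]]), 1e-3)
  expect_lt(fit$random_intercept_sd, 0.05)
})

test_that("with constant covariates the intercept is the logit response rate", {
  set.seed(83)
  tbl <- tibble::tibble(subject = rep(1:6, each = 100),
                        prop_sync = 0, max_offset_s = 0,
                        response_common = rbinom(600, 1, 0.7))
  fit <- suppressMessages(suppressWarnings(
    fit_causal_glmm(tbl, include_sync = FALSE, include_interaction = FALSE)))
  expect_lt(abs(fit$beta_intercept - qlogis(mean(tbl$response_common))), 0.1)
})

test_that("the fitted model recovers generating coefficients", {
  beta <- c(intercept = 1.76, sync = 0, offset = -17, interaction = 0)
  tbl <- redraw_responses(glmm_design, beta, re_sd = 0.5, seed = 84)
  fit <- fit_causal_glmm(tbl)
  wald <- confint(fit$model, parm = "beta_", method = "Wald", level = 0.95)
  expect_true(wald["(Intercept)", 1] < 1.76 && 1.76 < wald["(Intercept)", 2])
  expect_true(wald["max_offset_s", 1] < -17 && -17 < wald["max_offset_s", 2])
  expect_error(fit_causal_glmm(tbl[tbl$subject == 1, ]), ">= 2 subjects")
})

test_that("the integration boundary is the 0.5-probability offset", {
  b <- integration_boundary(beta_intercept = 1.76, beta_offset = -17)
  expect_equal(b, 1760 / 17, tolerance = 1e-12)
  expect_equal(plogis(1.76 + -17 * b / 1000), 0.5, tolerance = 1e-12)
  expect_equal(integration_boundary(beta_intercept = 0, beta_offset = -5), 0)
  expect_error(integration_boundary(beta_intercept = 1, beta_offset = 0),
               "undefined boundary")
  # a fit carrying a sync effect cannot define an offset-axis boundary
  beta <- c(intercept = 1, sync = 3, offset = -15, interaction = 0)
  tbl <- redraw_responses(glmm_design, beta, re_sd = 0.3, seed = 85)
  full <- fit_causal_glmm(tbl)
  expect_error(integration_boundary(full), "offset axis")
  reduced <- fit_causal_glmm(tbl, include_sync = FALSE,
                             include_interaction = FALSE)
  expect_gt(integration_boundary(reduced), 0)
})

test_that("bootstrap p-values floor at 1/(n_boot + 1) and intervals nest", {
  beta <- c(intercept = 2, sync = 0, offset = -20, interaction = 0)
  tbl <- redraw_responses(glmm_design, beta, re_sd = 0.3, seed = 86)
  fit <- fit_causal_glmm(tbl, include_sync = FALSE,
                         include_interaction = FALSE)
  boot <- bootstrap_pvalues(fit, n_boot = 60, seed = 87)
  est <- boot$estimates
  off <- est[est$coefficient == "max_offset_s", ]
  expect_equal(off$p_value, 1 / 61)   # every draw is far from zero
  expect_true(off$ci_lower < off$boot_mean && off$boot_mean < off$ci_upper)
  # 90% percentile interval nests inside the 99% interval of the same draws
  q99 <- quantile(boot$boot_samples[, "max_offset_s"], c(0.005, 0.995))
  expect_gte(off$ci_lower, q99[[1]])
  expect_lte(off$ci_upper, q99[[2]])
  # bootstrap is seed-reproducible
  boot2 <- bootstrap_pvalues(fit, n_boot = 60, seed = 87)
  expect_equal(boot$estimates, boot2$estimates)
})

test_that("bootstrap rejections of a null coefficient are calibrated", {
  beta <- c(intercept = 1.5, sync = 0, offset = -15, interaction = 0)
  rejections <- 0L
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    tbl <- redraw_responses(glmm_design, beta, re_sd = 0.3, seed = 8800 + r)
    fit <- fit_causal_glmm(tbl, include_interaction = FALSE)
    boot <- bootstrap_pvalues(fit, n_boot = 39, seed = 880 + r)
    p_sync <- boot$estimates$p_value[boot$estimates$coefficient == "prop_sync"]
    if (p_sync <= 0.1) rejections <- rejections + 1L
  }
  expect_lte(rejections, ceiling(0.35 * n_rep))
})

test_that("cue correlations match a hand-computed oracle", {
  tbl <- tibble::tibble(max_offset_ms = c(10, 40, 70, 120, 160),
                        prop_sync = c(0.8, 0.5, 0.45, 0.2, 0.1),
                        rate_hz = c(8, 10, 12, 14, 8))
  out <- feature_correlations(tbl)
  r_oracle <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(out$r[out$pair == "offset-sync"],
               r_oracle(tbl$max_offset_ms, tbl$prop_sync), tolerance = 1e-12)
  expect_equal(out$r[out$pair == "offset-rate"],
               r_oracle(tbl$max_offset_ms, tbl$rate_hz), tolerance = 1e-12)
  expect_equal(out$r[out$pair == "sync-rate"],
               r_oracle(tbl$prop_sync, tbl$rate_hz), tolerance = 1e-12)
  # a column against itself is perfectly correlated
  self <- feature_correlations(tibble::tibble(max_offset_ms = 1:5,
                                              prop_sync = 1:5,
                                              rate_hz = c(2, 1, 5, 3, 4)))
  expect_equal(self$r[self$pair == "offset-sync"], 1, tolerance = 1e-12)
  expect_error(feature_correlations(tbl[1:2, ]), ">= 3 rows")
  tbl$prop_sync <- 0.5
  expect_error(feature_correlations(tbl), "zero variance")
})
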