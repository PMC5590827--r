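#' Fit a cumulative-Gaussian psychometric function by MCMC
#'
#' Models the probability of a "comparison faster" response as
#' `P(faster) = Phi((x - mu) / sigma)` where `x` is the stimulus level
#' (rate difference from the standard, or an SNR after [z_transform()]).
#' Flat priors are used for both parameters: `mu ~ U(mu_range)` and
#' `log(sigma) ~ U(log_sigma_range)`. Sampling is by random-walk Metropolis
#' on `(mu, log sigma)` with a proposal scale adapted during burn-in, after
#' which `n_samples` thinned draws are retained.
#'
#' @param x numeric vector of stimulus levels (one per trial).
#' @param response binary vector (1 / `TRUE` = "comparison faster").
#' @param mu_range support of the flat prior on `mu` (default `c(-7, 7)`).
#' @param log_sigma_range support of the flat prior on `log(sigma)`
#'   (default `c(-2.3, 1.6)`).
#' @param n_samples posterior draws to retain (default 2000).
#' @param burn_in burn-in iterations (default 2000).
#' @param thin thinning interval after burn-in (default 5).
#' @param seed optional RNG seed.
#' @return An object of class `psychometric_posterior` with elements
#'   `mu_samples`, `sigma_samples`, `mu_hat`, `sigma_hat`, `ci95` (2 x 2
#'   matrix, rows mu/sigma), `acceptance_rate`, `rhat` (split-half potential
#'   scale reduction per parameter), `n_trials`, and `degenerate`.
#' @examples
#' set.seed(2)
#' x <- rep(c(-4, -2, -1, 1, 2, 4), each = 30)
#' resp <- rbinom(length(x), 1, pnorm(x / 2))
#' fit <- fit_psychometric(x, resp, seed = 9)
#' round(c(fit$mu_hat, fit$sigma_hat), 2)
#' @export
fit_psychometric <- function(x, response, mu_range = c(-7, 7),
                             log_sigma_range = c(-2.3, 1.6),
                             n_samples = 2000, burn_in = 2000, thin = 5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  response <- as.integer(response)
  stopifnot(length(x) == length(response), all(response %in% c(0L, 1L)))
  if (length(unique(x)) < 2L) {
    stop("need >= 2 distinct stimulus levels")
  }
  degenerate <- length(unique(response)) < 2L
  if (degenerate) {
    warning("fit-degenerate: all responses identical; posterior hugs prior bounds")
  }

  # aggregate to unique levels for a cheap likelihood
  lev <- sort(unique(x))
  k <- vapply(lev, function(l) sum(response[x == l]), numeric(1))
  n <- vapply(lev, function(l) sum(x == l), numeric(1))

  loglik <- function(mu, log_sigma) {
    z <- (lev - mu) / exp(log_sigma)
    sum(k * pnorm(z, log.p = TRUE) +
          (n - k) * pnorm(z, lower.tail = FALSE, log.p = TRUE))
  }
  in_prior <- function(mu, log_sigma) {
    mu >= mu_range[1] && mu <= mu_range[2] &&
      log_sigma >= log_sigma_range[1] && log_sigma <= log_sigma_range[2]
  }

  # initial state: level with response proportion nearest 0.5; mid-prior slope
  p_hat <- (k + 0.5) / (n + 1)
  mu0 <- min(max(lev[which.min(abs(p_hat - 0.5))], mu_range[1]), mu_range[2])
  ls0 <- mean(log_sigma_range)
  cur <- c(mu0, ls0)
  cur_ll <- loglik(cur[1], cur[2])

  step <- c(diff(mu_range), diff(log_sigma_range)) / 20
  n_iter <- burn_in + n_samples * thin
  keep_mu <- numeric(n_samples)
  keep_ls <- numeric(n_samples)
  n_acc <- 0L
  n_post <- 0L
  acc_window <- 0L
  for (it in seq_len(n_iter)) {
    prop <- cur + rnorm(2L) * step
    if (in_prior(prop[1], prop[2])) {
      prop_ll <- loglik(prop[1], prop[2])
      if (log(runif(1)) < prop_ll - cur_ll) {
        cur <- prop
        cur_ll <- prop_ll
        acc_window <- acc_window + 1L
        if (it > burn_in) n_acc <- n_acc + 1L
      }
    }
    if (it <= burn_in && it %% 100L == 0L) {
      # adapt towards ~30% acceptance during burn-in
      rate <- acc_window / 100
      step <- step * exp(rate - 0.3)
      acc_window <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      n_post <- n_post + 1L
      keep_mu[n_post] <- cur[1]
      keep_ls[n_post] <- cur[2]
    }
  }
  sigma <- exp(keep_ls)
  ci <- rbind(mu = quantile(keep_mu, c(0.025, 0.975), names = FALSE),
              sigma = quantile(sigma, c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("2.5%", "97.5%")
  structure(
    list(mu_samples = keep_mu, sigma_samples = sigma,
         mu_hat = mean(keep_mu), sigma_hat = mean(sigma), ci95 = ci,
         acceptance_rate = n_acc / (n_samples * thin),
         rhat = c(mu = split_rhat(keep_mu), sigma = split_rhat(keep_ls)),
         n_trials = length(x), degenerate = degenerate),
    class = "psychometric_posterior")
}

# split-half potential scale reduction on one chain
split_rhat <- function(draws) {
  n <- floor(length(draws) / 2)
  halves <- list(draws[seq_len(n)], draws[(n + 1):(2 * n)])
  w <- mean(vapply(halves, stats::var, numeric(1)))
  b <- n * stats::var(vapply(halves, mean, numeric(1)))
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @export
print.psychometric_posterior <- function(x, ...) {
  cat(sprintf(
    "<psychometric_posterior> mu = %.3f [%.3f, %.3f], sigma = %.3f [%.3f, %.3f] (n = %d)\n",
    x$mu_hat, x$ci95[1, 1], x$ci95[1, 2],
    x$sigma_hat, x$ci95[2, 1], x$ci95[2, 2], x$n_trials))
  invisible(x)
}

cell_key <- function(...) paste(..., sep = "|")

#' Fit psychometric functions per cell of a trial table
#'
#' @param trials data frame with columns `rate_diff`, `response_faster` and
#'   the grouping columns in `by`.
#' @param by character vector of grouping columns
#'   (default `c("subject", "condition", "modality")`).
#' @param level_col column holding the stimulus level (default `"rate_diff"`).
#' @param ... further arguments passed to [fit_psychometric()].
#' @return A named list of `psychometric_posterior` objects, keyed by the
#'   `|`-joined cell values.
#' @export
fit_psychometric_cells <- function(trials,
                                   by = c("subject", "condition", "modality"),
                                   level_col = "rate_diff", ...) {
  keys <- do.call(cell_key, trials[by])
  fits <- lapply(split(seq_len(nrow(trials)), keys), function(idx) {
    fit_psychometric(trials[[level_col]][idx], trials$response_faster[idx], ...)
  })
  fits
}

#' Transform stimulus levels to signal-to-noise units
#'
#' Replaces each trial's stimulus level `r` by `(r - mu_hat) / sigma_hat`
#' using the point estimates of the psychometric fit for that trial's cell,
#' so that all psychometric functions have `mu = 0`, `sigma = 1` and raw
#' data can be pooled across subjects, conditions and modalities.
#'
#' @param trials trial table (see [fit_psychometric_cells()]).
#' @param fits named list of fits from [fit_psychometric_cells()].
#' @param by grouping columns used for the fits.
#' @param level_col stimulus-level column.
#' @return `trials` with an added numeric column `z`.
#' @export
z_transform <- function(trials, fits,
                        by = c("subject", "condition", "modality"),
                        level_col = "rate_diff") {
  keys <- do.call(cell_key, trials[by])
  missing <- setdiff(unique(keys), names(fits))
  if (length(missing)) {
    stop("no psychometric fit for cell(s): ", paste(missing, collapse = ", "))
  }
  mu <- vapply(fits, `[[`, numeric(1), "mu_hat")[keys]
  sg <- vapply(fits, `[[`, numeric(1), "sigma_hat")[keys]
  trials$z <- unname((trials[[level_col]] - mu) / sg)
  trials
}

#' Attention-switch split of pooled z-scored trials
#'
#' Splits trials by whether the preceding comparison trial was in the same
#' modality condition ("stay") or a different one ("switch"), and fits an
#' independent psychometric function to each split in SNR units. Trials with
#' no recorded previous modality are excluded.
#'
#' @param ztrials z-scored trial table (needs columns `z`, `modality`,
#'   `prev_modality`, `response_faster`).
#' @param ... passed to [fit_psychometric()].
#' @return A list with `psychometric_posterior` elements `stay` and `switch`
#'   plus the split sizes.
#' @export
split_fit_switch <- function(ztrials, ...) {
  known <- !is.na(ztrials$prev_modality)
  t <- ztrials[known, ]
  stay <- t$prev_modality == t$modality
  if (!any(stay) || all(stay)) stop("empty attention-switch split")
  list(
    stay = fit_psychometric(t$z[stay], t$response_faster[stay], ...),
    switch = fit_psychometric(t$z[!stay], t$response_faster[!stay], ...),
    n = c(stay = sum(stay), switch = sum(!stay)))
}

#' Duration splits of pooled z-scored trials
#'
#' Two analyses of the duration-jitter manipulation: (1) independent fits to
#' short (-250 to -100 ms jitter) and long (+100 to +250 ms) trials, omitting
#' trials with smaller absolute jitter; (2) a per-jitter-level fit over the
#' 11 jitter values with an ordinary least-squares regression of the PSE on
#' jitter. A negative slope indicates counting (judgements driven by total
#' event number), a zero slope pure rate estimation.
#'
#' @param ztrials z-scored trial table (needs columns `z`,
#'   `duration_jitter_ms`, `response_faster`).
#' @param split_min_ms smallest absolute jitter admitted to the short/long
#'   split (default 100 ms).
#' @param ... passed to [fit_psychometric()].
#' @return A list with fits `short` and `long`, a tibble `pse_by_jitter`
#'   (`jitter_ms`, `pse`, `sigma`, `n`), and `regression` (lm fit of
#'   `pse ~ jitter_ms` with `slope`, `slope_ci90`, `r_squared`, `p_value`).
#' @export
split_fit_duration <- function(ztrials, split_min_ms = 100, ...) {
  j <- ztrials$duration_jitter_ms
  short <- j <= -split_min_ms
  long <- j >= split_min_ms
  if (!any(short) || !any(long)) stop("empty duration split")
  fits <- list(
    short = fit_psychometric(ztrials$z[short], ztrials$response_faster[short], ...),
    long = fit_psychometric(ztrials$z[long], ztrials$response_faster[long], ...))

  levels <- sort(unique(j))
  per <- lapply(levels, function(l) {
    idx <- j == l
    f <- fit_psychometric(ztrials$z[idx], ztrials$response_faster[idx], ...)
    tibble::tibble(jitter_ms = l, pse = f$mu_hat, sigma = f$sigma_hat,
                   n = sum(idx))
  })
  pse_tbl <- do.call(rbind, per)
  if (nrow(pse_tbl) < length(seq(-250, 250, 50))) {
    warning("regression over ", nrow(pse_tbl), " available jitter levels")
  }
  reg <- lm(pse ~ jitter_ms, data = pse_tbl)
  sm <- summary(reg)
  fits$pse_by_jitter <- pse_tbl
  fits$regression <- list(
    fit = reg,
    slope = unname(coef(reg)["jitter_ms"]),
    slope_ci90 = unname(confint(reg, "jitter_ms", level = 0.90)[1, ]),
    r_squared = sm$adj.r.squared,
    f_stat = unname(sm$fstatistic[1]),
    p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE)))
  fits
}

#' Causal split of temporal-conflict trials by the integration boundary
#'
#' Splits z-scored multisensory temporal-conflict trials by whether a
#' "common source" judgement is more likely according to the causal-judgement
#' model: trials whose maximum click-flash offset is at or below
#' `boundary_ms` form the common-likely group, the rest the separate-likely
#' group. Each group receives an independent psychometric fit in SNR units.
#'
#' @param ztrials z-scored trial table with columns `z`, `response_faster`.
#' @param max_offset_ms per-trial maximum click-flash offset (ms), aligned
#'   with `ztrials` rows.
#' @param boundary_ms integration boundary in ms (see
#'   [integration_boundary()]).
#' @param ... passed to [fit_psychometric()].
#' @return A list with fits `common` and `separate` and the split sizes.
#' @export
split_fit_causal <- function(ztrials, max_offset_ms, boundary_ms, ...) {
  stopifnot(length(max_offset_ms) == nrow(ztrials))
  common <- max_offset_ms <= boundary_ms
  if (!any(common)) stop("empty common-likely group at this boundary")
  if (all(common)) stop("empty separate-likely group at this boundary")
  list(
    common = fit_psychometric(ztrials$z[common],
                              ztrials$response_faster[common], ...),
    separate = fit_psychometric(ztrials$z[!common],
                                ztrials$response_faster[!common], ...),
    n = c(common = sum(common), separate = sum(!common)))
}

#' Export a psychometric fit (or list of fits) as JSON
#'
#' @param fits a `psychometric_posterior` or named list of them.
#' @param path output path; `NULL` returns the JSON string.
#' @param draws include the full posterior draws (default `FALSE`).
#' @return `path` invisibly, or the JSON string.
#' @export
write_fits_json <- function(fits, path = NULL, draws = FALSE) {
  one <- function(f) {
    out <- list(mu_hat = f$mu_hat, sigma_hat = f$sigma_hat,
                mu_ci95 = unname(f$ci95[1, ]), sigma_ci95 = unname(f$ci95[2, ]),
                n_trials = f$n_trials, acceptance_rate = f$acceptance_rate,
                rhat = as.list(f$rhat))
    if (draws) {
      out$mu_samples <- f$mu_samples
      out$sigma_samples <- f$sigma_samples
    }
    out
  }
  x <- if (inherits(fits, "psychometric_posterior")) one(fits) else lapply(fits, one)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
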