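#' Fit the logistic mixed-effects causal-judgement model
#'
#' Models the probability of a "common source" judgement on
#' temporal-conflict trials as a logistic function of the proportion of
#' synchronous click-flash pairs and the maximum click-flash offset (in
#' seconds), with a per-subject random intercept:
#' `logit P(common) = b0 + b_sync * prop_sync + b_off * offset_s
#'  (+ b_int * prop_sync * offset_s) + u_subject`.
#' Covariates are deliberately uncentered and unscaled so that
#' `-b0 / b_off` is directly the offset at which P(common) = 0.5 (the
#' integration boundary). Estimation is maximum likelihood with the Laplace
#' approximation to the random-intercept integral (via \pkg{lme4}).
#'
#' @param table data frame with columns `subject`, `prop_sync`,
#'   `max_offset_s`, `response_common` (binary).
#' @param include_sync include the proportion-synchronous main effect
#'   (default `TRUE`).
#' @param include_interaction include the sync x offset interaction
#'   (default `TRUE`).
#' @return An object of class `causal_glmm` with elements `beta_intercept`,
#'   `beta_sync`, `beta_offset`, `beta_interaction` (NA when excluded),
#'   `random_intercept_sd`, `converged`, and the underlying `model`.
#' @export
fit_causal_glmm <- function(table, include_sync = TRUE,
                            include_interaction = TRUE) {
  stopifnot(all(c("subject", "prop_sync", "max_offset_s", "response_common")
                %in% names(table)))
  if (length(unique(table$subject)) < 2) stop("need >= 2 subjects")
  if (length(unique(table$response_common)) < 2) {
    stop("both response values must be present")
  }
  terms <- "max_offset_s"
  if (include_sync) terms <- c("prop_sync", terms)
  if (include_interaction) {
    if (!include_sync) stop("interaction requires the sync main effect")
    terms <- c(terms, "prop_sync:max_offset_s")
  }
  form <- as.formula(paste("response_common ~",
                           paste(terms, collapse = " + "), "+ (1 | subject)"))
  model <- lme4::glmer(form, data = table, family = binomial)
  msgs <- model@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged && any(grepl("failed to converge", msgs))) {
    stop("causal GLMM failed to converge (possible complete separation)")
  }
  fe <- lme4::fixef(model)
  structure(
    list(beta_intercept = unname(fe["(Intercept)"]),
         beta_sync = if (include_sync) unname(fe["prop_sync"]) else NA_real_,
         beta_offset = unname(fe["max_offset_s"]),
         beta_interaction = if (include_interaction)
           unname(fe["prop_sync:max_offset_s"]) else NA_real_,
         random_intercept_sd =
           sqrt(unname(lme4::VarCorr(model)$subject[1, 1])),
         converged = converged,
         formula = form,
         table = table,
         model = model),
    class = "causal_glmm")
}

#' @export
print.causal_glmm <- function(x, ...) {
  cat("<causal_glmm> logit P(common) =\n")
  cat(sprintf("  %.3f%s %+.3f * max_offset_s%s + u_subject (sd %.3f)\n",
              x$beta_intercept,
              if (is.na(x$beta_sync)) "" else sprintf(" %+.3f * prop_sync", x$beta_sync),
              x$beta_offset,
              if (is.na(x$beta_interaction)) ""
              else sprintf(" %+.3f * sync:offset", x$beta_interaction),
              x$random_intercept_sd))
  invisible(x)
}

#' Parametric-bootstrap inference for the causal GLMM
#'
#' Simulates response tables from the fitted model, refits each, and forms
#' percentile confidence intervals per fixed effect. The two-sided p-value
#' for a coefficient is the tail probability of 0 under its bootstrap
#' distribution, floored at `1 / (n_boot + 1)`.
#'
#' @param fit a converged [fit_causal_glmm()] result.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param level confidence level for the percentile intervals (default 0.90).
#' @param seed optional RNG seed.
#' @return A list with `estimates` (a tibble: coefficient, estimate,
#'   ci_lower, ci_upper, p_value), `n_failed` (refits that errored, excluded),
#'   and `boot_samples` (matrix of bootstrap fixed effects).
#' @export
bootstrap_pvalues <- function(fit, n_boot = 1000, level = 0.90, seed = NULL) {
  stopifnot(inherits(fit, "causal_glmm"))
  if (!is.null(seed)) set.seed(seed)
  model <- fit$model
  fe <- lme4::fixef(model)
  sims <- simulate(model, nsim = n_boot)
  boot <- matrix(NA_real_, n_boot, length(fe),
                 dimnames = list(NULL, names(fe)))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    res <- tryCatch(lme4::fixef(lme4::refit(model, newresp = sims[[b]])),
                    error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else boot[b, ] <- res
  }
  if (n_failed > 0) {
    message(n_failed, " bootstrap refits failed and were excluded")
  }
  boot_ok <- boot[stats::complete.cases(boot), , drop = FALSE]
  a <- (1 - level) / 2
  est <- lapply(names(fe), function(nm) {
    bs <- boot_ok[, nm]
    p <- 2 * min(mean(bs <= 0), mean(bs >= 0))
    tibble::tibble(
      coefficient = nm,
      estimate = unname(fe[nm]),
      boot_mean = mean(bs),
      ci_lower = unname(quantile(bs, a)),
      ci_upper = unname(quantile(bs, 1 - a)),
      p_value = min(max(p, 1 / (n_boot + 1)), 1))
  })
  list(estimates = do.call(rbind, est), n_failed = n_failed,
       boot_samples = boot_ok, level = level)
}

#' Integration boundary of the causal-judgement model
#'
#' The maximum click-flash offset at which the fitted model predicts a 0.5
#' probability of a "common source" response: `-b0 / b_off`, converted to
#' ms. Defined on the offset axis, so the model must contain only the
#' intercept and the offset effect (fit with `include_sync = FALSE`), or the
#' coefficients can be supplied directly.
#'
#' @param fit a `causal_glmm` fit with sync and interaction terms absent or
#'   zero, or `NULL` if coefficients are given.
#' @param beta_intercept,beta_offset coefficients on the log-odds scale
#'   (offset effect per second); extracted from `fit` when omitted.
#' @return Boundary in ms.
#' @examples
#' integration_boundary(beta_intercept = 1.76, beta_offset = -17)  # ~103.5 ms
#' @export
integration_boundary <- function(fit = NULL, beta_intercept = NULL,
                                 beta_offset = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "causal_glmm"))
    if (!is.na(fit$beta_sync) &&
        (abs(fit$beta_sync) > 1e-8 ||
         (!is.na(fit$beta_interaction) && abs(fit$beta_interaction) > 1e-8))) {
      stop("boundary is defined on the offset axis: refit with include_sync = FALSE")
    }
    beta_intercept <- fit$beta_intercept
    beta_offset <- fit$beta_offset
  }
  if (beta_offset == 0) stop("undefined boundary: beta_offset is zero")
  -beta_intercept / beta_offset * 1000
}

#' Pairwise Pearson correlations among the temporal cues
#'
#' Product-moment correlations between maximum click-flash offset,
#' proportion synchronous, and nominal sequence rate, with their p-values.
#'
#' @param table data frame with columns `max_offset_ms` (or `max_offset_s`),
#'   `prop_sync`, `rate_hz`.
#' @return A tibble with columns `pair`, `r`, `p`.
#' @export
feature_correlations <- function(table) {
  if (nrow(table) < 3) stop("need >= 3 rows")
  off <- if ("max_offset_ms" %in% names(table)) table$max_offset_ms
         else table$max_offset_s
  cols <- list(offset = off, sync = table$prop_sync, rate = table$rate_hz)
  if (any(vapply(cols, sd, numeric(1)) == 0)) {
    stop("undefined correlation: a cue column has zero variance")
  }
  pairs <- list(c("offset", "sync"), c("offset", "rate"), c("sync", "rate"))
  rows <- lapply(pairs, function(p) {
    ct <- cor.test(cols[[p[1]]], cols[[p[2]]])
    tibble::tibble(pair = paste(p, collapse = "-"),
                   r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Export a causal GLMM fit as JSON
#' @param fit a `causal_glmm`.
#' @param path output path; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string.
#' @export
write_glmm_json <- function(fit, path = NULL) {
  x <- list(beta_intercept = fit$beta_intercept, beta_sync = fit$beta_sync,
            beta_offset = fit$beta_offset,
            beta_interaction = fit$beta_interaction,
            random_intercept_sd = fit$random_intercept_sd,
            converged = fit$converged)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
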