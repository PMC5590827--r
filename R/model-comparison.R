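#' Log model evidence for a fixed-parameter psychometric model
#'
#' With both parameters fixed the model has no free parameters, so the
#' evidence equals the Bernoulli likelihood of the responses under
#' `P(faster) = Phi((x - mu_fixed) / sigma_fixed)`. Used to score the
#' best-cue model (`mu_fixed = mu_best`, `sigma_fixed = sigma_best`) and the
#' optimal-integration model (`mu_fixed = 0`, `sigma_fixed = sigma_opt`)
#' against observed multisensory responses.
#'
#' @param response binary responses (1 = "comparison faster").
#' @param x stimulus levels, one per trial.
#' @param mu_fixed fixed PSE.
#' @param sigma_fixed fixed threshold (> 0).
#' @return Log evidence (a single number).
#' @export
model_evidence <- function(response, x, mu_fixed, sigma_fixed) {
  stopifnot(sigma_fixed > 0, length(response) == length(x))
  response <- as.integer(response)
  z <- (x - mu_fixed) / sigma_fixed
  sum(ifelse(response == 1L,
             pnorm(z, log.p = TRUE),
             pnorm(z, lower.tail = FALSE, log.p = TRUE)))
}

#' Log model evidence averaged over a threshold posterior
#'
#' Alternative to the plug-in point estimate of [model_evidence()]: the
#' evidence is the posterior-averaged likelihood,
#' `log mean_s L(data | mu_fixed, sigma_s)`, computed stably by
#' log-sum-exp over the supplied sigma draws.
#'
#' @inheritParams model_evidence
#' @param sigma_samples posterior draws of the predicted threshold.
#' @return Log evidence.
#' @export
model_evidence_posterior <- function(response, x, mu_fixed, sigma_samples) {
  ll <- vapply(sigma_samples, function(s) model_evidence(response, x, mu_fixed, s),
               numeric(1))
  m <- max(ll)
  m + log(mean(exp(ll - m)))
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects and fits a
#' Dirichlet distribution over model frequencies by the variational
#' fixed-point iteration of hierarchical group-level model selection:
#' posterior model assignments and the Dirichlet concentration are updated
#' alternately until convergence. For two models the exceedance probability
#' (the probability that one model is more frequent in the population than
#' the other) is computed exactly from the Beta distribution; for more
#' models it is estimated from Dirichlet Monte-Carlo draws.
#'
#' @param log_evidence numeric matrix, subjects x models, of log model
#'   evidences.
#' @param alpha0 Dirichlet prior concentration per model (default 1).
#' @param tol convergence tolerance on the concentration parameters
#'   (default 1e-8).
#' @param max_iter iteration cap.
#' @param n_mc Monte-Carlo draws for > 2 models.
#' @return An object of class `bms_result` with `alpha`, `expected_probs`,
#'   `exceedance`, `assignments` (subjects x models posterior), and
#'   `iterations`.
#' @export
rfx_bms <- function(log_evidence, alpha0 = 1, tol = 1e-8, max_iter = 10000,
                    n_mc = 1e5) {
  log_evidence <- as.matrix(log_evidence)
  if (!all(is.finite(log_evidence))) stop("non-finite log evidence")
  n <- nrow(log_evidence)
  k <- ncol(log_evidence)
  stopifnot(n >= 1, k >= 2)
  alpha0 <- rep_len(alpha0, k)
  alpha <- alpha0
  g <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    logu <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    logu <- logu - apply(logu, 1, max)
    u <- exp(logu)
    g <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  exceedance <- exceedance_probability(alpha, n_mc = n_mc)
  structure(
    list(alpha = alpha, expected_probs = alpha / sum(alpha),
         exceedance = exceedance, assignments = g, iterations = it),
    class = "bms_result")
}

#' Exceedance probabilities of a Dirichlet distribution
#'
#' For two models `P(p1 > p2)` is computed exactly from the Beta CDF at 0.5;
#' for more models it is estimated by Monte Carlo over Dirichlet draws.
#'
#' @param alpha Dirichlet concentration vector.
#' @param n_mc Monte-Carlo draws used when `length(alpha) > 2`.
#' @return A probability vector summing to 1.
#' @export
exceedance_probability <- function(alpha, n_mc = 1e5) {
  k <- length(alpha)
  if (k == 2) {
    xp1 <- pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(c(xp1, 1 - xp1))
  }
  draws <- matrix(rgamma(n_mc * k, shape = rep(alpha, each = n_mc)), n_mc, k)
  tabulate(max.col(draws), k) / n_mc
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n")
  cat("  alpha:          ", paste(sprintf("%.3f", x$alpha), collapse = ", "), "\n")
  cat("  expected probs: ", paste(sprintf("%.3f", x$expected_probs), collapse = ", "), "\n")
  cat("  exceedance:     ", paste(sprintf("%.3f", x$exceedance), collapse = ", "), "\n")
  invisible(x)
}
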