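#' Build a pipeline configuration
#'
#' All randomness in [run_pipeline()] flows from `seed` via named per-stage
#' substreams, so each stage is individually reproducible. The default sizes
#' give a complete single-CPU demonstration run in well under a minute per
#' stage; they are demonstration sizes, not the full study design.
#'
#' @param seed master seed (integer).
#' @param out_dir output directory for stage artifacts; `NULL` skips writing.
#' @param n_subjects_exp1 synthetic observers for the rate-discrimination
#'   stage.
#' @param conditions conditions simulated in the rate-discrimination stage.
#' @param n_per_cell trials per observer x condition x modality x level.
#' @param n_subjects_exp2,n_sessions_exp2 causality-judgement design size.
#' @param n_conflict,n_noconflict causality-judgement trials per rate per
#'   session.
#' @param mcmc_samples,mcmc_burn_in,mcmc_thin psychometric sampler settings.
#' @param n_perm permutations for the CCG analysis.
#' @param n_boot parametric-bootstrap replicates for the causal model.
#' @param stages character vector of stages to run, from
#'   `c("exp1", "exp2")`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            n_subjects_exp1 = 3,
                            conditions = c("no-conflict", "temporal"),
                            n_per_cell = 8,
                            n_subjects_exp2 = 3, n_sessions_exp2 = 1,
                            n_conflict = 25, n_noconflict = 5,
                            mcmc_samples = 1000, mcmc_burn_in = 1000,
                            mcmc_thin = 2,
                            n_perm = 200, n_boot = 0,
                            stages = c("exp1", "exp2")) {
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic substream seed derived from the master seed and a stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (seed * 7919 + h) %% .Machine$integer.max
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL   # hash the scientific parameters, not the destination
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("%08x", sum(utf8ToInt(as.character(json)) *
                        (seq_along(utf8ToInt(as.character(json))) %% 31 + 1)) %%
            .Machine$integer.max)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes, per the configuration: (exp1) synthetic rate-discrimination
#' data, per-cell psychometric fits, z-transform, best-cue and
#' optimal-integration predictions with classification, fixed-parameter
#' model evidence and random-effects model selection per condition, and the
#' attention-switch and duration splits; (exp2) synthetic causality
#' judgements, cue extraction, the causal GLMM with integration boundary and
#' cue correlations, the CCG difference function with permutation bounds for
#' the first subject, and the causal split of temporal-conflict
#' discrimination trials. Stage artifacts are written to `config$out_dir`
#' when set, together with a manifest recording the seed and config hash.
#'
#' @param config a [pipeline_config()].
#' @return A named list (report bundle) with per-stage results and a
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(manifest = list(seed = config$seed,
                              config_hash = config_hash(config),
                              stages = config$stages))
  dir <- config$out_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  save_json <- function(x, name) {
    if (!is.null(dir)) {
      jsonlite::write_json(
        c(list(.seed = config$seed, .config_hash = out$manifest$config_hash), x),
        file.path(dir, name), auto_unbox = TRUE, digits = NA, null = "null")
    }
  }

  if ("exp1" %in% config$stages) {
    set.seed(stage_seed(config$seed, "exp1-data"))
    observers <- replicate(config$n_subjects_exp1,
                           observer_spec(sigma_a = runif(1, 1.5, 3),
                                         sigma_v = runif(1, 1.5, 3),
                                         strategy = "optimal",
                                         counting_weight = 0.5),
                           simplify = FALSE)
    trials <- simulate_exp1_dataset(
      observers, conditions = config$conditions,
      n_per_cell = config$n_per_cell,
      seed = stage_seed(config$seed, "exp1-trials"))
    fits <- fit_psychometric_cells(
      trials, n_samples = config$mcmc_samples,
      burn_in = config$mcmc_burn_in, thin = config$mcmc_thin,
      seed = stage_seed(config$seed, "exp1-fits"))
    ztrials <- z_transform(trials, fits)

    # cue-combination predictions + model comparison per condition
    conditions <- config$conditions
    evidence <- classification <- setNames(vector("list", length(conditions)),
                                           conditions)
    for (cond in conditions) {
      le <- matrix(NA_real_, config$n_subjects_exp1, 2,
                   dimnames = list(NULL, c("optimal", "best_cue")))
      cls <- character(config$n_subjects_exp1)
      for (s in seq_len(config$n_subjects_exp1)) {
        post_a <- fits[[cell_key(s, cond, "A")]]
        post_v <- fits[[cell_key(s, cond, "V")]]
        post_av <- fits[[cell_key(s, cond, "AV")]]
        pred <- integration_prediction(
          post_a, post_v, seed = stage_seed(config$seed, paste0("opt", s, cond)))
        cls[s] <- classify_integration(post_av, pred)
        av <- trials[trials$subject == s & trials$condition == cond &
                       trials$modality == "AV", ]
        le[s, "optimal"] <- model_evidence(av$response_faster, av$rate_diff,
                                           0, pred$optimal$sigma_hat)
        le[s, "best_cue"] <- model_evidence(av$response_faster, av$rate_diff,
                                            pred$best$mu_best, pred$best$sigma_hat)
      }
      classification[[cond]] <- cls
      evidence[[cond]] <- list(log_evidence = le, bms = rfx_bms(le))
    }
    switch_split <- split_fit_switch(
      ztrials, n_samples = config$mcmc_samples,
      burn_in = config$mcmc_burn_in, thin = config$mcmc_thin,
      seed = stage_seed(config$seed, "switch"))
    duration_split <- split_fit_duration(
      ztrials, n_samples = config$mcmc_samples,
      burn_in = config$mcmc_burn_in, thin = config$mcmc_thin,
      seed = stage_seed(config$seed, "duration"))

    out$exp1 <- list(trials = trials, fits = fits, ztrials = ztrials,
                     classification = classification, evidence = evidence,
                     switch_split = switch_split,
                     duration_split = duration_split)
    if (!is.null(dir)) {
      write_trials_csv(trials, file.path(dir, "exp1_trials.csv"))
      write_fits_json(fits, file.path(dir, "exp1_fits.json"))
      save_json(list(classification = classification,
                     exceedance = lapply(evidence, function(e)
                       e$bms$exceedance)), "exp1_model_comparison.json")
    }
  }

  if ("exp2" %in% config$stages) {
    sim <- simulate_exp2_dataset(
      causal_observer_spec(),
      n_subjects = config$n_subjects_exp2,
      n_sessions = config$n_sessions_exp2,
      n_conflict = config$n_conflict, n_noconflict = config$n_noconflict,
      seed = stage_seed(config$seed, "exp2-data"))
    conflict <- sim$trials[sim$trials$temporal_conflict, ]
    glmm_full <- fit_causal_glmm(conflict)
    glmm_reduced <- fit_causal_glmm(conflict, include_sync = FALSE,
                                    include_interaction = FALSE)
    boundary <- integration_boundary(glmm_reduced)
    correlations <- feature_correlations(conflict)
    boot <- if (config$n_boot > 0) {
      bootstrap_pvalues(glmm_full, n_boot = config$n_boot,
                        seed = stage_seed(config$seed, "boot"))
    }
    # CCG analysis for the first subject's conflict trials
    s1 <- which(sim$trials$temporal_conflict & sim$trials$subject == 1)
    ccg <- permutation_bounds(sim$pairs[s1],
                              sim$trials$response_common[s1],
                              n_perm = config$n_perm,
                              seed = stage_seed(config$seed, "ccg"))
    out$exp2 <- list(trials = sim$trials, glmm = glmm_full,
                     glmm_reduced = glmm_reduced, boundary_ms = boundary,
                     correlations = correlations, bootstrap = boot,
                     ccg = ccg)
    if (!is.null(dir)) {
      write.csv(sim$trials, file.path(dir, "exp2_trials.csv"),
                row.names = FALSE)
      write_glmm_json(glmm_reduced, file.path(dir, "exp2_glmm_reduced.json"))
      write_ccg_difference_csv(ccg, file.path(dir, "exp2_ccg_subject1.csv"))
      save_json(list(boundary_ms = boundary,
                     correlations = as.list(setNames(correlations$r,
                                                     correlations$pair))),
                "exp2_summary.json")
    }
  }

  if (!is.null(dir)) save_json(out$manifest, "manifest.json")
  out
}

#' Write a trial table as delimited text
#' @param trials trial tibble (e.g. from [simulate_exp1_dataset()]).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trials_csv()]
#' @param path input path.
#' @return A tibble.
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path)
  if ("prev_modality" %in% names(df)) {
    df$prev_modality <- as.character(df$prev_modality)
  }
  tibble::as_tibble(df)
}
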