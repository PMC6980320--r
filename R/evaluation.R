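#' Prediction metrics
#'
#' `rmse` is the root mean squared error. `log_loss` is the negative mean
#' Bernoulli log-likelihood `-mean(y log p + (1-y) log(1-p))`; probabilities
#' are clipped to `[1e-15, 1 - 1e-15]` so the loss is finite.
#'
#' @param predictions Numeric predictions (probabilities for `log_loss`).
#' @param truth Observed outcomes (0/1 for `log_loss`).
#' @return Nonnegative scalar.
#' @export
rmse <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  sqrt(mean((predictions - truth)^2))
}

#' @rdname rmse
#' @export
log_loss <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  if (!all(truth %in% c(0, 1))) stop("'truth' must be 0/1 for log loss")
  p <- pmin(pmax(predictions, 1e-15), 1 - 1e-15)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Percent change of a score relative to the Merged learner
#'
#' @param score Score of the comparator strategy.
#' @param merged_score Score of the Merged learner (must be > 0).
#' @return `100 * (score - merged_score) / merged_score`.
#' @export
percent_change_vs_merged <- function(score, merged_score) {
  if (any(merged_score <= 0)) stop("'merged_score' must be positive")
  100 * (score - merged_score) / merged_score
}

all_strategies <- c("merged", "unweighted", "weighting_forests", "weighting_trees")

# fit the requested strategies on one simulated collection and score each on
# every validation study; pooled score = equal-weight mean over studies
evaluate_iteration <- function(sim, strategies, m, mtry, seed, stacking) {
  task <- if (sim$model$outcome_type == "binary") "classification" else "regression"
  metric <- if (task == "classification") log_loss else rmse
  val <- validation_studies(sim$collection)
  ensembles <- lapply(strategies, function(s) {
    fit_ensemble(s, sim$collection, m = m, mtry = mtry, seed = seed,
                 task = task, stacking = stacking)
  })
  names(ensembles) <- strategies
  per_study <- do.call(rbind, lapply(strategies, function(s) {
    sc <- vapply(val, function(v) {
      metric(predict(ensembles[[s]], v$features), v$outcome)
    }, numeric(1))
    data.frame(strategy = s,
               study_id = vapply(val, `[[`, character(1), "study_id"),
               score = sc, stringsAsFactors = FALSE)
  }))
  pooled <- stats::aggregate(score ~ strategy, per_study, mean)
  list(per_study = per_study, pooled = pooled, ensembles = ensembles)
}

#' Run a simulation scenario
#'
#' For each iteration: build a fresh collection, fit every requested
#' strategy on the same training data, and score each on the identical
#' validation studies (RMSE for continuous outcomes, log loss for binary).
#' Per-validation-study scores are averaged with equal study weight into the
#' pooled iteration score; the scenario summary reports per-strategy mean,
#' standard error, 1.96 x SE confidence half-width and percent change of the
#' mean versus the Merged learner. Iterations are independently seeded from
#' `master_seed`, so results are order-independent and reproducible; a
#' failing iteration is recorded and skipped.
#'
#' @param config A [scenario_config()].
#' @param n_iterations Number of iterations; default from the config.
#' @param master_seed Master seed; default from the config.
#' @param strategies Strategies to fit (default all four).
#' @param m,mtry Forest size and mtry forwarded to [fit_ensemble()].
#' @param stacking Stacking arguments forwarded to [fit_ensemble()].
#' @param diagnostics Also collect, per iteration, the tree-level weights
#'   and [tree_structure_table()] of each stacked strategy (default FALSE).
#'
#' @return An object of class `scenario_result`: `summary` (per-strategy
#'   data frame with `mean_score`, `se`, `ci_halfwidth`,
#'   `pct_change_vs_merged`), `iterations` (pooled score per iteration x
#'   strategy), `per_study` (score per iteration x strategy x validation
#'   study), `diagnostics` (list per iteration or NULL), `config`,
#'   `n_failed`, `failures`.
#' @export
run_scenario <- function(config, n_iterations = config$n_iterations,
                         master_seed = config$master_seed,
                         strategies = all_strategies, m = 10L, mtry = NULL,
                         stacking = list(), diagnostics = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  strategies <- match.arg(strategies, all_strategies, several.ok = TRUE)
  iter_seeds <- seed_stream(master_seed, 2L * n_iterations)
  rows_it <- list(); rows_st <- list(); diag <- list()
  failures <- character(0)
  for (i in seq_len(n_iterations)) {
    res <- tryCatch({
      sim <- build_collection(config, iter_seeds[i])
      ev <- evaluate_iteration(sim, strategies, m, mtry,
                               seed = iter_seeds[n_iterations + i], stacking)
      if (diagnostics) {
        d <- lapply(ev$ensembles[intersect(strategies,
                                           c("weighting_forests", "weighting_trees"))],
                    function(e) list(weights = tree_level_weights(e),
                                     structure = tree_structure_table(e, sim$model)))
        diag[[length(diag) + 1L]] <- d
      }
      ev
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("iteration %d: %s", i, conditionMessage(res)))
      next
    }
    res$pooled$iteration <- i
    res$pooled$seed <- iter_seeds[i]
    res$per_study$iteration <- i
    rows_it[[length(rows_it) + 1L]] <- res$pooled
    rows_st[[length(rows_st) + 1L]] <- res$per_study
  }
  if (!length(rows_it)) stop("every iteration failed: ", paste(failures, collapse = "; "))
  iterations <- do.call(rbind, rows_it)
  per_study <- do.call(rbind, rows_st)
  agg <- stats::aggregate(score ~ strategy, iterations,
                          function(x) c(mean = mean(x),
                                        se = stats::sd(x) / sqrt(length(x))))
  summary <- data.frame(strategy = agg$strategy,
                        mean_score = agg$score[, "mean"],
                        se = agg$score[, "se"],
                        stringsAsFactors = FALSE)
  summary$ci_halfwidth <- 1.96 * summary$se
  if ("merged" %in% summary$strategy) {
    ms <- summary$mean_score[summary$strategy == "merged"]
    summary$pct_change_vs_merged <- percent_change_vs_merged(summary$mean_score, ms)
  } else {
    summary$pct_change_vs_merged <- NA_real_
  }
  summary <- summary[match(intersect(all_strategies, summary$strategy),
                           summary$strategy), ]
  rownames(summary) <- NULL
  structure(
    list(summary = summary, iterations = iterations, per_study = per_study,
         diagnostics = if (diagnostics) diag else NULL, config = config,
         n_failed = length(failures), failures = failures),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d iterations (%d failed)\n",
              length(unique(x$iterations$iteration)), x$n_failed))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Sweep the feature-effect heterogeneity level
#'
#' Runs one scenario per level with `l_high = level`, `l_low` held at 0.25
#' and `l_validate = level / 2` (the validation studies sit between the two
#' training levels). All levels share the same per-iteration seeds (common
#' random numbers): iteration i draws the same generative model and feature
#' matrices at every level, and the coefficient-perturbation draws scale
#' with the level, so level contrasts are paired and free of between-level
#' simulation noise.
#'
#' @param config Base [scenario_config()].
#' @param levels Numeric vector of heterogeneity levels (the high training
#'   level).
#' @param n_iterations,master_seed,strategies,m,mtry,stacking As in
#'   [run_scenario()].
#' @return An object of class `heterogeneity_sweep`: `results` (list of
#'   `scenario_result`, one per level) and `summary` (combined per-level,
#'   per-strategy data frame with a `level` column).
#' @export
run_heterogeneity_sweep <- function(config, levels,
                                    n_iterations = config$n_iterations,
                                    master_seed = config$master_seed,
                                    strategies = all_strategies, m = 10L,
                                    mtry = NULL, stacking = list()) {
  if (!length(levels)) stop("'levels' must be non-empty")
  results <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    cfg <- config
    cfg$l_high <- levels[i]
    cfg$l_low <- 0.25
    cfg$l_validate <- levels[i] / 2
    if (cfg$l_low > cfg$l_high) cfg$l_low <- cfg$l_high
    results[[i]] <- run_scenario(cfg, n_iterations = n_iterations,
                                 master_seed = master_seed,
                                 strategies = strategies, m = m, mtry = mtry,
                                 stacking = stacking)
  }
  names(results) <- as.character(levels)
  summary <- do.call(rbind, lapply(seq_along(levels), function(i) {
    s <- results[[i]]$summary
    s$level <- levels[i]
    s
  }))
  structure(list(results = results, summary = summary, levels = levels),
            class = "heterogeneity_sweep")
}

#' @export
print.heterogeneity_sweep <- function(x, ...) {
  cat(sprintf("<heterogeneity_sweep> %d levels\n", length(x$levels)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Monte-Carlo curve of interaction-explained outcome variance
#'
#' For each interaction strength, draws fresh generative models and feature
#' matrices and averages the share of outcome variance attributable to the
#' interaction terms (see [interaction_variance_share()]).
#'
#' @param config A [scenario_config()] supplying `p`, the feature source,
#'   per-study sample size and noise level.
#' @param strengths Interaction-strength grid (e.g. `0:3`).
#' @param n_reps Monte-Carlo replicates per strength.
#' @param master_seed Integer seed.
#' @return Data frame with `strength`, `mean_share` (in `[0, 1]`) and `se`.
#' @export
interaction_share_curve <- function(config, strengths = 0:3, n_reps = 50L,
                                    master_seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- seed_stream(master_seed, 2L * length(strengths) * n_reps)
  out <- data.frame(strength = strengths, mean_share = NA_real_, se = NA_real_)
  idx <- 0L
  for (si in seq_along(strengths)) {
    shares <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      idx <- idx + 1L
      model <- draw_generative_model(config$p, seeds[idx], interactions = TRUE,
                                     interaction_strength = strengths[si],
                                     noise_sd = config$noise_sd)
      X <- sample_features(config$feature_source, config$n[1L], config$p,
                           seeds[length(seeds) + 1L - idx])
      shares[r] <- interaction_variance_share(X, model)
    }
    out$mean_share[si] <- mean(shares)
    out$se[si] <- stats::sd(shares) / sqrt(n_reps)
  }
  out
}
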