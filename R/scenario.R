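#' Define a simulation scenario
#'
#' Collects every knob of the multi-study generator in one validated object.
#' Defaults reproduce the baseline study conditions: K = 10 training and
#' V = 5 validation studies of 100 samples each over p = 100 features, 10 of
#' which carry the outcome; half the training studies receive low coefficient
#' perturbation (l = 0.25), half the high level (l = 1), and validation
#' studies an intermediate level (0.4 at baseline; heterogeneity sweeps use
#' half the high level).
#'
#' @param mode `"multi_study"` (independent feature draws per study),
#'   `"repeated_single_study"` (one feature matrix reused for every training
#'   study, removing feature-distribution heterogeneity; validation studies
#'   keep independent draws), or `"pseudo_split"` (one source matrix shuffled
#'   and split into 5 equal parts, 4 train + 1 validate; any remainder rows
#'   go to the last part).
#' @param K,V Training and validation study counts (`pseudo_split` forces
#'   K = 4, V = 1).
#' @param n Per-study sample size, a scalar or length-`K+V` vector.
#' @param p Feature count (>= 10).
#' @param feature_source Feature source spec, see [sample_features()].
#' @param l_low,l_high Coefficient-perturbation levels for the low- and
#'   high-heterogeneity training studies.
#' @param l_validate Perturbation level for validation studies; default
#'   `l_high / 2`.
#' @param n_low_train Number of training studies at `l_low`; default
#'   `floor(K / 2)`.
#' @param interaction_scenario `"none"`, `"two_train_two_test"` (interaction
#'   terms active in 2 training and 2 validation studies) or
#'   `"six_train_two_test"` (6 training, 2 validation).
#' @param interaction_strength Magnitude of interaction coefficients.
#' @param noise_sd Outcome noise standard deviation.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param binary_scale Logistic scale for binary outcomes.
#' @param pseudo_n_source Source matrix row count for `pseudo_split`
#'   (default 510).
#' @param n_iterations Default iteration count for [run_scenario()].
#' @param master_seed Default master seed for [run_scenario()].
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(mode = c("multi_study", "repeated_single_study", "pseudo_split"),
                            K = 10L, V = 5L, n = 100L, p = 100L,
                            feature_source = list(type = "synthetic_mvn",
                                                  block_size = 10L, rho = 0.3),
                            l_low = 0.25, l_high = 1, l_validate = NULL,
                            n_low_train = NULL,
                            interaction_scenario = c("none", "two_train_two_test",
                                                     "six_train_two_test"),
                            interaction_strength = 2, noise_sd = 1,
                            outcome_type = c("continuous", "binary"),
                            binary_scale = 1, pseudo_n_source = 510L,
                            n_iterations = 20L, master_seed = 1L) {
  mode <- match.arg(mode)
  interaction_scenario <- match.arg(interaction_scenario)
  outcome_type <- match.arg(outcome_type)
  if (mode == "pseudo_split") { K <- 4L; V <- 1L }
  K <- as.integer(K); V <- as.integer(V)
  if (K < 2L) stop("'K' must be at least 2")
  if (V < 1L) stop("'V' must be at least 1")
  if (p < 10L) stop("'p' must be at least 10")
  if (l_low < 0 || l_high < 0) stop("heterogeneity levels must be nonnegative")
  if (l_low > l_high) stop("'l_low' must not exceed 'l_high'")
  if (is.null(l_validate)) l_validate <- l_high / 2
  if (l_validate < 0) stop("'l_validate' must be nonnegative")
  if (is.null(n_low_train)) n_low_train <- K %/% 2L
  n_low_train <- as.integer(n_low_train)
  if (n_low_train < 0L || n_low_train > K) stop("'n_low_train' must lie in [0, K]")
  n <- as.integer(n)
  if (length(n) == 1L) n <- rep(n, K + V)
  if (length(n) != K + V) stop("'n' must be a scalar or have length K + V")
  if (any(n < 2L)) stop("per-study sample sizes must be at least 2")
  needed <- switch(interaction_scenario, none = c(0L, 0L),
                   two_train_two_test = c(2L, 2L),
                   six_train_two_test = c(6L, 2L))
  if (needed[1L] > K || needed[2L] > V) {
    stop("interaction scenario places interactions in more studies than exist")
  }
  if (n_iterations < 1L) stop("'n_iterations' must be at least 1")
  structure(
    list(mode = mode, K = K, V = V, n = n, p = as.integer(p),
         feature_source = feature_source, l_low = l_low, l_high = l_high,
         l_validate = l_validate, n_low_train = n_low_train,
         interaction_scenario = interaction_scenario,
         interaction_strength = interaction_strength, noise_sd = noise_sd,
         outcome_type = outcome_type, binary_scale = binary_scale,
         pseudo_n_source = as.integer(pseudo_n_source),
         n_iterations = as.integer(n_iterations),
         master_seed = as.integer(master_seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0("<scenario_config> mode=%s K=%d V=%d p=%d | l: %.3g/%.3g ",
                     "(validate %.3g) | interactions: %s (s=%.3g) | %s outcome\n"),
              x$mode, x$K, x$V, x$p, x$l_low, x$l_high, x$l_validate,
              x$interaction_scenario, x$interaction_strength, x$outcome_type))
  invisible(x)
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [scenario_config()]; unknown keys error.
#'
#' @param path File path.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$feature_source$matrix)) {
    vals$feature_source$matrix <- as.matrix(vals$feature_source$matrix)
  }
  do.call(scenario_config, vals)
}

# draw independent sub-seeds from one seed (kept below 2^31)
seed_stream <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Build one simulated multi-study collection
#'
#' Realizes a scenario: draws the generative model, assigns heterogeneity
#' levels and interaction placement to studies, samples per-study features
#' according to the scenario mode, perturbs coefficients once per study, and
#' generates outcomes.
#'
#' @param config A [scenario_config()].
#' @param iteration_seed Integer seed for this realization.
#'
#' @return An object of class `ms_simulation`: `collection`
#'   ([ms_collection()]), `model` (the base [draw_generative_model()] object),
#'   `study_models` (named list of per-study perturbed models; studies outside
#'   the interaction placement have their interaction coefficients zeroed),
#'   and `meta` (data frame of study id, role, heterogeneity level `l`,
#'   `has_interactions`, sample size).
#' @export
build_collection <- function(config, iteration_seed) {
  stopifnot(inherits(config, "scenario_config"))
  K <- config$K; V <- config$V
  seeds <- seed_stream(iteration_seed, 4L + 3L * (K + V))
  model <- draw_generative_model(
    config$p, seeds[1L],
    interactions = config$interaction_scenario != "none",
    interaction_strength = config$interaction_strength,
    noise_sd = config$noise_sd, outcome_type = config$outcome_type,
    binary_scale = config$binary_scale
  )

  set.seed(seeds[2L])
  low_train <- sample.int(K, config$n_low_train)
  l_train <- ifelse(seq_len(K) %in% low_train, config$l_low, config$l_high)
  n_int <- switch(config$interaction_scenario, none = c(0L, 0L),
                  two_train_two_test = c(2L, 2L), six_train_two_test = c(6L, 2L))
  int_train <- if (n_int[1L]) sample.int(K, n_int[1L]) else integer(0)
  int_val <- if (n_int[2L]) sample.int(V, n_int[2L]) else integer(0)

  roles <- c(rep("train", K), rep("validate", V))
  ids <- c(paste0("study", seq_len(K)), paste0("val", seq_len(V)))
  l_all <- c(l_train, rep(config$l_validate, V))
  has_int <- c(seq_len(K) %in% int_train, seq_len(V) %in% int_val)

  feat_seeds <- seeds[4L + seq_len(K + V)]
  coef_seeds <- seeds[4L + K + V + seq_len(K + V)]
  outcome_seeds <- seeds[4L + 2L * (K + V) + seq_len(K + V)]

  features <- vector("list", K + V)
  if (config$mode == "multi_study") {
    for (i in seq_len(K + V)) {
      features[[i]] <- sample_features(config$feature_source, config$n[i],
                                       config$p, feat_seeds[i])
    }
  } else if (config$mode == "repeated_single_study") {
    shared <- sample_features(config$feature_source, config$n[1L], config$p,
                              feat_seeds[1L])
    for (i in seq_len(K)) features[[i]] <- shared
    for (i in K + seq_len(V)) {
      features[[i]] <- sample_features(config$feature_source, config$n[i],
                                       config$p, feat_seeds[i])
    }
  } else { # pseudo_split: shuffle one source matrix into 5 equal parts
    src <- sample_features(config$feature_source, config$pseudo_n_source,
                           config$p, feat_seeds[1L])
    set.seed(seeds[3L])
    perm <- sample.int(nrow(src))
    size <- nrow(src) %/% 5L
    bounds <- c(seq(0L, by = size, length.out = 5L), nrow(src))
    for (i in seq_len(5L)) {
      rows <- perm[(bounds[i] + 1L):bounds[i + 1L]]
      features[[i]] <- src[rows, , drop = FALSE]
    }
  }

  studies <- vector("list", K + V)
  study_models <- vector("list", K + V)
  for (i in seq_len(K + V)) {
    pm <- perturb_coefficients(model, l_all[i], coef_seeds[i])
    if (!has_int[i] && length(pm$interaction_coef)) {
      pm$interaction_coef <- rep(0, length(pm$interaction_coef))
    }
    set.seed(outcome_seeds[i])
    y <- generate_outcome(features[[i]], pm)
    studies[[i]] <- ms_study(ids[i], features[[i]], y, roles[i])
    study_models[[i]] <- pm
  }
  names(study_models) <- ids

  structure(
    list(collection = ms_collection(studies), model = model,
         study_models = study_models,
         meta = data.frame(study_id = ids, role = roles, l = l_all,
                           has_interactions = has_int,
                           n = vapply(studies, function(s) nrow(s$features), integer(1)),
                           stringsAsFactors = FALSE)),
    class = "ms_simulation"
  )
}

#' @export
print.ms_simulation <- function(x, ...) {
  cat(sprintf("<ms_simulation> %d train + %d validation studies, p = %d, %d interaction terms\n",
              x$collection$K, x$collection$V, x$model$p,
              length(x$model$interaction_coef)))
  invisible(x)
}
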