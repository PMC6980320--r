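#' Sample a feature matrix
#'
#' Draws study feature vectors either from a block-correlated multivariate
#' normal (an analytic stand-in for gene-expression covariance) or by
#' resampling rows of a user-supplied source matrix, which preserves the
#' source's marginal distributions and covariances.
#'
#' @param source_spec A list describing the feature source. Either
#'   `list(type = "synthetic_mvn", block_size =, rho =)` with features grouped
#'   into blocks of `block_size` (default 10) having within-block correlation
#'   `rho` (default 0.3, must satisfy `-1/(block_size-1) < rho < 1` for a
#'   positive-definite covariance), or `list(type = "resample", matrix =)`
#'   whose rows are drawn with replacement and restricted to `p` randomly
#'   chosen columns.
#' @param n Number of samples (>= 2).
#' @param p Number of features (>= 10).
#' @param seed Integer seed.
#'
#' @return An `n x p` numeric matrix with no missing values.
#' @export
sample_features <- function(source_spec, n, p, seed) {
  if (p < 10L) stop("'p' must be at least 10")
  if (n < 2L) stop("'n' must be at least 2")
  type <- source_spec$type %||% "synthetic_mvn"
  set.seed(seed)
  if (type == "synthetic_mvn") {
    b <- as.integer(source_spec$block_size %||% 10L)
    rho <- source_spec$rho %||% 0.3
    if (b < 1L) stop("'block_size' must be positive")
    if (rho >= 1 || (b > 1L && rho <= -1 / (b - 1))) {
      stop("within-block correlation does not give a positive-definite covariance")
    }
    # equicorrelated block: x = sqrt(rho) z_block + sqrt(1-rho) eps
    n_blocks <- ceiling(p / b)
    block_id <- rep(seq_len(n_blocks), each = b)[seq_len(p)]
    z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    eps <- matrix(stats::rnorm(n * p), n, p)
    x <- sqrt(max(rho, 0)) * z[, block_id, drop = FALSE] + sqrt(1 - max(rho, 0)) * eps
    if (rho < 0) { # negative rho: fall back to explicit Cholesky per block
      sigma <- diag(1 - rho, b) + matrix(rho, b, b)
      ch <- chol(sigma)
      x <- eps
      for (g in seq_len(n_blocks)) {
        cols <- which(block_id == g)
        x[, cols] <- matrix(stats::rnorm(n * length(cols)), n) %*%
          ch[seq_along(cols), seq_along(cols)]
      }
    }
    colnames(x) <- paste0("f", seq_len(p))
    x
  } else if (type == "resample") {
    src <- as.matrix(source_spec$matrix)
    if (p > ncol(src)) stop("'p' exceeds the source matrix column count")
    rows <- sample.int(nrow(src), n, replace = TRUE)
    cols <- sample.int(ncol(src), p)
    out <- src[rows, cols, drop = FALSE]
    colnames(out) <- paste0("f", seq_len(p))
    rownames(out) <- NULL
    out
  } else {
    stop("unknown feature source type: ", type)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a generative model for the outcome
#'
#' Chooses 10 of the `p` features as the "true" variables of a linear
#' data-generating model. Each true coefficient is drawn uniformly from
#' `[-5, -0.5] U [0.5, 5]` (each half with probability 1/2), so every true
#' variable has a bounded-away-from-zero contribution. When interactions are
#' enabled, 3 of the 10 true variables are selected and each of their 3
#' pairwise products enters the model with coefficient
#' `interaction_strength` times a random sign.
#'
#' @param p Total feature count (>= 10).
#' @param seed Integer seed.
#' @param interactions Logical; include interaction terms in the model?
#' @param interaction_strength Nonnegative magnitude of each interaction
#'   coefficient.
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   continuous outcomes (default 1).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param binary_scale Divisor applied to the standardized linear predictor
#'   before the logistic link (binary outcomes only; larger values flatten
#'   the probabilities toward 1/2).
#'
#' @return An object of class `gen_model`: fields `p`, `true_idx` (10 feature
#'   indices), `coef` (length 10), `interaction_idx` (0 or 3 indices),
#'   `interaction_pairs` (3 x 2 index matrix or NULL), `interaction_coef`
#'   (length 3 or 0), `noise_sd`, `outcome_type`, `binary_scale`.
#' @export
draw_generative_model <- function(p, seed, interactions = FALSE,
                                  interaction_strength = 2, noise_sd = 1,
                                  outcome_type = c("continuous", "binary"),
                                  binary_scale = 1) {
  outcome_type <- match.arg(outcome_type)
  if (p < 10L) stop("'p' must be at least 10")
  if (interaction_strength < 0) stop("'interaction_strength' must be nonnegative")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  set.seed(seed)
  true_idx <- sort(sample.int(p, 10L))
  coef <- sample(c(-1, 1), 10L, replace = TRUE) * stats::runif(10L, 0.5, 5)
  if (interactions) {
    interaction_idx <- sort(sample(true_idx, 3L))
    interaction_pairs <- t(utils::combn(interaction_idx, 2L))
    interaction_coef <- interaction_strength * sample(c(-1, 1), 3L, replace = TRUE)
  } else {
    interaction_idx <- integer(0)
    interaction_pairs <- NULL
    interaction_coef <- numeric(0)
  }
  structure(
    list(p = as.integer(p), true_idx = true_idx, coef = coef,
         interaction_idx = interaction_idx,
         interaction_pairs = interaction_pairs,
         interaction_coef = interaction_coef,
         noise_sd = noise_sd, outcome_type = outcome_type,
         binary_scale = binary_scale),
    class = "gen_model"
  )
}

#' @export
print.gen_model <- function(x, ...) {
  cat(sprintf("<gen_model> p = %d, 10 true variables, %d interaction terms, %s outcome\n",
              x$p, length(x$interaction_coef), x$outcome_type))
  invisible(x)
}

#' Perturb model coefficients for one study
#'
#' Applies feature-effect heterogeneity: each coefficient (main effects and,
#' when present, interaction coefficients) is independently redrawn uniformly
#' from `[c - l, c + l]` around its base value `c`. One draw per study, not
#' per sample.
#'
#' @param model A [draw_generative_model()] object.
#' @param l Nonnegative heterogeneity level (half-width of the perturbation
#'   window).
#' @param seed Integer seed.
#'
#' @return A `gen_model` with `coef` and `interaction_coef` replaced by their
#'   perturbed values.
#' @export
perturb_coefficients <- function(model, l, seed) {
  stopifnot(inherits(model, "gen_model"))
  if (l < 0) stop("heterogeneity level 'l' must be nonnegative")
  set.seed(seed)
  model$coef <- stats::runif(length(model$coef), model$coef - l, model$coef + l)
  if (length(model$interaction_coef)) {
    model$interaction_coef <- stats::runif(length(model$interaction_coef),
                                           model$interaction_coef - l,
                                           model$interaction_coef + l)
  }
  model
}

# linear predictor: main effects on the true variables plus the pairwise
# interaction products, using the model's (possibly perturbed) coefficients
linear_predictor <- function(features, model) {
  if (ncol(features) < max(model$true_idx)) {
    stop("'features' has fewer columns than the model's largest true index")
  }
  lp <- drop(features[, model$true_idx, drop = FALSE] %*% model$coef)
  if (length(model$interaction_coef)) {
    for (j in seq_along(model$interaction_coef)) {
      a <- model$interaction_pairs[j, 1L]
      b <- model$interaction_pairs[j, 2L]
      lp <- lp + model$interaction_coef[j] * features[, a] * features[, b]
    }
  }
  lp
}

#' Generate outcomes from a (perturbed) generative model
#'
#' Continuous outcomes are the linear predictor (main effects plus any
#' interaction products) plus Gaussian noise with sd `model$noise_sd`.
#' Binary outcomes are Bernoulli draws with success probability
#' `plogis(z / binary_scale)` where `z` is the centered, unit-variance
#' standardization of the linear predictor.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param features Numeric matrix with at least `max(true_idx)` columns.
#' @param model A (typically perturbed) `gen_model`.
#'
#' @return Numeric outcome vector of length `nrow(features)` (0/1 for binary).
#' @export
generate_outcome <- function(features, model) {
  stopifnot(inherits(model, "gen_model"))
  lp <- linear_predictor(features, model)
  if (model$outcome_type == "continuous") {
    lp + stats::rnorm(length(lp), sd = model$noise_sd)
  } else {
    s <- stats::sd(lp)
    z <- if (is.na(s) || s == 0) lp - mean(lp) else (lp - mean(lp)) / s
    stats::rbinom(length(lp), 1L, stats::plogis(z / model$binary_scale))
  }
}

#' Share of outcome variance explained by interaction terms
#'
#' Decomposes the generative signal on a given feature matrix into main-effect
#' and interaction parts and returns the fraction of total outcome variance
#' (including the noise variance) attributable to the interaction terms:
#' `var(interaction part) / (var(linear predictor) + noise_sd^2)`.
#' Exactly 0 when the model has no interactions or strength 0.
#'
#' @param features Feature matrix.
#' @param model A `gen_model`.
#' @return A fraction in `[0, 1]`.
#' @export
interaction_variance_share <- function(features, model) {
  stopifnot(inherits(model, "gen_model"))
  if (!length(model$interaction_coef) || all(model$interaction_coef == 0)) return(0)
  lp <- linear_predictor(features, model)
  int <- numeric(nrow(features))
  for (j in seq_along(model$interaction_coef)) {
    a <- model$interaction_pairs[j, 1L]
    b <- model$interaction_pairs[j, 2L]
    int <- int + model$interaction_coef[j] * features[, a] * features[, b]
  }
  stats::var(int) / (stats::var(lp) + model$noise_sd^2)
}
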