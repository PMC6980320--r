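test_that("synthetic MVN features honor the block-correlation spec", {
  spec0 <- list(type = "synthetic_mvn", block_size = 5L, rho = 0)
  X <- sample_features(spec0, n = 2000L, p = 10L, seed = 4L)
  expect_equal(dim(X), c(2000L, 10L))
  expect_false(anyNA(X))
  r <- cor(X)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  spec6 <- list(type = "synthetic_mvn", block_size = 5L, rho = 0.6)
  X6 <- sample_features(spec6, n = 2000L, p = 10L, seed = 4L)
  r6 <- cor(X6)
  within <- c(r6[1:5, 1:5][upper.tri(diag(5))], r6[6:10, 6:10][upper.tri(diag(5))])
  expect_lt(abs(mean(within) - 0.6), 0.05)
  between <- r6[1:5, 6:10]
  expect_lt(max(abs(between)), 0.15)

  bad <- list(type = "synthetic_mvn", block_size = 5L, rho = -0.5)
  expect_error(sample_features(bad, 10L, 10L, 1L), "positive-definite")
})

test_that("resampled features are rows of the source matrix", {
  src <- matrix(seq_len(40), nrow = 4) # 4 x 10
  spec <- list(type = "resample", matrix = src)
  X <- sample_features(spec, n = 25L, p = 10L, seed = 9L)
  expect_equal(dim(X), c(25L, 10L))
  # every output row must be a permutation-consistent copy of some source row:
  # sort each row since columns are randomly reordered
  src_sorted <- t(apply(src, 1L, sort))
  out_sorted <- t(apply(X, 1L, sort))
  expect_true(all(apply(out_sorted, 1L, function(r) {
    any(apply(src_sorted, 1L, function(s) all(s == r)))
  })))
  expect_error(sample_features(spec, 5L, 11L, 1L), "exceeds")
})

test_that("generative model draws respect the coefficient support and symmetry", {
  for (seed in 1:5) {
    gm <- draw_generative_model(100L, seed)
    expect_length(gm$true_idx, 10L)
    expect_false(anyDuplicated(gm$true_idx) > 0)
    expect_true(all(abs(gm$coef) >= 0.5 & abs(gm$coef) <= 5))
    expect_length(gm$interaction_coef, 0L)
  }
  gm_int <- draw_generative_model(100L, 3L, interactions = TRUE,
                                  interaction_strength = 1.5)
  expect_length(gm_int$interaction_idx, 3L)
  expect_true(all(gm_int$interaction_idx %in% gm_int$true_idx))
  expect_equal(abs(gm_int$interaction_coef), rep(1.5, 3L))
  expect_error(draw_generative_model(9L, 1L), "at least 10")

  # Monte-Carlo sign symmetry of a single coefficient
  signs <- vapply(1:10000, function(s) {
    draw_generative_model(10L, s)$coef[1L] > 0
  }, logical(1))
  expect_lt(abs(mean(signs) - 0.5), 0.02)
})

test_that("coefficient perturbation is uniform on [c - l, c + l]", {
  gm <- draw_generative_model(20L, 7L, interactions = TRUE)
  expect_identical(perturb_coefficients(gm, 0, 1L)$coef, gm$coef)
  expect_error(perturb_coefficients(gm, -1, 1L), "nonnegative")

  # support over many draws, main and interaction coefficients alike
  for (s in 1:1000) {
    pm <- perturb_coefficients(gm, 1, s)
    expect_true(all(pm$coef >= gm$coef - 1 & pm$coef <= gm$coef + 1))
    if (s <= 50) {
      expect_true(all(pm$interaction_coef >= gm$interaction_coef - 1 &
                        pm$interaction_coef <= gm$interaction_coef + 1))
    }
  }

  # moments of Uniform(c - 1, c + 1): mean c, variance 1/3
  gm1 <- draw_generative_model(10L, 1L)
  draws <- vapply(1:10000, function(s) {
    perturb_coefficients(gm1, 1, s)$coef[1L]
  }, numeric(1))
  expect_lt(abs(mean(draws) - gm1$coef[1L]), 0.03)
  expect_lt(abs(var(draws) - 1 / 3) / (1 / 3), 0.1)
})

test_that("outcomes follow the linear-plus-interaction model", {
  gm <- draw_generative_model(12L, 2L)
  gm$coef[] <- 0
  gm$noise_sd <- 0
  X <- matrix(rnorm(60), 5L, 12L)
  expect_equal(generate_outcome(X, gm), rep(0, 5L))

  gm2 <- gm
  gm2$coef[] <- 0
  gm2$coef[3L] <- 2
  expect_equal(generate_outcome(X, gm2), 2 * X[, gm2$true_idx[3L]])

  gm_int <- draw_generative_model(12L, 5L, interactions = TRUE,
                                  interaction_strength = 2, noise_sd = 0)
  lp_manual <- drop(X[, gm_int$true_idx] %*% gm_int$coef)
  for (j in 1:3) {
    lp_manual <- lp_manual + gm_int$interaction_coef[j] *
      X[, gm_int$interaction_pairs[j, 1L]] * X[, gm_int$interaction_pairs[j, 2L]]
  }
  expect_equal(generate_outcome(X, gm_int), lp_manual)
  expect_error(generate_outcome(X[, 1:3], gm), "fewer columns")
})

test_that("interaction variance share is zero without interactions and grows with strength", {
  cfg <- small_config()
  X <- sample_features(cfg$feature_source, 200L, cfg$p, 8L)
  gm0 <- draw_generative_model(cfg$p, 3L, interactions = TRUE,
                               interaction_strength = 0)
  expect_identical(interaction_variance_share(X, gm0), 0)
  shares <- vapply(c(0.5, 1, 2, 4), function(s) {
    gm <- draw_generative_model(cfg$p, 3L, interactions = TRUE,
                                interaction_strength = s)
    interaction_variance_share(X, gm)
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_true(all(shares >= 0 & shares <= 1))
})

test_that("binary outcomes are Bernoulli with logistic probabilities", {
  gm <- draw_generative_model(12L, 2L, outcome_type = "binary")
  X <- matrix(rnorm(12 * 500), 500L, 12L)
  set.seed(1)
  y <- generate_outcome(X, gm)
  expect_true(all(y %in% c(0, 1)))
  # standardized linear predictor keeps classes roughly balanced
  expect_gt(mean(y), 0.2)
  expect_lt(mean(y), 0.8)
})

test_that("build_collection realizes modes, levels and interaction placement", {
  cfg <- small_config(interaction_scenario = "two_train_two_test")
  sim <- build_collection(cfg, 5L)
  expect_s3_class(sim$collection, "ms_collection")
  expect_equal(sim$collection$K, 3L)
  expect_equal(sim$collection$V, 2L)
  expect_equal(sum(sim$meta$has_interactions[sim$meta$role == "train"]), 2L)
  expect_equal(sum(sim$meta$has_interactions[sim$meta$role == "validate"]), 2L)
  # non-interaction studies have zeroed interaction coefficients
  off <- sim$meta$study_id[!sim$meta$has_interactions]
  for (id in off) expect_true(all(sim$study_models[[id]]$interaction_coef == 0))
  # perturbed coefficients stay inside the study's window
  for (i in seq_len(nrow(sim$meta))) {
    pm <- sim$study_models[[sim$meta$study_id[i]]]
    l <- sim$meta$l[i]
    expect_true(all(abs(pm$coef - sim$model$coef) <= l + 1e-12))
  }

  rep_cfg <- small_config(mode = "repeated_single_study")
  rsim <- build_collection(rep_cfg, 5L)
  tr <- train_studies(rsim$collection)
  for (k in 2:length(tr)) expect_identical(tr[[k]]$features, tr[[1L]]$features)

  ps_cfg <- small_config(mode = "pseudo_split", pseudo_n_source = 103L)
  psim <- build_collection(ps_cfg, 5L)
  expect_equal(psim$collection$K, 4L)
  expect_equal(psim$collection$V, 1L)
  sizes <- vapply(psim$collection$studies, function(s) nrow(s$features), integer(1))
  expect_equal(sizes, c(20L, 20L, 20L, 20L, 23L)) # remainder goes to the last part

  zero_cfg <- small_config(l_low = 0, l_high = 0, l_validate = 0)
  zsim <- build_collection(zero_cfg, 5L)
  coefs <- vapply(zsim$study_models, function(m) m$coef, numeric(10L))
  expect_true(all(apply(coefs, 1L, function(r) max(r) - min(r)) < 1e-12))
})

test_that("collections and scenario configs round-trip through text files", {
  sim <- build_collection(small_config(), 3L)
  dir <- withr::local_tempdir()
  write_collection(sim$collection, dir)
  back <- read_collection(dir)
  expect_equal(back$K, sim$collection$K)
  expect_equal(back$studies[[1L]]$features, sim$collection$studies[[1L]]$features,
               tolerance = 1e-8)
  expect_equal(back$studies[[4L]]$outcome, sim$collection$studies[[4L]]$outcome,
               tolerance = 1e-8)

  cfg_path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(K = 4, V = 2, n = 30, p = 15, l_high = 2,
                        interaction_scenario = "two_train_two_test"), cfg_path)
  cfg <- read_scenario_config(cfg_path)
  expect_equal(cfg$K, 4L)
  expect_equal(cfg$l_validate, 1) # default rule: half the high level
  yaml::write_yaml(list(K = 4, nonsense = 1), cfg_path)
  expect_error(read_scenario_config(cfg_path), "unknown config keys")
})
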