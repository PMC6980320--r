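test_that("the stack matrix has one row per training observation, one column per component", {
  coll <- step_collection()
  tr <- train_studies(coll)
  forests <- lapply(seq_along(tr), function(k) {
    train_forest(tr[[k]], m = 4L, seed = k)
  })
  stack <- build_stack_matrix(forests, coll)
  N <- sum(vapply(tr, function(s) nrow(s$features), integer(1)))
  expect_equal(dim(stack$T), c(N, 2L))
  expect_equal(length(stack$Y), N)
  expect_equal(stack$row_study, rep(c("s1", "s2"), each = 30L))
  expect_false(anyNA(stack$T))
  # column k holds forest k's predictions on the stacked studies
  man <- c(predict(forests[[2L]], tr[[1L]]$features),
           predict(forests[[2L]], tr[[2L]]$features))
  expect_equal(unname(stack$T[, 2L]), man)

  trees <- unlist(lapply(forests, extract_trees), recursive = FALSE)
  tstack <- build_stack_matrix(trees, coll)
  expect_equal(ncol(tstack$T), 8L) # K * m columns
  expect_equal(tstack$col_component[1:4], paste0("s1.", 1:4))
  # tree columns average back to the forest column
  expect_equal(rowMeans(tstack$T[, 1:4]), unname(stack$T[, 1L]), tolerance = 1e-12)
})

test_that("own-study rows can use out-of-bag forest predictions", {
  coll <- step_collection()
  tr <- train_studies(coll)
  forests <- lapply(seq_along(tr), function(k) train_forest(tr[[k]], m = 10L, seed = k))
  plain <- build_stack_matrix(forests, coll)
  oob <- build_stack_matrix(forests, coll, oob_own_study = TRUE)
  # own-study block changes, cross-study blocks do not
  expect_false(isTRUE(all.equal(plain$T[1:30, 1L], oob$T[1:30, 1L])))
  expect_equal(plain$T[31:60, 1L], oob$T[31:60, 1L])
  expect_equal(plain$T[1:30, 2L], oob$T[1:30, 2L])
})

test_that("stacking weights are nonnegative and reward a perfect predictor", {
  set.seed(3)
  N <- 60L
  Y <- rnorm(N)
  T_ <- cbind(perfect = Y, noise1 = rnorm(N), noise2 = rnorm(N))
  stack <- structure(list(T = T_, Y = Y, row_study = rep("s", N),
                          col_component = colnames(T_), level = "forest"),
                     class = "stack_matrix")
  fit <- solve_nn_ridge(stack, lambda_grid = 1e-8, seed = 1L)
  expect_true(all(fit$w_stack >= 0))
  expect_equal(unname(fit$w_stack["perfect"]), 1, tolerance = 1e-6)
  expect_lt(max(abs(fit$w_stack[c("noise1", "noise2")])), 1e-6)
  expect_lt(abs(fit$intercept), 1e-6)
})

test_that("the solver matches the brute-force QP oracle at fixed penalties", {
  lambdas <- c(0.01, 0.1, 1, 10, 100)
  for (seed in 1:10) {
    stack <- random_stack(N = 30L, J = 4L, seed = seed)
    for (lam in lambdas) {
      fit <- solve_nn_ridge(stack, lambda_grid = lam, standardize = FALSE)
      oracle <- oracle_nn_ridge(stack$T, stack$Y, lam)
      got <- nn_ridge_objective(stack$T, stack$Y, unname(fit$w_stack),
                                fit$intercept, lam)
      expect_lt(abs(got - oracle$value) / max(abs(oracle$value), 1e-12), 1e-6)
    }
  }
})

test_that("the solver agrees with an independent Lawson-Hanson implementation", {
  skip_if_not_installed("pracma")
  for (seed in 1:5) {
    stack <- random_stack(N = 40L, J = 5L, seed = seed)
    lam <- 0.5
    fit <- solve_nn_ridge(stack, lambda_grid = lam, standardize = FALSE,
                          intercept = FALSE)
    # ridge-augmented NNLS: min ||[T; sqrt(lam) I] w - [Y; 0]||, w >= 0
    A <- rbind(stack$T, sqrt(lam) * diag(ncol(stack$T)))
    b <- c(stack$Y, numeric(ncol(stack$T)))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(unname(fit$w_stack), ref, tolerance = 1e-8)
  }
})

test_that("ridge shrinkage is monotone and the small-penalty limit is NNLS", {
  skip_if_not_installed("pracma")
  stack <- random_stack(N = 50L, J = 5L, seed = 7L)
  grid <- 10^seq(-4, 3, length.out = 15L)
  norms <- vapply(grid, function(lam) {
    sum(solve_nn_ridge(stack, lambda_grid = lam, standardize = FALSE,
                       intercept = FALSE)$w_stack^2)
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  nnls_ref <- pracma::lsqnonneg(stack$T, stack$Y)$x
  tiny <- solve_nn_ridge(stack, lambda_grid = 1e-10, standardize = FALSE,
                         intercept = FALSE)
  expect_equal(unname(tiny$w_stack), nnls_ref, tolerance = 1e-5)
})

test_that("cross-validation selects a penalty from the grid deterministically", {
  stack <- random_stack(N = 80L, J = 4L, seed = 2L)
  grid <- 10^seq(2, -4, length.out = 20L)
  fit1 <- solve_nn_ridge(stack, lambda_grid = grid, cv_folds = 5L, seed = 11L)
  fit2 <- solve_nn_ridge(stack, lambda_grid = grid, cv_folds = 5L, seed = 11L)
  expect_identical(fit1$w_stack, fit2$w_stack)
  expect_true(fit1$lambda %in% grid)
  expect_equal(nrow(fit1$cv_curve), 20L)
  expect_true(all(fit1$cv_curve$cv_error > 0))
  # study-level folds also run (2 studies -> capped folds)
  stack$row_study <- rep(c("a", "b"), each = 40L)
  fit3 <- solve_nn_ridge(stack, lambda_grid = grid, cv_folds = 5L,
                         fold_type = "study", seed = 1L)
  expect_true(all(fit3$w_stack >= 0))
  expect_error(solve_nn_ridge(stack, lambda_grid = grid, cv_folds = 100L),
               "cv_folds")
})

test_that("degenerate stacking inputs are handled as documented", {
  # all-constant outcome: intercept = mean(Y), all weights 0
  stack <- random_stack(N = 30L, J = 3L, seed = 4L)
  stack$Y <- rep(2.5, 30L)
  fit <- solve_nn_ridge(stack, lambda_grid = c(1, 10), cv_folds = 3L)
  expect_equal(unname(fit$w_stack), rep(0, 3L))
  expect_equal(fit$intercept, 2.5)

  # constant column gets weight 0 with a warning
  stack2 <- random_stack(N = 30L, J = 3L, seed = 5L)
  stack2$T[, 2L] <- 0
  expect_warning(fit2 <- solve_nn_ridge(stack2, lambda_grid = 1), "weight 0")
  expect_equal(unname(fit2$w_stack[2L]), 0)

  # a component predicting the constant 5 yields an all-5 column upstream
  coll <- step_collection()
  tr <- train_studies(coll)
  const <- ms_study("s1", tr[[1L]]$features, rep(5, 30L), "train")
  f_const <- train_forest(const, m = 2L, seed = 1L)
  f_real <- train_forest(tr[[2L]], m = 2L, seed = 2L)
  stack3 <- build_stack_matrix(list(f_const, f_real), coll)
  expect_equal(unname(stack3$T[, 1L]), rep(5, 60L))

  # lasso penalty variant stays nonnegative and shrinks harder to zero
  stack4 <- random_stack(N = 40L, J = 4L, seed = 6L)
  fl <- solve_nn_ridge(stack4, lambda_grid = 50, penalty = "lasso",
                       standardize = FALSE, intercept = FALSE)
  expect_true(all(fl$w_stack >= 0))
  fr <- solve_nn_ridge(stack4, lambda_grid = 50, penalty = "ridge",
                       standardize = FALSE, intercept = FALSE)
  expect_lte(sum(fl$w_stack > 1e-10), sum(fr$w_stack > 1e-10))
})

test_that("implied tree weights spread each forest weight over its trees", {
  w <- c(s1 = 0.1)
  expect_equal(unname(implied_tree_weights(w, 10L)), rep(0.01, 10L))
  w2 <- c(a = 0.3, b = 0)
  imp <- implied_tree_weights(w2, 4L)
  expect_length(imp, 8L)
  expect_equal(sum(imp), sum(w2))
  expect_named(imp, c(paste0("a.", 1:4), paste0("b.", 1:4)))
  # equal weighting of 100 trees corresponds to 0.01 per tree
  expect_equal(unname(implied_tree_weights(rep(0.1, 10L), 10L)),
               rep(0.01, 100L))
})

test_that("stack matrices and stacking fits round-trip through text files", {
  stack <- random_stack(N = 20L, J = 3L, seed = 9L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stack_matrix(stack, path)
  back <- read_stack_matrix(path)
  expect_equal(back$T, stack$T, tolerance = 1e-8)
  expect_equal(back$Y, stack$Y, tolerance = 1e-8)

  fit <- solve_nn_ridge(stack, lambda_grid = 10^seq(1, -2, length.out = 5L),
                        cv_folds = 4L, seed = 2L)
  fpath <- withr::local_tempfile(fileext = ".yaml")
  write_stacking_fit(fit, fpath)
  fback <- read_stacking_fit(fpath)
  expect_equal(fback$w_stack, fit$w_stack, tolerance = 1e-10)
  expect_equal(fback$lambda, fit$lambda)
  expect_equal(fback$cv_curve$cv_error, fit$cv_curve$cv_error, tolerance = 1e-10)
})
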