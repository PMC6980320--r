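# Shared fixtures and the brute-force QP oracle, all built in code.

# small scenario: quick to simulate and fit in unit tests
small_config <- function(...) {
  scenario_config(K = 3L, V = 2L, n = 40L, p = 12L,
                  feature_source = list(type = "synthetic_mvn",
                                        block_size = 4L, rho = 0.2),
                  n_iterations = 2L, ...)
}

# the baseline study conditions: K = 10 + V = 5 studies of 100 samples over
# p = 100 features, perturbation levels .25 / 1 in training and .4 in
# validation
baseline_config <- function(...) {
  scenario_config(K = 10L, V = 5L, n = 100L, p = 100L,
                  l_low = 0.25, l_high = 1, l_validate = 0.4, ...)
}

# deterministic two-study collection with a single informative feature
step_collection <- function(n = 30L, p = 10L, seed = 11L) {
  set.seed(seed)
  studies <- lapply(1:3, function(k) {
    X <- matrix(rnorm(n * p), n, p)
    y <- 2 * X[, 1] + rnorm(n, sd = 0.1)
    ms_study(paste0("s", k), X, y, if (k < 3) "train" else "validate")
  })
  ms_collection(studies)
}

# a fake extracted tree carrying only the fields tree_structure_metrics reads
fake_tree <- function(split_variables, tree_id = "fake.1") {
  structure(list(tree_id = tree_id, index = 1L, forest = NULL,
                 split_variables = as.integer(split_variables),
                 oob_indices = integer(0)),
            class = "study_tree")
}

# Brute-force oracle for  min_{w>=0, b0} ||Y - b0 - T w||^2 + lambda ||w||^2 :
# enumerate every candidate passive set, solve the equality-restricted ridge
# problem in closed form, keep the feasible solution with the lowest
# objective. Exact for convex QPs since the optimal passive set is among the
# subsets. Independent of the package's active-set path.
oracle_nn_ridge <- function(T_, Y, lambda, intercept = TRUE) {
  J <- ncol(T_)
  obj <- function(w, b0) sum((Y - b0 - drop(T_ %*% w))^2) + lambda * sum(w^2)
  best <- list(value = if (intercept) obj(numeric(J), mean(Y)) else obj(numeric(J), 0),
               w = numeric(J), b0 = if (intercept) mean(Y) else 0)
  for (mask in seq_len(2^J - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(J) - 1L)) > 0)
    A <- T_[, S, drop = FALSE]
    if (intercept) A <- cbind(1, A)
    pen <- diag(c(if (intercept) 0 else NULL, rep(lambda, length(S))),
                ncol(A), ncol(A))
    sol <- tryCatch(solve(crossprod(A) + pen, crossprod(A, Y)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    b0 <- if (intercept) sol[1] else 0
    wS <- if (intercept) sol[-1] else drop(sol)
    if (any(wS < 0)) next
    w <- numeric(J); w[S] <- wS
    val <- obj(w, b0)
    if (val < best$value) best <- list(value = val, w = w, b0 = b0)
  }
  best
}

# objective evaluated on a stacking fit (unstandardized scale)
nn_ridge_objective <- function(T_, Y, w, b0, lambda) {
  sum((Y - b0 - drop(T_ %*% w))^2) + lambda * sum(w^2)
}

# random small stacking instance with some signal
random_stack <- function(N, J, seed) {
  set.seed(seed)
  T_ <- matrix(rnorm(N * J), N, J)
  Y <- drop(T_ %*% runif(J, 0, 1)) + rnorm(N, sd = 0.5)
  structure(list(T = `colnames<-`(T_, paste0("c", seq_len(J))), Y = Y,
                 row_study = rep("s1", N),
                 col_component = paste0("c", seq_len(J)), level = "forest"),
            class = "stack_matrix")
}
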