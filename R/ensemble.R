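#' Fit a cross-study ensemble predictor
#'
#' Assembles one of the four comparator strategies from a training
#' collection:
#' \describe{
#'   \item{`merged`}{a single forest of `K * m` trees trained on the
#'     row-concatenation of all training studies, weight 1.}
#'   \item{`unweighted`}{K per-study forests, equal weights `1/K`,
#'     intercept 0.}
#'   \item{`weighting_forests`}{K per-study forests combined with
#'     non-negative ridge stacking weights and intercept.}
#'   \item{`weighting_trees`}{the `K * m` trees extracted from the per-study
#'     forests, each weighted individually by the same stacking method.}
#' }
#'
#' @param strategy One of `"merged"`, `"unweighted"`, `"weighting_forests"`,
#'   `"weighting_trees"`.
#' @param collection An [ms_collection()] (or an `ms_simulation`, whose
#'   collection is used).
#' @param m Trees per single-study forest (default 10). The merged forest
#'   gets `K * m` trees so every strategy holds the same total.
#' @param mtry Candidate variables per split; default `min(9, p)`.
#' @param seed Integer seed (forest training and stacking folds).
#' @param task `"regression"` or `"classification"`.
#' @param stacking List of arguments forwarded to [solve_nn_ridge()]
#'   (e.g. `lambda_grid`, `cv_folds`, `penalty`, `intercept`,
#'   `oob_own_study` for the stack matrix).
#'
#' @return An object of class `cs_ensemble`: `strategy`, `level`
#'   (`"forest"` or `"tree"`), `forests` (list of `study_forest`), `weights`
#'   (nonnegative, aligned to components: per forest at forest level, per
#'   tree in forest-then-tree order at tree level), `intercept`, `task`,
#'   `m`, `K`, and `stacking_fit` (NULL for merged/unweighted).
#' @export
fit_ensemble <- function(strategy = c("merged", "unweighted",
                                      "weighting_forests", "weighting_trees"),
                         collection, m = 10L, mtry = NULL, seed = 1L,
                         task = c("regression", "classification"),
                         stacking = list()) {
  strategy <- match.arg(strategy)
  task <- match.arg(task)
  if (inherits(collection, "ms_simulation")) collection <- collection$collection
  stopifnot(inherits(collection, "ms_collection"))
  tr <- train_studies(collection)
  K <- length(tr)
  if (strategy != "merged" && K < 2L) {
    stop("ensemble strategies other than 'merged' need at least 2 training studies")
  }
  seeds <- seed_stream(seed, K + 2L)

  if (strategy == "merged") {
    forest <- train_merged(collection, total_trees = K * m, mtry = mtry,
                           seed = seeds[K + 1L], task = task)
    return(new_cs_ensemble("merged", "forest", list(forest), weights = 1,
                           intercept = 0, task = task, m = K * m, K = K,
                           fit = NULL))
  }

  forests <- lapply(seq_len(K), function(k) {
    train_forest(tr[[k]], m = m, mtry = mtry, seed = seeds[k], task = task)
  })

  if (strategy == "unweighted") {
    return(new_cs_ensemble("unweighted", "forest", forests,
                           weights = rep(1 / K, K), intercept = 0,
                           task = task, m = m, K = K, fit = NULL))
  }

  oob_own <- isTRUE(stacking$oob_own_study)
  stacking$oob_own_study <- NULL
  components <- if (strategy == "weighting_forests") forests else {
    unlist(lapply(forests, extract_trees), recursive = FALSE)
  }
  stack <- build_stack_matrix(components, collection, oob_own_study = oob_own)
  args <- c(list(stack = stack), stacking)
  if (is.null(args$seed)) args$seed <- seeds[K + 2L]
  fit <- do.call(solve_nn_ridge, args)
  level <- if (strategy == "weighting_forests") "forest" else "tree"
  new_cs_ensemble(strategy, level, forests, weights = unname(fit$w_stack),
                  intercept = fit$intercept, task = task, m = m, K = K,
                  fit = fit)
}

new_cs_ensemble <- function(strategy, level, forests, weights, intercept,
                            task, m, K, fit) {
  structure(
    list(strategy = strategy, level = level, forests = forests,
         weights = weights, intercept = intercept, task = task,
         m = as.integer(m), K = as.integer(K), stacking_fit = fit),
    class = "cs_ensemble"
  )
}

#' @export
print.cs_ensemble <- function(x, ...) {
  cat(sprintf("<cs_ensemble> %s: %d %s-level component(s), intercept = %.4g, %s\n",
              x$strategy, length(x$weights), x$level, x$intercept, x$task))
  invisible(x)
}

#' Number of weighted components of an ensemble
#'
#' One for `merged`, K forests for `unweighted`/`weighting_forests`,
#' `K * m` trees for `weighting_trees`.
#'
#' @param ensemble A `cs_ensemble`.
#' @return Integer count, equal to `length(ensemble$weights)`.
#' @export
n_components <- function(ensemble) {
  stopifnot(inherits(ensemble, "cs_ensemble"))
  length(ensemble$weights)
}

#' Tree-level weights of any ensemble
#'
#' Expresses every strategy on the common per-tree scale: `merged` and
#' `unweighted` spread their equal weighting over all trees (1/(K*m) each),
#' `weighting_forests` divides each forest weight by `m` (the implied tree
#' weights), and `weighting_trees` returns its direct weights.
#'
#' @param ensemble A `cs_ensemble`.
#' @return Named numeric vector, one entry per tree in forest-then-tree order.
#' @export
tree_level_weights <- function(ensemble) {
  stopifnot(inherits(ensemble, "cs_ensemble"))
  if (ensemble$strategy == "merged") {
    f <- ensemble$forests[[1L]]
    return(stats::setNames(rep(1 / f$m, f$m),
                           paste(f$study_id, seq_len(f$m), sep = ".")))
  }
  ids <- unlist(lapply(ensemble$forests, function(f) {
    paste(f$study_id, seq_len(f$m), sep = ".")
  }))
  w <- if (ensemble$level == "forest") {
    rep(ensemble$weights / ensemble$m, each = ensemble$m)
  } else {
    ensemble$weights
  }
  stats::setNames(w, ids)
}

#' Serialize / restore a fitted ensemble
#'
#' Writes a directory bundling the ensemble's configuration (strategy,
#' weights, intercept, task), each component forest (via [write_forest()];
#' forests are retrained from their stored data and seed on read, which
#' reproduces them exactly), and the stacking fit when present.
#'
#' @param ensemble A `cs_ensemble`.
#' @param dir Output directory, created if needed.
#' @return `write_ensemble` invisibly returns `dir`; `read_ensemble`
#'   returns a `cs_ensemble` whose predictions match the original.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "cs_ensemble"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(ensemble$forests, function(f) {
    fn <- paste0("forest_", f$study_id, ".tsv")
    write_forest(f, file.path(dir, fn))
    fn
  }, character(1))
  meta <- list(strategy = ensemble$strategy, level = ensemble$level,
               weights = ensemble$weights, intercept = ensemble$intercept,
               task = ensemble$task, m = ensemble$m, K = ensemble$K,
               forest_files = unname(files),
               has_stacking_fit = !is.null(ensemble$stacking_fit))
  yaml::write_yaml(meta, file.path(dir, "ensemble.yaml"), precision = 17L)
  if (!is.null(ensemble$stacking_fit)) {
    write_stacking_fit(ensemble$stacking_fit, file.path(dir, "stacking.yaml"))
  }
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "ensemble.yaml"))
  forests <- lapply(meta$forest_files, function(fn) {
    read_forest(file.path(dir, fn))
  })
  fit <- if (isTRUE(meta$has_stacking_fit)) {
    read_stacking_fit(file.path(dir, "stacking.yaml"))
  }
  new_cs_ensemble(meta$strategy, meta$level, forests,
                  weights = as.numeric(meta$weights),
                  intercept = meta$intercept, task = meta$task,
                  m = meta$m, K = meta$K, fit = fit)
}

#' Predict with a cross-study ensemble
#'
#' Returns `intercept + sum_j w_j * component_j(X)`. Classification outputs
#' are clipped to `[1e-15, 1 - 1e-15]` so log loss is always finite.
#'
#' @param object A `cs_ensemble`.
#' @param X Feature matrix with the training feature dimension.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.cs_ensemble <- function(object, X, ...) {
  X <- as.matrix(X)
  pred <- rep(object$intercept, nrow(X))
  if (object$level == "forest") {
    for (k in seq_along(object$forests)) {
      if (object$weights[k] != 0) {
        pred <- pred + object$weights[k] * predict(object$forests[[k]], X)
      }
    }
  } else {
    off <- 0L
    for (f in object$forests) {
      w <- object$weights[off + seq_len(f$m)]
      if (any(w != 0)) pred <- pred + drop(predict_tree_matrix(f, X) %*% w)
      off <- off + f$m
    }
  }
  if (object$task == "classification") {
    pred <- pmin(pmax(pred, 1e-15), 1 - 1e-15)
  }
  pred
}
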