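#' Build the cross-study stacked prediction matrix
#'
#' Column j of `T` holds component j's predictions on every training-study
#' observation, studies stacked in collection order; `Y` stacks the true
#' outcomes in the same row order. Components are whole per-study forests
#' (J = K columns) or individually extracted trees (J = K x m columns). By
#' default each component's predictions on its own source study are ordinary
#' refit predictions; `oob_own_study = TRUE` substitutes out-of-bag
#' predictions on own-study rows where available (rows in-bag for every tree
#' keep the refit prediction).
#'
#' @param components List of `study_forest` or `study_tree` objects, all
#'   trained.
#' @param collection The [ms_collection()] whose training studies form the
#'   rows.
#' @param oob_own_study Substitute out-of-bag predictions for own-study rows.
#'
#' @return An object of class `stack_matrix`: `T` (N x J matrix), `Y`
#'   (length N), `row_study` (study id per row), `col_component` (component
#'   id per column), `level` (`"forest"` or `"tree"`).
#' @export
build_stack_matrix <- function(components, collection, oob_own_study = FALSE) {
  stopifnot(inherits(collection, "ms_collection"))
  if (!length(components)) stop("'components' is empty")
  is_forest <- vapply(components, inherits, logical(1), "study_forest")
  is_tree <- vapply(components, inherits, logical(1), "study_tree")
  if (!all(is_forest) && !all(is_tree)) {
    stop("'components' must be all study_forest or all study_tree objects")
  }
  level <- if (all(is_forest)) "forest" else "tree"
  tr <- train_studies(collection)
  if (!length(tr)) stop("collection has no training studies")

  # group tree components by their parent forest for batched prediction
  if (level == "tree") {
    fkey <- vapply(components, function(t) t$forest$study_id, character(1))
    forests <- components[!duplicated(fkey)]
    forests <- lapply(forests, `[[`, "forest")
    names(forests) <- unique(fkey)
    col_ids <- vapply(components, `[[`, character(1), "tree_id")
  } else {
    forests <- components
    names(forests) <- vapply(components, `[[`, character(1), "study_id")
    col_ids <- names(forests)
  }

  blocks <- vector("list", length(tr))
  for (i in seq_along(tr)) {
    s <- tr[[i]]
    if (level == "forest") {
      cols <- lapply(components, function(f) {
        pr <- predict(f, s$features)
        if (oob_own_study && f$study_id == s$study_id) {
          pr <- oob_forest_prediction(f, fallback = pr)
        }
        pr
      })
      blocks[[i]] <- do.call(cbind, cols)
    } else {
      # a single tree has no alternative out-of-bag prediction, so the
      # oob_own_study substitution only applies at the forest level
      mats <- lapply(forests, function(f) predict_tree_matrix(f, s$features))
      full <- do.call(cbind, mats)
      idx <- match(col_ids, unlist(lapply(names(forests), function(id) {
        paste(id, seq_len(forests[[id]]$m), sep = ".")
      })))
      blocks[[i]] <- full[, idx, drop = FALSE]
    }
  }
  T_ <- do.call(rbind, blocks)
  colnames(T_) <- col_ids
  structure(
    list(T = T_,
         Y = unlist(lapply(tr, `[[`, "outcome"), use.names = FALSE),
         row_study = rep(vapply(tr, `[[`, character(1), "study_id"),
                         vapply(tr, function(s) nrow(s$features), integer(1))),
         col_component = col_ids, level = level),
    class = "stack_matrix"
  )
}

# per-row OOB forest prediction: mean over trees for which the row is
# out-of-bag; rows in-bag for every tree fall back to the refit prediction
oob_forest_prediction <- function(forest, fallback) {
  pm <- predict_tree_matrix(forest, forest$features)
  out <- fallback
  for (r in seq_len(nrow(pm))) {
    oob_trees <- which(vapply(forest$inbag, function(cnt) cnt[r] == 0L, logical(1)))
    if (length(oob_trees)) out[r] <- mean(pm[r, oob_trees])
  }
  out
}

#' @export
print.stack_matrix <- function(x, ...) {
  cat(sprintf("<stack_matrix> %d observations x %d %s-level components\n",
              nrow(x$T), ncol(x$T), x$level))
  invisible(x)
}

#' Write / read a stack matrix as delimited text
#'
#' Header row carries the component ids; a leading `study_id` column and a
#' trailing `outcome` column carry the row bookkeeping.
#'
#' @param stack A `stack_matrix`.
#' @param path File path.
#' @return `write_stack_matrix` invisibly returns `path`;
#'   `read_stack_matrix` returns a `stack_matrix`.
#' @export
write_stack_matrix <- function(stack, path) {
  stopifnot(inherits(stack, "stack_matrix"))
  df <- data.frame(study_id = stack$row_study, stack$T, outcome = stack$Y,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_matrix
#' @export
read_stack_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  comp <- setdiff(names(df), c("study_id", "outcome"))
  T_ <- as.matrix(df[, comp, drop = FALSE])
  structure(
    list(T = T_, Y = df$outcome, row_study = df$study_id,
         col_component = comp,
         level = if (all(grepl("\\.", comp))) "tree" else "forest"),
    class = "stack_matrix"
  )
}

# Active-set non-negative quadratic program on normal equations:
#   min_w  0.5 w'Gw - d'w   s.t. w >= 0
# Lawson-Hanson style with an optional warm-started passive set, used to
# sweep a descending ridge path cheaply (the passive set changes little
# between neighboring penalties).
nnls_normal <- function(G, d, passive = NULL, tol = 1e-10) {
  J <- length(d)
  w <- numeric(J)
  P <- if (is.null(passive)) rep(FALSE, J) else passive
  scale <- max(abs(d), 1)
  for (iter in seq_len(10L * J + 10L)) {
    if (any(P)) {
      wp <- tryCatch(solve(G[P, P, drop = FALSE], d[P]), error = function(e) NULL)
      if (is.null(wp)) { P <- rep(FALSE, J); w <- numeric(J); next }
      while (any(wp <= 0)) {
        idxP <- which(P)
        neg <- wp <= 0
        alpha <- min(w[idxP][neg] / (w[idxP][neg] - wp[neg]))
        w[idxP] <- w[idxP] + alpha * (wp - w[idxP])
        P[idxP[w[idxP] <= tol * scale]] <- FALSE
        w[!P] <- 0
        if (!any(P)) { wp <- numeric(0); break }
        wp <- solve(G[P, P, drop = FALSE], d[P])
      }
      w[] <- 0
      if (length(wp)) w[P] <- wp
    }
    g <- d - drop(G %*% w)
    cand <- !P & g > tol * scale
    if (!any(cand)) break
    P[which.max(replace(g, !cand, -Inf))] <- TRUE
  }
  list(w = w, passive = P)
}

#' Solve the non-negative penalized stacking regression
#'
#' Fits the stacking weights by regressing the stacked outcomes on the
#' stacked component predictions under a non-negativity constraint and a
#' ridge (or optionally lasso) penalty:
#' \deqn{\min_{w \ge 0, b_0} \; \|Y - b_0 - T w\|^2 + \lambda \|w\|^2}
#' with the intercept unpenalized and unconstrained. The penalty strength is
#' chosen by cross-validation over a log-spaced grid. Columns of `T` are
#' standardized internally before penalization and the weights
#' back-transformed (non-negativity is preserved under positive column
#' scaling); zero-variance columns receive weight 0. The exact solution at
#' each penalty is computed by an active-set non-negative quadratic program
#' on the normal equations, warm-started along the descending penalty path.
#' Weights are not normalized to sum to 1.
#'
#' @param stack A [build_stack_matrix()] result.
#' @param lambda_grid Penalty grid; default 100 log-spaced values spanning
#'   `N x 10^-8` to `N x 10^3` (the standardized Gram diagonal is of order
#'   N, so the grid covers effectively unpenalized through fully shrunk
#'   fits). A length-1 grid skips cross-validation.
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param penalty `"ridge"` (default) or `"lasso"`.
#' @param seed Seed for fold assignment.
#' @param intercept Include an unpenalized intercept (default TRUE).
#' @param standardize Standardize `T` columns internally (default TRUE).
#' @param fold_type `"observation"` (default) or `"study"` (folds are whole
#'   studies; `cv_folds` is then capped at the study count).
#'
#' @return An object of class `stacking_fit`: `w_stack` (nonnegative, named
#'   by component), `intercept`, `lambda` (selected penalty), `penalty`,
#'   `cv_folds`, `cv_curve` (data frame of `lambda`, `cv_error`),
#'   `lambda_grid`, `level`, `col_component`.
#' @export
solve_nn_ridge <- function(stack, lambda_grid = NULL, cv_folds = 10L,
                           penalty = c("ridge", "lasso"), seed = 1L,
                           intercept = TRUE, standardize = TRUE,
                           fold_type = c("observation", "study")) {
  stopifnot(inherits(stack, "stack_matrix"))
  penalty <- match.arg(penalty)
  fold_type <- match.arg(fold_type)
  T_ <- stack$T
  Y <- stack$Y
  N <- nrow(T_); J <- ncol(T_)
  if (is.null(lambda_grid)) {
    lambda_grid <- N * 10^seq(3, -8, length.out = 100L)
  }
  if (!length(lambda_grid)) stop("'lambda_grid' must be non-empty")
  lambda_grid <- sort(unique(as.numeric(lambda_grid)), decreasing = TRUE)
  do_cv <- length(lambda_grid) > 1L
  if (do_cv && (cv_folds < 2L || N <= cv_folds)) {
    stop("need N > cv_folds >= 2 for cross-validation")
  }

  # degenerate cases
  if (stats::var(Y) == 0) {
    w <- stats::setNames(numeric(J), stack$col_component)
    return(new_stacking_fit(w, if (intercept) mean(Y) else 0, NA_real_,
                            penalty, cv_folds, NULL, lambda_grid, stack))
  }
  sds <- apply(T_, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant stacking column(s) received weight 0")
  }

  fit_path <- function(Tm, Yv, grid) {
    # returns J_kept x length(grid) matrix of standardized-scale weights
    if (intercept) {
      cm <- colMeans(Tm); Yc <- Yv - mean(Yv)
    } else {
      cm <- rep(0, ncol(Tm)); Yc <- Yv
    }
    Tc <- sweep(Tm, 2L, cm)
    if (standardize) {
      sd_loc <- apply(Tm, 2L, stats::sd)
      sd_loc[sd_loc == 0] <- 1
      Tc <- sweep(Tc, 2L, sd_loc, "/")
    } else {
      sd_loc <- rep(1, ncol(Tm))
    }
    G <- crossprod(Tc)
    d <- drop(crossprod(Tc, Yc))
    W <- matrix(0, ncol(Tm), length(grid))
    pass <- NULL
    for (g in seq_along(grid)) {
      lam <- grid[g]
      res <- if (penalty == "ridge") {
        nnls_normal(G + diag(lam, ncol(Tm)), d, passive = pass)
      } else {
        nnls_normal(G, d - lam / 2, passive = pass)
      }
      pass <- res$passive
      W[, g] <- res$w
    }
    list(W = W, cm = cm, sd = sd_loc)
  }

  Tk <- T_[, keep, drop = FALSE]
  cv_curve <- NULL
  if (do_cv) {
    set.seed(seed)
    folds <- if (fold_type == "observation") {
      sample(rep(seq_len(cv_folds), length.out = N))
    } else {
      ids <- unique(stack$row_study)
      k <- min(cv_folds, length(ids))
      fid <- sample(rep(seq_len(k), length.out = length(ids)))
      fid[match(stack$row_study, ids)]
    }
    sse <- numeric(length(lambda_grid))
    for (f in sort(unique(folds))) {
      trn <- folds != f
      path <- fit_path(Tk[trn, , drop = FALSE], Y[trn], lambda_grid)
      Tt <- sweep(sweep(Tk[!trn, , drop = FALSE], 2L, path$cm), 2L, path$sd, "/")
      pred <- Tt %*% path$W
      if (intercept) pred <- pred + mean(Y[trn])
      sse <- sse + colSums((Y[!trn] - pred)^2)
    }
    cv_curve <- data.frame(lambda = lambda_grid, cv_error = sse / N)
    lambda <- lambda_grid[which.min(cv_curve$cv_error)]
  } else {
    lambda <- lambda_grid
  }

  path <- fit_path(Tk, Y, lambda)
  w_kept <- drop(path$W) / path$sd # back-transform to the original scale
  w <- stats::setNames(numeric(J), stack$col_component)
  w[keep] <- pmax(w_kept, 0)
  b0 <- if (intercept) mean(Y) - sum(colMeans(T_) * w) else 0
  new_stacking_fit(w, b0, lambda, penalty, cv_folds, cv_curve, lambda_grid, stack)
}

new_stacking_fit <- function(w, intercept, lambda, penalty, cv_folds,
                             cv_curve, lambda_grid, stack) {
  structure(
    list(w_stack = w, intercept = intercept, lambda = lambda,
         penalty = penalty, cv_folds = as.integer(cv_folds),
         cv_curve = cv_curve, lambda_grid = lambda_grid,
         level = stack$level, col_component = stack$col_component),
    class = "stacking_fit"
  )
}

#' @export
print.stacking_fit <- function(x, ...) {
  cat(sprintf("<stacking_fit> %d %s-level weights (%s penalty), lambda = %.4g, intercept = %.4g\n",
              length(x$w_stack), x$level, x$penalty, x$lambda, x$intercept))
  cat(sprintf("  %d nonzero weights, sum = %.4g\n",
              sum(x$w_stack > 0), sum(x$w_stack)))
  invisible(x)
}

#' Serialize / restore a stacking fit
#'
#' Plain-text round trip including the penalty grid and CV curve for audit.
#'
#' @param fit A `stacking_fit`.
#' @param path File path.
#' @return `write_stacking_fit` invisibly returns `path`;
#'   `read_stacking_fit` returns a `stacking_fit`.
#' @export
write_stacking_fit <- function(fit, path) {
  stopifnot(inherits(fit, "stacking_fit"))
  obj <- fit
  class(obj) <- NULL
  obj$cv_curve <- if (is.null(fit$cv_curve)) NULL else as.list(fit$cv_curve)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_stacking_fit
#' @export
read_stacking_fit <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(
    list(w_stack = stats::setNames(as.numeric(obj$w_stack), obj$col_component),
         intercept = obj$intercept, lambda = obj$lambda,
         penalty = obj$penalty, cv_folds = as.integer(obj$cv_folds),
         cv_curve = if (is.null(obj$cv_curve)) NULL else as.data.frame(obj$cv_curve),
         lambda_grid = as.numeric(obj$lambda_grid), level = obj$level,
         col_component = obj$col_component),
    class = "stacking_fit"
  )
}

#' Implied tree-level weights of a forest-level fit
#'
#' When a whole forest receives stacking weight `w_k`, each of its `m` member
#' trees is implicitly weighted `w_k / m`. Summing the implied tree weights
#' recovers the forest weights exactly.
#'
#' @param fit A forest-level `stacking_fit`, or a bare nonnegative numeric
#'   vector of forest weights.
#' @param m Trees per forest.
#' @return Numeric vector of length `K * m`, named `"<forest>.<tree>"` when
#'   forest names are available, repeating each `w_k / m` `m` times in forest
#'   order.
#' @export
implied_tree_weights <- function(fit, m) {
  if (inherits(fit, "stacking_fit")) {
    if (fit$level != "forest") stop("'fit' must be a forest-level stacking fit")
    w <- fit$w_stack
  } else {
    w <- fit
  }
  if (m < 1L) stop("'m' must be at least 1")
  out <- rep(w / m, each = m)
  if (!is.null(names(w))) {
    names(out) <- paste(rep(names(w), each = m), rep(seq_len(m), length(w)),
                        sep = ".")
  }
  out
}
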