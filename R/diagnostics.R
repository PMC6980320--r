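#' Tree-structure metrics relative to the generative model
#'
#' For one tree: `freq_true_vars` is the fraction of internal split nodes
#' whose split variable is one of the model's true variables (0 for a tree
#' with no splits), and `n_interaction_vars` counts the distinct
#' interaction-involved variables among the tree's split variables.
#'
#' @param tree A `study_tree` from [extract_trees()].
#' @param model The `gen_model` that generated the data.
#' @return A one-row data frame: `tree_id`, `freq_true_vars`,
#'   `n_interaction_vars`.
#' @export
tree_structure_metrics <- function(tree, model) {
  stopifnot(inherits(tree, "study_tree"), inherits(model, "gen_model"))
  sv <- tree$split_variables
  data.frame(
    tree_id = tree$tree_id,
    freq_true_vars = if (length(sv)) mean(sv %in% model$true_idx) else 0,
    n_interaction_vars = length(intersect(unique(sv), model$interaction_idx)),
    stringsAsFactors = FALSE
  )
}

#' Per-tree structure table for an ensemble
#'
#' Applies [tree_structure_metrics()] to every tree of every forest in a
#' fitted ensemble and attaches each tree's weight on the common tree-level
#' scale (see [tree_level_weights()]).
#'
#' @param ensemble A `cs_ensemble`.
#' @param model The `gen_model` behind the training data.
#' @return Data frame with one row per tree: `tree_id`, `weight`,
#'   `freq_true_vars`, `n_interaction_vars`.
#' @export
tree_structure_table <- function(ensemble, model) {
  stopifnot(inherits(ensemble, "cs_ensemble"))
  trees <- unlist(lapply(ensemble$forests, extract_trees), recursive = FALSE)
  tab <- do.call(rbind, lapply(trees, tree_structure_metrics, model = model))
  w <- tree_level_weights(ensemble)
  tab$weight <- unname(w[match(tab$tree_id, names(w))])
  tab[, c("tree_id", "weight", "freq_true_vars", "n_interaction_vars")]
}

#' Out-of-bag permutation variable importance
#'
#' For each tree, the out-of-bag MSE (Brier error for classification) is
#' recorded, then recomputed after permuting each predictor column; the raw
#' importance of a variable is the mean over trees of the error increase,
#' and the reported importance normalizes that mean by the standard
#' deviation of the per-tree differences. Variables used by no tree have
#' raw (and normalized) importance exactly 0. One seeded permutation per
#' variable per forest is applied to the whole column and evaluated on each
#' tree's out-of-bag rows. Trees with an empty out-of-bag set are skipped
#' with a warning.
#'
#' @param forests A `study_forest`, a list of them, or a `cs_ensemble`
#'   (its per-study forests are used).
#' @param seed Integer seed for the permutations.
#' @return A list: `importance` (normalized, length p), `raw` (mean
#'   difference), `raw_sd` (sd of per-tree differences), `per_tree`
#'   (trees x p matrix of differences), `n_trees_used`.
#' @export
permutation_importance <- function(forests, seed = 1L) {
  if (inherits(forests, "cs_ensemble")) forests <- forests$forests
  if (inherits(forests, "study_forest")) forests <- list(forests)
  stopifnot(all(vapply(forests, inherits, logical(1), "study_forest")))
  p <- length(forests[[1L]]$feature_names)
  if (sum(vapply(forests, `[[`, integer(1), "m")) < 2L) {
    stop("need at least 2 trees for the normalization step")
  }
  err <- function(pred, y, task) mean((y - pred)^2)
  diffs <- list()
  tree_ids <- character(0)
  skipped <- 0L
  fseeds <- seed_stream(seed, length(forests))
  for (fi in seq_along(forests)) {
    f <- forests[[fi]]
    X <- f$features
    y <- f$outcome
    base_pm <- predict_tree_matrix(f, X)
    used <- sort(unique(unlist(f$split_vars)))
    perm_seeds <- seed_stream(fseeds[fi], max(length(used), 1L))
    # permuted-error matrix: trees x p (columns for unused vars stay at base)
    d_f <- matrix(0, f$m, p)
    base_err <- numeric(f$m)
    ok <- logical(f$m)
    for (t in seq_len(f$m)) {
      oob <- f$oob[[t]]
      if (!length(oob)) { skipped <- skipped + 1L; next }
      ok[t] <- TRUE
      base_err[t] <- err(base_pm[oob, t], y[oob], f$task)
    }
    for (vi in seq_along(used)) {
      v <- used[vi]
      set.seed(perm_seeds[vi])
      Xp <- X
      Xp[, v] <- X[sample.int(nrow(X)), v]
      pm <- predict_tree_matrix(f, Xp)
      for (t in which(ok)) {
        oob <- f$oob[[t]]
        d_f[t, v] <- err(pm[oob, t], y[oob], f$task) - base_err[t]
      }
    }
    diffs[[fi]] <- d_f[ok, , drop = FALSE]
    if (any(ok)) {
      tree_ids <- c(tree_ids, paste(f$study_id, which(ok), sep = "."))
    }
  }
  if (skipped) {
    warning(skipped, " tree(s) with an empty out-of-bag set were skipped")
  }
  per_tree <- do.call(rbind, diffs)
  rownames(per_tree) <- tree_ids
  colnames(per_tree) <- forests[[1L]]$feature_names
  raw <- colMeans(per_tree)
  raw_sd <- apply(per_tree, 2L, stats::sd)
  imp <- ifelse(raw_sd > 0, raw / raw_sd, 0)
  list(importance = imp, raw = raw, raw_sd = raw_sd, per_tree = per_tree,
       n_trees_used = nrow(per_tree))
}

#' Proportion of total variable importance on the true variables
#'
#' Negative importances are floored at 0 before forming the proportion, so
#' the result always lies in `[0, 1]`.
#'
#' @param importance Numeric importance vector over all p variables.
#' @param true_idx Indices of the true variables.
#' @return `sum(importance[true_idx]) / sum(importance)` after flooring;
#'   0 (with a warning) when every floored importance is 0.
#' @export
proportion_true_varimp <- function(importance, true_idx) {
  imp <- pmax(as.numeric(importance), 0)
  tot <- sum(imp)
  if (tot == 0) {
    warning("all importances are zero; returning 0")
    return(0)
  }
  sum(imp[true_idx]) / tot
}

#' Decile-band summary of tree weights
#'
#' Sorts the weights ascending (ties broken by component index) and reports
#' the mean weight in the bottom 10%, the top 10% and overall. With fewer
#' than 10 weights only the overall band is reported.
#'
#' @param weights Numeric weight vector.
#' @return Data frame with columns `band` (`"0-10%"`, `"90-100%"`,
#'   `"0-100%"`) and `mean_weight`.
#' @export
weight_decile_summary <- function(weights) {
  w <- as.numeric(weights)
  n <- length(w)
  if (n < 10L) {
    return(data.frame(band = "0-100%", mean_weight = mean(w),
                      stringsAsFactors = FALSE))
  }
  ord <- order(w) # stable: ties keep component order
  k <- n %/% 10L
  data.frame(
    band = c("0-10%", "90-100%", "0-100%"),
    mean_weight = c(mean(w[ord[seq_len(k)]]),
                    mean(w[ord[(n - k + 1L):n]]),
                    mean(w)),
    stringsAsFactors = FALSE
  )
}

#' Structure metrics by weight-decile band
#'
#' Groups a [tree_structure_table()] into bottom-decile, top-decile and
#' overall bands by tree weight and averages each structure metric within
#' the band.
#'
#' @param structure_table Output of [tree_structure_table()].
#' @return Data frame with one row per band and the mean `weight`,
#'   `freq_true_vars` and `n_interaction_vars` within it.
#' @export
decile_structure_summary <- function(structure_table) {
  stopifnot(all(c("weight", "freq_true_vars", "n_interaction_vars") %in%
                  names(structure_table)))
  w <- structure_table$weight
  n <- length(w)
  ord <- order(w)
  k <- max(n %/% 10L, 1L)
  bands <- list("0-10%" = ord[seq_len(k)],
                "90-100%" = ord[(n - k + 1L):n],
                "0-100%" = seq_len(n))
  do.call(rbind, lapply(names(bands), function(b) {
    rows <- structure_table[bands[[b]], ]
    data.frame(band = b, mean_weight = mean(rows$weight),
               freq_true_vars = mean(rows$freq_true_vars),
               n_interaction_vars = mean(rows$n_interaction_vars),
               stringsAsFactors = FALSE)
  }))
}

#' Difference between implied and direct tree weights
#'
#' Aligns a tree-level stacking fit with a forest-level fit over the same
#' trees and returns, per tree, the implied forest weight `w_k / m` minus
#' the direct tree weight.
#'
#' @param tree_fit A tree-level `stacking_fit`.
#' @param forest_fit A forest-level `stacking_fit` over the same forests.
#' @param m Trees per forest.
#' @return Named numeric vector of per-tree differences, in the tree fit's
#'   component order.
#' @export
weight_difference_distribution <- function(tree_fit, forest_fit, m) {
  stopifnot(inherits(tree_fit, "stacking_fit"),
            inherits(forest_fit, "stacking_fit"))
  if (tree_fit$level != "tree" || forest_fit$level != "forest") {
    stop("'tree_fit' must be tree-level and 'forest_fit' forest-level")
  }
  implied <- implied_tree_weights(forest_fit, m)
  if (!setequal(names(implied), names(tree_fit$w_stack))) {
    stop("component ids of the two fits do not align")
  }
  implied[names(tree_fit$w_stack)] - tree_fit$w_stack
}
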