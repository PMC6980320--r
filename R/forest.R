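#' Train a random forest on one study
#'
#' Wraps [ranger::ranger()] with the bookkeeping this package needs from each
#' forest: per-tree in-bag counts (hence out-of-bag row indices), per-tree
#' split-variable multisets, and the training data itself, so that individual
#' trees can later be treated as standalone learners and inspected.
#'
#' @param study An [ms_study()].
#' @param m Trees per forest (default 10).
#' @param mtry Candidate variables per split; default `min(9, p)`.
#' @param seed Integer seed; forests are deterministic given the seed.
#' @param bootstrap Draw bootstrap samples per tree (default TRUE). Setting
#'   FALSE trains every tree on the full study (no out-of-bag rows).
#' @param min_node_size Minimum node size; NULL uses ranger's task default.
#' @param task `"regression"` or `"classification"`. Classification expects a
#'   0/1 outcome and grows probability trees whose predictions are class-1
#'   probabilities.
#'
#' @return An object of class `study_forest`: `study_id`, `fit` (the ranger
#'   object), `m`, `mtry`, `task`, `feature_names`, `features`/`outcome`
#'   (training data), `inbag` (list of per-tree in-bag count vectors),
#'   `oob` (list of per-tree out-of-bag row indices) and `split_vars`
#'   (list of per-tree integer multisets of split-variable indices).
#' @export
train_forest <- function(study, m = 10L, mtry = NULL, seed = 1L,
                         bootstrap = TRUE, min_node_size = NULL,
                         task = c("regression", "classification")) {
  stopifnot(inherits(study, "ms_study"))
  task <- match.arg(task)
  p <- ncol(study$features)
  if (is.null(mtry)) mtry <- min(9L, p)
  if (mtry < 1L || mtry > p) stop("'mtry' must lie in [1, p]")
  x <- as.data.frame(study$features)
  y <- study$outcome
  if (task == "classification") {
    if (!all(y %in% c(0, 1))) stop("classification expects a 0/1 outcome")
    y <- factor(y, levels = c(0, 1))
  }
  fit <- ranger::ranger(
    x = x, y = y, num.trees = m, mtry = mtry, seed = seed,
    num.threads = 1L, keep.inbag = TRUE,
    replace = bootstrap, sample.fraction = 1,
    min.node.size = min_node_size,
    probability = task == "classification",
    respect.unordered.factors = FALSE
  )
  split_vars <- lapply(seq_len(m), function(t) {
    info <- ranger::treeInfo(fit, t)
    ids <- info$splitvarID[!info$terminal]
    as.integer(ids) + 1L # ranger is 0-based
  })
  inbag <- fit$inbag.counts
  oob <- lapply(inbag, function(cnt) which(cnt == 0L))
  structure(
    list(study_id = study$study_id, fit = fit, m = as.integer(m),
         mtry = as.integer(mtry), task = task,
         feature_names = colnames(study$features),
         features = study$features, outcome = study$outcome,
         inbag = inbag, oob = oob, split_vars = split_vars,
         seed = as.integer(seed)),
    class = "study_forest"
  )
}

#' @export
print.study_forest <- function(x, ...) {
  cat(sprintf("<study_forest> '%s': %d %s trees, mtry = %d, n = %d, p = %d\n",
              x$study_id, x$m, x$task, x$mtry, length(x$outcome),
              length(x$feature_names)))
  invisible(x)
}

check_feature_dim <- function(forest, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(forest$feature_names)) {
    stop(sprintf("feature dimension mismatch: expected p = %d, got %d",
                 length(forest$feature_names), ncol(X)))
  }
  colnames(X) <- forest$feature_names
  as.data.frame(X)
}

#' Predict with a study forest
#'
#' The forest prediction is the unweighted mean of its member trees'
#' predictions (class-1 probability mean for classification).
#'
#' @param object A `study_forest`.
#' @param X Feature matrix with the training feature dimension.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.study_forest <- function(object, X, ...) {
  df <- check_feature_dim(object, X)
  pr <- predict(object$fit, df, num.threads = 1L)$predictions
  if (object$task == "classification") pr <- pr[, "1"]
  as.numeric(pr)
}

#' Per-tree predictions of a forest
#'
#' @param forest A `study_forest`.
#' @param X Feature matrix.
#' @return An `nrow(X) x m` matrix, one column per member tree (class-1
#'   probabilities for classification).
#' @export
predict_tree_matrix <- function(forest, X) {
  df <- check_feature_dim(forest, X)
  pr <- predict(forest$fit, df, predict.all = TRUE, num.threads = 1L)$predictions
  if (forest$task == "classification") pr <- pr[, "1", , drop = TRUE]
  matrix(pr, nrow = nrow(df), ncol = forest$m)
}

#' Train the Merged forest
#'
#' One forest of `total_trees` trees trained on the row-concatenation of all
#' training studies, so the merged comparator holds as many trees as the
#' weighted ensembles it is compared against (K forests x m trees).
#'
#' @param collection An [ms_collection()] with at least one training study.
#' @param total_trees Number of trees; default `K * m` with m = 10.
#' @param mtry,seed,min_node_size,task As in [train_forest()].
#' @return A `study_forest` with `study_id = "merged"`.
#' @export
train_merged <- function(collection, total_trees = NULL, mtry = NULL,
                         seed = 1L, min_node_size = NULL,
                         task = c("regression", "classification")) {
  task <- match.arg(task)
  tr <- train_studies(collection)
  if (!length(tr)) stop("collection has no training studies")
  if (is.null(total_trees)) total_trees <- 10L * length(tr)
  feats <- do.call(rbind, lapply(tr, `[[`, "features"))
  y <- unlist(lapply(tr, `[[`, "outcome"), use.names = FALSE)
  merged <- ms_study("merged", feats, y, "train")
  train_forest(merged, m = total_trees, mtry = mtry, seed = seed,
               min_node_size = min_node_size, task = task)
}

#' Extract a forest's member trees as standalone predictors
#'
#' The mean of the extracted trees' predictions reproduces the forest
#' prediction exactly.
#'
#' @param forest A `study_forest`.
#' @return A list of `m` objects of class `study_tree`, each with `tree_id`
#'   (`"<study_id>.<index>"`), `index`, the parent `forest`,
#'   `split_variables` (integer multiset of feature indices used at split
#'   nodes) and `oob_indices` (training rows outside the tree's bootstrap
#'   sample).
#' @export
extract_trees <- function(forest) {
  stopifnot(inherits(forest, "study_forest"))
  lapply(seq_len(forest$m), function(t) {
    structure(
      list(tree_id = paste(forest$study_id, t, sep = "."),
           index = t, forest = forest,
           split_variables = forest$split_vars[[t]],
           oob_indices = forest$oob[[t]]),
      class = "study_tree"
    )
  })
}

#' @export
print.study_tree <- function(x, ...) {
  cat(sprintf("<study_tree> %s: %d split nodes, %d OOB rows\n",
              x$tree_id, length(x$split_variables), length(x$oob_indices)))
  invisible(x)
}

#' Predict with a single extracted tree
#'
#' @param object A `study_tree`.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.study_tree <- function(object, X, ...) {
  predict_tree_matrix(object$forest, X)[, object$index]
}

#' Serialize a forest's defining inputs to a file
#'
#' Stores the training data, hyperparameters and seed as plain text
#' (RDS-free); [read_forest()] retrains and reproduces predictions exactly,
#' since forests are deterministic given their seed.
#'
#' @param forest A `study_forest`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "study_forest"))
  header <- sprintf("# study_forest %s m=%d mtry=%d seed=%d task=%s",
                    forest$study_id, forest$m, forest$mtry, forest$seed,
                    forest$task)
  df <- data.frame(forest$features, .outcome = forest$outcome,
                   check.names = FALSE)
  # full double precision so retraining reproduces the forest bit-exactly
  df[] <- lapply(df, function(col) formatC(col, digits = 17, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  opts <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  id <- sub("^# study_forest ([^ ]+).*", "\\1", header)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  feats <- as.matrix(df[, setdiff(names(df), ".outcome"), drop = FALSE])
  study <- ms_study(id, feats, df$.outcome, "train")
  train_forest(study, m = as.integer(opts["m"]), mtry = as.integer(opts["mtry"]),
               seed = as.integer(opts["seed"]), task = opts[["task"]])
}
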