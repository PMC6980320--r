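#' Construct a single study
#'
#' A study bundles a numeric feature matrix with its outcome vector and its
#' role in the collection (training or validation). All studies in a
#' collection must share the same ordered feature set.
#'
#' @param study_id Character scalar identifying the study.
#' @param features Numeric matrix, samples in rows and features in columns.
#'   Column names are assigned (`f1`, `f2`, ...) when missing.
#' @param outcome Numeric vector of length `nrow(features)`. For binary
#'   outcomes use 0/1 coding.
#' @param role One of `"train"` or `"validate"`.
#'
#' @return An object of class `ms_study` with fields `study_id`, `features`,
#'   `outcome` and `role`.
#' @export
ms_study <- function(study_id, features, outcome, role = c("train", "validate")) {
  role <- match.arg(role)
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("'features' must be a numeric matrix")
  if (nrow(features) < 2L) stop("a study needs at least 2 samples")
  if (anyNA(features) || anyNA(outcome)) stop("missing values are not allowed")
  if (length(outcome) != nrow(features)) {
    stop("'outcome' length must equal the number of feature rows")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  structure(
    list(study_id = as.character(study_id), features = features,
         outcome = as.numeric(outcome), role = role),
    class = "ms_study"
  )
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf("<ms_study> '%s' (%s): %d samples x %d features\n",
              x$study_id, x$role, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Construct a multi-study collection
#'
#' @param studies List of [ms_study()] objects sharing one ordered feature set.
#'
#' @return An object of class `ms_collection` with the studies, the training
#'   count `K`, the validation count `V` and the shared `feature_names`.
#' @export
ms_collection <- function(studies) {
  if (!length(studies) || !all(vapply(studies, inherits, logical(1), "ms_study"))) {
    stop("'studies' must be a non-empty list of ms_study objects")
  }
  fn <- colnames(studies[[1L]]$features)
  for (s in studies) {
    if (!identical(colnames(s$features), fn)) {
      stop("all studies must share the same ordered feature set")
    }
  }
  roles <- vapply(studies, `[[`, character(1), "role")
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) stop("study ids must be unique")
  structure(
    list(studies = studies, K = sum(roles == "train"),
         V = sum(roles == "validate"), feature_names = fn),
    class = "ms_collection"
  )
}

#' @export
print.ms_collection <- function(x, ...) {
  cat(sprintf("<ms_collection> %d train + %d validation studies, p = %d\n",
              x$K, x$V, length(x$feature_names)))
  invisible(x)
}

#' Subset the training or validation studies of a collection
#'
#' @param collection An [ms_collection()].
#' @return A list of `ms_study` objects.
#' @export
train_studies <- function(collection) {
  stopifnot(inherits(collection, "ms_collection"))
  Filter(function(s) s$role == "train", collection$studies)
}

#' @rdname train_studies
#' @export
validation_studies <- function(collection) {
  stopifnot(inherits(collection, "ms_collection"))
  Filter(function(s) s$role == "validate", collection$studies)
}

#' Write a collection to delimited text files
#'
#' One tab-separated file per study (features, then `outcome` and `study_id`
#' columns) plus a `manifest.tsv` listing ids, roles and sample sizes.
#'
#' @param collection An [ms_collection()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the manifest data frame.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "ms_collection"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(
    study_id = vapply(collection$studies, `[[`, character(1), "study_id"),
    role = vapply(collection$studies, `[[`, character(1), "role"),
    n = vapply(collection$studies, function(s) nrow(s$features), integer(1)),
    file = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(collection$studies)) {
    s <- collection$studies[[i]]
    df <- data.frame(s$features, outcome = s$outcome,
                     study_id = s$study_id, check.names = FALSE)
    f <- file.path(dir, paste0(s$study_id, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$file[i] <- basename(f)
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a collection written by [write_collection()]
#'
#' @param dir Directory containing the per-study files and `manifest.tsv`.
#' @return An [ms_collection()].
#' @export
read_collection <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  studies <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- utils::read.table(file.path(dir, manifest$file[i]), sep = "\t",
                            header = TRUE, check.names = FALSE)
    feat <- as.matrix(df[, setdiff(names(df), c("outcome", "study_id")), drop = FALSE])
    ms_study(manifest$study_id[i], feat, df$outcome, manifest$role[i])
  })
  ms_collection(studies)
}
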