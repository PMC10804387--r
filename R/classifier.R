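# Training step: a random-forest classifier supervised by virtual labels.
# The only tuned hyperparameter is the number of trees, selected from a grid
# spanning 1-1000 by stratified k-fold cross-validated accuracy (ties go to
# the smaller forest); all other forest parameters stay at library defaults.
# Blank series never enter training -- they are the natural test set -- and
# Others rows are dropped before fitting.

#' Training configuration
#'
#' @param estimator_grid Tree counts to evaluate, all within `[1, 1000]`.
#'   The default grid spans that range at ten points; set
#'   `full_sweep = TRUE` for the exhaustive 1..1000 sweep.
#' @param cv_folds Number of stratified cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment and forest fits.
#' @param label_source `"virtual"` (rule-derived labels) or `"human"`
#'   (expert ground truth); recorded in model provenance.
#' @param full_sweep Replace the grid by `1:1000`.
#' @return A `train_config` list.
#' @export
train_config <- function(estimator_grid = c(1, 5, 10, 25, 50, 100, 200, 400,
                                            700, 1000),
                         cv_folds = 5L, seed = 1L,
                         label_source = c("virtual", "human"),
                         full_sweep = FALSE) {
  label_source <- match.arg(label_source)
  if (isTRUE(full_sweep)) estimator_grid <- 1:1000
  estimator_grid <- sort(unique(as.integer(estimator_grid)))
  if (any(estimator_grid < 1L) || any(estimator_grid > 1000L)) {
    stop("estimator_grid values must lie in [1, 1000]", call. = FALSE)
  }
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(estimator_grid = estimator_grid,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 label_source = label_source),
            class = "train_config")
}

# per-class round-robin fold assignment after a seeded shuffle; protects
# rare classes (Scout, Perfusion) from fold starvation
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.fit_forest <- function(x, y, num_trees, seed) {
  ranger::ranger(x = x, y = y, num.trees = num_trees, seed = seed,
                 num.threads = 1L)
}

#' Train the sequence-type classifier
#'
#' For each grid value the stratified k-fold CV accuracy is computed under a
#' fixed seed; the tree count maximising mean CV accuracy (tie: smallest) is
#' refit on all rows.
#'
#' @param x Feature matrix from [apply_schema()] (carries its schema).
#' @param labels Character vector of sequence labels aligned with the rows
#'   of `x`.  Must contain no `"BLANK"`; rows labeled `"Others"` are dropped
#'   before fitting.
#' @param config A [train_config()].
#' @param dataset_ids Character vector recorded in provenance.
#' @return A `seq_model`: the fitted forest, `selected_n_estimators`,
#'   `feature_schema`, `class_list`, the full `cv_curve` (mean and sd of CV
#'   accuracy per grid point), and training provenance.
#' @export
train_classifier <- function(x, labels, config = train_config(),
                             dataset_ids = "dataset-1") {
  stopifnot(is.matrix(x), inherits(config, "train_config"))
  schema <- attr(x, "schema")
  if (is.null(schema)) {
    stop("feature matrix must carry its schema (use apply_schema())",
         call. = FALSE)
  }
  if (length(labels) != nrow(x)) {
    stop("labels and feature matrix are not aligned", call. = FALSE)
  }
  assert_labels(labels)
  if (any(labels == "BLANK")) {
    stop("training labels must not contain BLANK (blank series are the ",
         "test set)", call. = FALSE)
  }
  drop_others <- labels == "Others"
  if (any(drop_others)) {
    message(sum(drop_others), " 'Others' row(s) excluded from training")
    x <- x[!drop_others, , drop = FALSE]
    labels <- labels[!drop_others]
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training requires examples of at least two classes", call. = FALSE)
  }
  if (nrow(x) < config$cv_folds) {
    stop("fewer training rows than cross-validation folds", call. = FALSE)
  }

  y <- factor(labels, levels = classes)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  folds <- stratified_folds(labels, config$cv_folds)

  grid <- config$estimator_grid
  mean_acc <- numeric(length(grid))
  sd_acc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    accs <- numeric(config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      if (length(unique(labels[tr])) < 2L) {
        accs[f] <- NA_real_
        next
      }
      fit <- .fit_forest(x[tr, , drop = FALSE],
                         droplevels(y[tr]), grid[gi],
                         seed = config$seed + 7919L * f + grid[gi])
      pred <- stats::predict(fit, data = x[!tr, , drop = FALSE])$predictions
      accs[f] <- mean(as.character(pred) == labels[!tr])
    }
    mean_acc[gi] <- mean(accs, na.rm = TRUE)
    sd_acc[gi] <- stats::sd(accs, na.rm = TRUE)
  }
  best <- which.max(mean_acc)  # grid sorted ascending: first max = smallest
  forest <- .fit_forest(x, y, grid[best], seed = config$seed)

  structure(list(
    forest = forest,
    selected_n_estimators = grid[best],
    feature_schema = schema,
    class_list = classes,
    cv_curve = data.frame(n_estimators = grid, mean_accuracy = mean_acc,
                          sd_accuracy = sd_acc),
    provenance = list(dataset_ids = dataset_ids,
                      label_source = config$label_source,
                      seed = config$seed, n_train = nrow(x),
                      schema_hash = schema_hash(schema))
  ), class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  cat(sprintf(
    "<seq_model> %d classes, %d trees (CV accuracy %.3f), %d training rows\n",
    length(x$class_list), x$selected_n_estimators,
    x$cv_curve$mean_accuracy[x$cv_curve$n_estimators ==
                               x$selected_n_estimators],
    x$provenance$n_train))
  invisible(x)
}

#' Predict sequence types for series records
#'
#' @param object A `seq_model`.
#' @param newdata `series_records` (schema applied internally) or a feature
#'   matrix already in the model's column order.
#' @param ... Unused.
#' @return Character vector of labels from the model's `class_list`.
#' @export
predict.seq_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else
    apply_schema(newdata, object$feature_schema)
  if (!identical(colnames(x), object$feature_schema$column_order)) {
    stop("feature columns do not match the model's schema", call. = FALSE)
  }
  as.character(stats::predict(object$forest, data = x,
                              num.threads = 1L, seed = object$provenance$seed
                              )$predictions)
}

#' Compose final labels: rule labels pass through, blanks are predicted
#'
#' @param decisions A [label_dataset()] result.
#' @param model A trained `seq_model`.
#' @param records The `series_records` the decisions were computed from
#'   (row-aligned).
#' @return Character labels with no `"BLANK"` entries.
#' @export
compose_final_labels <- function(decisions, model, records) {
  stopifnot(nrow(decisions) == nrow(records))
  out <- decisions$label
  blank <- which(out == "BLANK")
  if (length(blank) > 0L) {
    out[blank] <- predict(model, records[blank, , drop = FALSE])
  }
  out
}

#' Retrain on pre-existing datasets plus a newly appended one
#'
#' Concatenates every dataset's non-blank, non-Others rows, refits the
#' feature schema on the combined training rows, and trains as
#' [train_classifier()].  Labels come from rule decisions only: appending an
#' archive requires no human labeling.
#'
#' @param datasets List of datasets, each a list with `records`
#'   (`series_records`), `decisions` ([label_dataset()] output) and
#'   optionally `id`.  The newly appended archive is simply the last
#'   element.
#' @param config A [train_config()].
#' @return A `seq_model` whose provenance lists every input dataset id.
#' @export
retrain_classifier <- function(datasets, config = train_config()) {
  if (length(datasets) < 1L) stop("need at least one dataset", call. = FALSE)
  recs <- list()
  labs <- list()
  ids <- character(length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    stopifnot(nrow(d$records) == nrow(d$decisions))
    keep <- !(d$decisions$label %in% c("BLANK", "Others"))
    recs[[i]] <- as.data.frame(d$records)[keep, , drop = FALSE]
    labs[[i]] <- d$decisions$label[keep]
    ids[i] <- if (!is.null(d$id)) d$id else sprintf("dataset-%d", i)
  }
  combined <- as_series_records(do.call(rbind, recs))
  labels <- unlist(labs, use.names = FALSE)
  schema <- fit_schema(combined)
  x <- apply_schema(combined, schema)
  train_classifier(x, labels, config, dataset_ids = ids)
}

#' Persist / restore a trained model
#'
#' The model is written as an RDS file with a human-readable JSON sidecar
#' (`<path>.manifest.json`) describing provenance, the CV curve, and the
#' schema hash, so inference-only runs are reproducible and auditable.
#'
#' @param model A `seq_model`.
#' @param path Model file path (e.g. `model.rds`).
#' @return `load_model()` returns the `seq_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seq_model"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(selected_n_estimators = model$selected_n_estimators,
         class_list = model$class_list,
         cv_curve = model$cv_curve,
         provenance = model$provenance),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "seq_model")) {
    stop("not a seqsort model file: ", path, call. = FALSE)
  }
  model
}
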