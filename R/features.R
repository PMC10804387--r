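# Training-preparation step: turn series records into a fixed-width numeric
# matrix.  Numeric acquisition parameters are min-max normalized with bounds
# fitted on training data; categorical/multi-valued attributes are one-hot
# encoded against fitted token vocabularies.  Missing numeric values become
# the sentinel -1 plus a per-attribute missing-indicator column, keeping
# missingness informative (InversionTime is absent outside inversion-recovery
# sequences, which is itself a strong signal).
#
# The free-text fields (SeriesDescription, ProtocolName) are deliberately
# NOT features: the classifier must recover blank series from acquisition
# parameters, not re-learn the rule keywords.

FEATURE_NUMERIC <- c("repetition_time", "echo_time", "flip_angle",
                     "imaging_frequency", "n_phase_encoding_steps", "rows",
                     "columns", "inversion_time", "slice_thickness",
                     "slice_num")
FEATURE_CATEGORICAL <- c("scanning_sequence", "sequence_variant",
                         "mr_acquisition_type", "image_type", "scan_options",
                         "body_part_examined")

.cat_tokens <- function(records, attr) {
  col <- records[[attr]]
  if (attr %in% LIST_COLUMNS) {
    lapply(col, function(v) if (is.null(v)) character(0) else as.character(v))
  } else {
    lapply(col, function(v) {
      if (length(v) != 1L || is.na(v) || !nzchar(v)) character(0) else v
    })
  }
}

#' Fit a feature schema on training records
#'
#' @param records Training `series_records` (at least one row).
#' @return A `feature_schema`: per-numeric-attribute min/max bounds fitted on
#'   non-missing training values (attributes with no observed value are
#'   dropped with a warning), per-categorical-attribute token vocabularies
#'   (multi-valued attributes contribute each token), and the frozen output
#'   `column_order`.
#' @export
fit_schema <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cannot fit a feature schema on an empty record set", call. = FALSE)
  }
  records <- as_series_records(records)
  numeric_features <- list()
  for (attr in FEATURE_NUMERIC) {
    vals <- records[[attr]][!is.na(records[[attr]])]
    if (length(vals) == 0L) {
      warning("numeric feature '", attr,
              "' has no observed training value; dropped", call. = FALSE)
      next
    }
    numeric_features[[attr]] <- c(min = as.numeric(min(vals)),
                                  max = as.numeric(max(vals)))
  }
  vocabularies <- list()
  for (attr in FEATURE_CATEGORICAL) {
    toks <- sort(unique(unlist(.cat_tokens(records, attr))))
    if (length(toks) == 0L) {
      warning("categorical feature '", attr,
              "' has no observed training token; dropped", call. = FALSE)
      next
    }
    vocabularies[[attr]] <- toks
  }
  column_order <- c(
    as.vector(rbind(names(numeric_features),
                    paste0(names(numeric_features), "_missing"))),
    unlist(lapply(names(vocabularies), function(a) {
      paste0(a, "=", vocabularies[[a]])
    }), use.names = FALSE)
  )
  structure(list(numeric_features = numeric_features,
                 vocabularies = vocabularies,
                 column_order = column_order,
                 missing_policy = "sentinel -1 + indicator column"),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d columns (%d numeric, %d one-hot)\n",
              length(x$column_order), 2 * length(x$numeric_features),
              length(x$column_order) - 2 * length(x$numeric_features)))
  invisible(x)
}

#' Apply a fitted schema to records
#'
#' Numeric `x` becomes `(x - min) / (max - min)` (0 when `max == min`),
#' clipped to `[-0.5, 1.5]` for out-of-range inference values; missing
#' numeric cells become the sentinel `-1` with the paired indicator set to 1.
#' Unseen categorical tokens yield all-zero indicators.
#'
#' @param records A `series_records` data.frame.
#' @param schema A fitted [fit_schema()] result.
#' @return Numeric matrix (rows = series, rownames = `series_uid`, columns =
#'   `schema$column_order`) with the schema in attribute `"schema"`.
#' @export
apply_schema <- function(records, schema) {
  stopifnot(inherits(schema, "feature_schema"))
  records <- as_series_records(records)
  n <- nrow(records)
  mat <- matrix(0, nrow = n, ncol = length(schema$column_order),
                dimnames = list(records$series_uid, schema$column_order))
  for (attr in names(schema$numeric_features)) {
    b <- schema$numeric_features[[attr]]
    x <- records[[attr]]
    rng <- b[["max"]] - b[["min"]]
    scaled <- if (rng > 0) (x - b[["min"]]) / rng else rep(0, n)
    scaled <- pmin(pmax(scaled, -0.5), 1.5)
    miss <- is.na(x)
    scaled[miss] <- -1
    mat[, attr] <- scaled
    mat[, paste0(attr, "_missing")] <- as.numeric(miss)
  }
  for (attr in names(schema$vocabularies)) {
    vocab <- schema$vocabularies[[attr]]
    toks <- .cat_tokens(records, attr)
    for (tok in vocab) {
      mat[, paste0(attr, "=", tok)] <-
        vapply(toks, function(tt) as.numeric(tok %in% tt), 0)
    }
  }
  attr(mat, "schema") <- schema
  mat
}

#' Serialize / restore a feature schema as JSON
#'
#' @param schema A `feature_schema`.
#' @param path File path.
#' @return `read_schema()` returns the restored `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$numeric_features <- lapply(x$numeric_features, function(b) {
    b <- unlist(b)
    if (!is.null(names(b)) && all(c("min", "max") %in% names(b))) {
      c(min = as.numeric(b[["min"]]), max = as.numeric(b[["max"]]))
    } else {
      c(min = as.numeric(b[1]), max = as.numeric(b[2]))
    }
  })
  x$vocabularies <- lapply(x$vocabularies, as.character)
  x$column_order <- as.character(x$column_order)
  structure(x, class = "feature_schema")
}

# stable content hash used in provenance manifests
schema_hash <- function(schema) {
  s <- paste(utils::capture.output(utils::str(unclass(schema), digits.d = 12)),
             collapse = "\n")
  # polynomial rolling hash; only needs to detect schema drift
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
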