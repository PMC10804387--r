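# SeriesRecord container: one row per MRI series, holding the extracted
# header attribute set plus the derived slice count.  Multi-valued DICOM
# attributes (ImageType, ScanningSequence, ...) are list columns; a NULL
# element means the tag was absent, which is distinct from an empty string
# or an empty code list.  Auxiliary columns image_orientation / b_value feed
# detail_descriptors() and are never classifier features.

RECORD_COLUMNS <- c(
  "series_uid", "series_description", "protocol_name",
  "scanning_sequence", "sequence_variant", "mr_acquisition_type",
  "image_type", "repetition_time", "echo_time", "flip_angle",
  "imaging_frequency", "n_phase_encoding_steps", "rows", "columns",
  "inversion_time", "slice_thickness", "scan_options",
  "body_part_examined", "slice_num", "image_orientation", "b_value"
)

LIST_COLUMNS <- c("scanning_sequence", "sequence_variant", "image_type",
                  "scan_options", "image_orientation")
TEXT_COLUMNS <- c("series_uid", "series_description", "protocol_name",
                  "mr_acquisition_type", "body_part_examined")
NUMERIC_COLUMNS <- c("repetition_time", "echo_time", "flip_angle",
                     "imaging_frequency", "n_phase_encoding_steps", "rows",
                     "columns", "inversion_time", "slice_thickness",
                     "slice_num", "b_value")

as_series_records <- function(df) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("series records missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, RECORD_COLUMNS]
  rownames(df) <- NULL
  class(df) <- c("series_records", "data.frame")
  df
}

#' @export
print.series_records <- function(x, ...) {
  cat(sprintf("<series_records> %d series\n", nrow(x)))
  print.data.frame(utils::head(
    x[, c("series_uid", "series_description", "protocol_name",
          "repetition_time", "echo_time", "inversion_time", "slice_num")]),
    ...)
  invisible(x)
}

# reserved encodings for the delimited on-disk form
MISSING_TOKEN <- "\\N"
LIST_SEP <- "|"

.encode_cell <- function(value, is_list) {
  if (is_list) {
    if (is.null(value) || (length(value) == 1L && all(is.na(value)))) {
      return(MISSING_TOKEN)
    }
    return(paste(as.character(value), collapse = LIST_SEP))
  }
  if (is.na(value)) return(MISSING_TOKEN)
  as.character(value)
}

#' Write / read series records as a delimited table
#'
#' Lossless CSV round trip of the extraction output.  Missing values are
#' written as the reserved token `\\N` (distinct from an empty string, which
#' is written as an empty field); multi-valued attributes are joined with
#' `|`.  Both tokens are reserved and must not occur inside values.
#'
#' @param records A `series_records` data.frame.
#' @param path File path.
#' @return `read_records()` returns the restored `series_records`;
#'   `write_records()` returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  records <- as_series_records(records)
  enc <- records
  for (col in RECORD_COLUMNS) {
    is_list <- col %in% LIST_COLUMNS
    vals <- if (is_list) records[[col]] else as.list(records[[col]])
    enc[[col]] <- vapply(vals, .encode_cell, "", is_list = is_list)
  }
  utils::write.csv(as.data.frame(enc)[, RECORD_COLUMNS], path,
                   row.names = FALSE, quote = TRUE, na = MISSING_TOKEN)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  raw_df <- utils::read.csv(path, colClasses = "character",
                            check.names = FALSE, na.strings = character(0))
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw_df))
  if (length(missing_cols) > 0L) {
    stop("malformed records table (missing columns ",
         paste(missing_cols, collapse = ", "), "): ", path, call. = FALSE)
  }
  n <- nrow(raw_df)
  out <- list()
  for (col in RECORD_COLUMNS) {
    cells <- raw_df[[col]]
    if (col %in% LIST_COLUMNS) {
      numeric_list <- col == "image_orientation"
      out[[col]] <- I(lapply(seq_len(n), function(i) {
        cell <- cells[i]
        if (identical(cell, MISSING_TOKEN)) return(NULL)
        parts <- if (nzchar(cell)) {
          strsplit(cell, LIST_SEP, fixed = TRUE)[[1]]
        } else {
          character(0)
        }
        if (numeric_list) as.numeric(parts) else parts
      }))
    } else if (col %in% NUMERIC_COLUMNS) {
      vals <- suppressWarnings(as.numeric(ifelse(cells == MISSING_TOKEN,
                                                 NA, cells)))
      bad <- which(!is.na(cells) & cells != MISSING_TOKEN & is.na(vals))
      if (length(bad) > 0L) {
        stop(sprintf("parse error in column '%s', row %d: %s",
                     col, bad[1], cells[bad[1]]), call. = FALSE)
      }
      out[[col]] <- if (col == "slice_num") as.integer(vals) else vals
    } else {
      out[[col]] <- ifelse(cells == MISSING_TOKEN, NA_character_, cells)
    }
  }
  df <- data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  as_series_records(df)
}
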