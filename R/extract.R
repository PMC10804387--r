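# Pre-processing step: walk an archive directory, group DICOM files into
# series by SeriesInstanceUID, and extract the fixed header attribute set
# plus the derived slice count.

.header_field <- function(h, keyword, kind = c("text", "list", "numeric")) {
  kind <- match.arg(kind)
  v <- h[[keyword]]
  if (kind == "text") {
    if (is.null(v)) return(NA_character_)
    v <- as.character(v)
    if (length(v) == 0L) return(NA_character_)
    v[1]
  } else if (kind == "list") {
    if (is.null(v) || length(v) == 0L) return(NULL)
    as.character(v)
  } else {
    if (is.null(v) || length(v) == 0L || all(is.na(v))) return(NA_real_)
    as.numeric(v)[1]
  }
}

.file_to_fields <- function(h) {
  orient <- h[["ImageOrientationPatient"]]
  if (!is.null(orient) && length(orient) != 6L) orient <- NULL
  list(
    series_description = .header_field(h, "SeriesDescription"),
    protocol_name = .header_field(h, "ProtocolName"),
    scanning_sequence = .header_field(h, "ScanningSequence", "list"),
    sequence_variant = .header_field(h, "SequenceVariant", "list"),
    mr_acquisition_type = .header_field(h, "MRAcquisitionType"),
    image_type = .header_field(h, "ImageType", "list"),
    repetition_time = .header_field(h, "RepetitionTime", "numeric"),
    echo_time = .header_field(h, "EchoTime", "numeric"),
    flip_angle = .header_field(h, "FlipAngle", "numeric"),
    imaging_frequency = .header_field(h, "ImagingFrequency", "numeric"),
    n_phase_encoding_steps = .header_field(h, "NumberOfPhaseEncodingSteps",
                                           "numeric"),
    rows = .header_field(h, "Rows", "numeric"),
    columns = .header_field(h, "Columns", "numeric"),
    inversion_time = .header_field(h, "InversionTime", "numeric"),
    slice_thickness = .header_field(h, "SliceThickness", "numeric"),
    scan_options = .header_field(h, "ScanOptions", "list"),
    body_part_examined = .header_field(h, "BodyPartExamined"),
    image_orientation = if (is.null(orient)) NULL else as.numeric(orient),
    b_value = .header_field(h, "DiffusionBValue", "numeric")
  )
}

#' Scan a DICOM archive into per-series records
#'
#' Walks `root` recursively, reads every DICOM Part-10 file, groups files by
#' `SeriesInstanceUID`, and builds one record per series.  Attribute values
#' are taken from the first file of the series (sorted by InstanceNumber,
#' ties by filename); the slice count is the number of files in the series.
#' Non-DICOM or unreadable files are skipped with a warning, never abort the
#' scan.  When files within one series disagree on an extracted attribute, a
#' message flags the series and the first file's value is kept.
#'
#' @param root Archive directory.
#' @param check_consistency Compare header fields across the files of each
#'   series and flag disagreements (default `TRUE`).
#' @return A `series_records` data.frame (one row per series) with the
#'   per-series file paths in attribute `"files"` (a named list,
#'   `series_uid` -> character vector of paths).
#' @export
scan_archive <- function(root, check_consistency = TRUE) {
  if (!dir.exists(root)) stop("archive directory not found: ", root,
                              call. = FALSE)
  files <- list.files(root, recursive = TRUE, full.names = TRUE,
                      no.. = TRUE)
  files <- files[!dir.exists(files)]
  headers <- vector("list", length(files))
  keep <- logical(length(files))
  for (i in seq_along(files)) {
    h <- tryCatch(dicom_read(files[i]),
                  seqsort_not_dicom = function(e) NULL,
                  error = function(e) {
                    warning(sprintf("skipping unreadable file %s: %s",
                                    files[i], conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
    if (is.null(h)) next
    uid <- .header_field(h, "SeriesInstanceUID")
    if (is.na(uid)) {
      warning("skipping DICOM file without SeriesInstanceUID: ", files[i],
              call. = FALSE)
      next
    }
    headers[[i]] <- h
    keep[i] <- TRUE
  }
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(sprintf("%d non-DICOM/unreadable file(s) skipped under %s",
                    n_skipped, root), call. = FALSE)
  }
  files <- files[keep]
  headers <- headers[keep]
  if (length(files) == 0L) {
    stop("no readable DICOM files found under ", root, call. = FALSE)
  }

  uids <- vapply(headers, function(h) .header_field(h, "SeriesInstanceUID"),
                 "")
  inst <- vapply(headers, function(h) {
    v <- .header_field(h, "InstanceNumber", "numeric")
    if (is.na(v)) Inf else v
  }, 0)
  groups <- split(seq_along(files), uids)

  rows <- vector("list", length(groups))
  file_map <- vector("list", length(groups))
  names(file_map) <- names(groups)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    idx <- idx[order(inst[idx], files[idx])]
    fields <- .file_to_fields(headers[[idx[1]]])
    if (check_consistency && length(idx) > 1L) {
      for (j in idx[-1]) {
        other <- .file_to_fields(headers[[j]])
        same <- mapply(identical, fields[names(fields) != "b_value"],
                       other[names(other) != "b_value"])
        if (!all(same)) {
          message(sprintf(
            "series %s: files disagree on %s; keeping first file's values",
            names(groups)[g],
            paste(names(same)[!same], collapse = ", ")))
          break
        }
      }
    }
    rows[[g]] <- c(list(series_uid = names(groups)[g]), fields,
                   list(slice_num = length(idx)))
    file_map[[g]] <- files[idx]
  }

  df <- data.frame(
    series_uid = vapply(rows, `[[`, "", "series_uid"),
    series_description = vapply(rows, `[[`, "", "series_description"),
    protocol_name = vapply(rows, `[[`, "", "protocol_name"),
    scanning_sequence = I(lapply(rows, `[[`, "scanning_sequence")),
    sequence_variant = I(lapply(rows, `[[`, "sequence_variant")),
    mr_acquisition_type = vapply(rows, `[[`, "", "mr_acquisition_type"),
    image_type = I(lapply(rows, `[[`, "image_type")),
    repetition_time = vapply(rows, `[[`, 0, "repetition_time"),
    echo_time = vapply(rows, `[[`, 0, "echo_time"),
    flip_angle = vapply(rows, `[[`, 0, "flip_angle"),
    imaging_frequency = vapply(rows, `[[`, 0, "imaging_frequency"),
    n_phase_encoding_steps = vapply(rows, `[[`, 0, "n_phase_encoding_steps"),
    rows = vapply(rows, `[[`, 0, "rows"),
    columns = vapply(rows, `[[`, 0, "columns"),
    inversion_time = vapply(rows, `[[`, 0, "inversion_time"),
    slice_thickness = vapply(rows, `[[`, 0, "slice_thickness"),
    scan_options = I(lapply(rows, `[[`, "scan_options")),
    body_part_examined = vapply(rows, `[[`, "", "body_part_examined"),
    slice_num = vapply(rows, function(r) as.integer(r$slice_num), 0L),
    image_orientation = I(lapply(rows, `[[`, "image_orientation")),
    b_value = vapply(rows, `[[`, 0, "b_value"),
    stringsAsFactors = FALSE
  )
  out <- as_series_records(df)
  attr(out, "files") <- file_map
  out
}

#' Detail descriptors of one series: 2D/3D scheme, acquisition plane, b-value
#'
#' The scheme is copied from `MRAcquisitionType`; the plane is computed from
#' the slice normal (cross product of the row and column direction cosines):
#' the dominant normal component maps z to axial, x to sagittal, y to
#' coronal, and anything below the dominance threshold is oblique.
#'
#' @param record A single-row series record (optional if both `orientation`
#'   and `b_value` are given).
#' @param orientation Six direction cosines (row xyz, column xyz) or `NULL`;
#'   defaults to the record's `image_orientation`.
#' @param b_value Diffusion b-value in s/mm^2 or `NULL`; defaults to the
#'   record's `b_value`.
#' @param dominance Threshold on the dominant |normal component| below which
#'   the plane is reported oblique (default 0.8).
#' @return List with `scheme` (`"2D"`, `"3D"` or `"unknown"`), `plane`
#'   (`"axial"`, `"sagittal"`, `"coronal"`, `"oblique"` or `"unknown"`), and
#'   `b_value` (number, or `NA` for unknown).
#' @examples
#' detail_descriptors(orientation = c(1, 0, 0, 0, 1, 0))$plane  # "axial"
#' @export
detail_descriptors <- function(record = NULL, orientation = NULL,
                               b_value = NULL, dominance = 0.8) {
  if (is.null(orientation) && !is.null(record)) {
    orientation <- record$image_orientation
    if (is.list(orientation)) orientation <- orientation[[1]]
  }
  if (is.null(b_value) && !is.null(record)) {
    b_value <- record$b_value
    if (is.list(b_value)) b_value <- b_value[[1]]
  }
  scheme <- "unknown"
  if (!is.null(record)) {
    acq <- record$mr_acquisition_type
    if (is.list(acq)) acq <- acq[[1]]
    if (length(acq) == 1L && !is.na(acq) && acq %in% c("2D", "3D")) {
      scheme <- acq
    }
  }

  plane <- "unknown"
  if (!is.null(orientation) && !(length(orientation) == 1L &&
                                 is.na(orientation))) {
    if (length(orientation) != 6L || any(is.na(orientation))) {
      stop("orientation must be six direction cosines", call. = FALSE)
    }
    r <- orientation[1:3]
    cvec <- orientation[4:6]
    normal <- c(r[2] * cvec[3] - r[3] * cvec[2],
                r[3] * cvec[1] - r[1] * cvec[3],
                r[1] * cvec[2] - r[2] * cvec[1])
    nn <- sqrt(sum(normal^2))
    if (nn > 0) {
      normal <- abs(normal) / nn
      axis <- which.max(normal)
      plane <- if (normal[axis] < dominance) "oblique" else {
        c("sagittal", "coronal", "axial")[axis]
      }
    }
  }

  if (is.null(b_value) || length(b_value) == 0L) b_value <- NA_real_
  list(scheme = scheme, plane = plane, b_value = as.numeric(b_value)[1])
}
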