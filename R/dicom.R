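# Minimal DICOM Part-10 header codec.
#
# The package classifies MRI series from header metadata only, so this codec
# covers exactly what that requires: Part-10 files (128-byte preamble + "DICM"
# + explicit-VR file meta group) with the dataset in explicit or implicit VR
# little endian, value parsing for the string/numeric VRs used by the tags in
# the extraction set, and pixel data treated as an opaque blob.  Undefined
# lengths (0xFFFFFFFF) and big-endian / deflated transfer syntaxes are not
# supported and raise an error, which scan_archive() downgrades to a skip.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
MR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.4"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7426.1"

# VRs encoded with a 12-byte explicit header (2 reserved bytes + 32-bit length)
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dicom_dict <- local({
  kw <- c("ImageType", "SOPClassUID", "SOPInstanceUID", "Modality",
          "Manufacturer", "SeriesDescription", "PatientName", "PatientID",
          "BodyPartExamined", "ScanningSequence", "SequenceVariant",
          "ScanOptions", "MRAcquisitionType", "SliceThickness",
          "RepetitionTime", "EchoTime", "InversionTime", "ImagingFrequency",
          "NumberOfPhaseEncodingSteps", "ProtocolName", "FlipAngle",
          "DiffusionBValue", "StudyInstanceUID", "SeriesInstanceUID",
          "SeriesNumber", "InstanceNumber", "ImageOrientationPatient",
          "SamplesPerPixel", "PhotometricInterpretation", "Rows", "Columns",
          "BitsAllocated", "BitsStored", "HighBit", "PixelRepresentation",
          "PixelData")
  grp <- c(0x0008, 0x0008, 0x0008, 0x0008, 0x0008, 0x0008, 0x0010, 0x0010,
           0x0018, 0x0018, 0x0018, 0x0018, 0x0018, 0x0018, 0x0018, 0x0018,
           0x0018, 0x0018, 0x0018, 0x0018, 0x0018, 0x0018, 0x0020, 0x0020,
           0x0020, 0x0020, 0x0020, 0x0028, 0x0028, 0x0028, 0x0028, 0x0028,
           0x0028, 0x0028, 0x0028, 0x7FE0)
  ele <- c(0x0008, 0x0016, 0x0018, 0x0060, 0x0070, 0x103E, 0x0010, 0x0020,
           0x0015, 0x0020, 0x0021, 0x0022, 0x0023, 0x0050, 0x0080, 0x0081,
           0x0082, 0x0084, 0x0089, 0x1030, 0x1314, 0x9087, 0x000D, 0x000E,
           0x0011, 0x0013, 0x0037, 0x0002, 0x0004, 0x0010, 0x0011, 0x0100,
           0x0101, 0x0102, 0x0103, 0x0010)
  vr <- c("CS", "UI", "UI", "CS", "LO", "LO", "PN", "LO", "CS", "CS", "CS",
          "CS", "CS", "DS", "DS", "DS", "DS", "DS", "IS", "LO", "DS", "FD",
          "UI", "UI", "IS", "IS", "DS", "US", "CS", "US", "US", "US", "US",
          "US", "US", "OW")
  df <- data.frame(keyword = kw, group = grp, element = ele, vr = vr,
                   stringsAsFactors = FALSE)
  df$key <- sprintf("%04X%04X", df$group, df$element)
  df
})

#' Dictionary of the DICOM attributes this package reads and writes
#'
#' @return A data.frame with columns `keyword`, `group`, `element` (integer
#'   tag halves) and `vr`, covering the attribute set consumed by
#'   [scan_archive()] plus the identifiers needed to write valid Part-10
#'   files.
#' @export
dicom_dictionary <- function() {
  .dicom_dict[, c("keyword", "group", "element", "vr")]
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.encode_value <- function(vr, value) {
  if (vr %in% c("UI", "CS", "LO", "SH", "PN", "DA", "TM", "ST")) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) {
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    }
    b
  } else if (vr == "DS") {
    s <- paste(vapply(value, function(v) {
      out <- formatC(v, format = "fg", digits = 10, width = 1)
      if (nchar(out) > 16L) out <- formatC(v, format = "g", digits = 8)
      out
    }, ""), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L) b <- c(b, charToRaw(" "))
    b
  } else if (vr == "IS") {
    b <- charToRaw(paste(as.character(as.integer(value)), collapse = "\\"))
    if (length(b) %% 2L == 1L) b <- c(b, charToRaw(" "))
    b
  } else if (vr == "US") {
    .u16(value)
  } else if (vr == "UL") {
    .u32(value)
  } else if (vr == "FD") {
    writeBin(as.double(value), raw(), size = 8L, endian = "little")
  } else if (vr %in% c("OW", "OB")) {
    b <- as.raw(value)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else {
    stop("unsupported VR for writing: ", vr, call. = FALSE)
  }
}

.encode_element <- function(group, element, vr, value, explicit) {
  body <- .encode_value(vr, value)
  tag <- c(.u16(group), .u16(element))
  if (explicit) {
    if (vr %in% LONG_VRS) {
      c(tag, charToRaw(vr), as.raw(c(0L, 0L)), .u32(length(body)), body)
    } else {
      c(tag, charToRaw(vr), .u16(length(body)), body)
    }
  } else {
    c(tag, .u32(length(body)), body)
  }
}

#' Write a single-frame MR DICOM Part-10 file
#'
#' @param path Output file path.
#' @param tags Named list of attribute values; names are dictionary keywords
#'   (see [dicom_dictionary()]).  `NULL` entries are dropped (tag absent from
#'   the file).
#' @param transfer_syntax `"explicit"` (default) or `"implicit"` VR little
#'   endian.
#' @return `path`, invisibly.
#' @export
dicom_write <- function(path, tags,
                        transfer_syntax = c("explicit", "implicit")) {
  transfer_syntax <- match.arg(transfer_syntax)
  explicit <- transfer_syntax == "explicit"
  ts_uid <- if (explicit) TS_EXPLICIT_LE else TS_IMPLICIT_LE

  tags <- tags[!vapply(tags, is.null, TRUE)]
  dict <- .dicom_dict
  idx <- match(names(tags), dict$keyword)
  if (anyNA(idx)) {
    stop("unknown DICOM keyword(s): ",
         paste(names(tags)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ord <- order(dict$group[idx], dict$element[idx])
  tags <- tags[ord]
  idx <- idx[ord]

  body <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    body[[i]] <- .encode_element(dict$group[idx[i]], dict$element[idx[i]],
                                 dict$vr[idx[i]], tags[[i]], explicit)
  }
  body <- do.call(c, body)

  sop_instance <- tags[["SOPInstanceUID"]]
  if (is.null(sop_instance)) sop_instance <- "0"
  meta <- c(
    .encode_element(0x0002, 0x0002, "UI", MR_SOP_CLASS, TRUE),
    .encode_element(0x0002, 0x0003, "UI", sop_instance, TRUE),
    .encode_element(0x0002, 0x0010, "UI", ts_uid, TRUE),
    .encode_element(0x0002, 0x0012, "UI", IMPLEMENTATION_UID, TRUE)
  )
  meta <- c(.encode_element(0x0002, 0x0000, "UL", length(meta), TRUE), meta)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# strip trailing padding (space for text VRs, NUL for UIDs) before decoding
.strip_pad <- function(bytes) {
  while (length(bytes) > 0L &&
         (bytes[length(bytes)] == as.raw(0x20) ||
          bytes[length(bytes)] == as.raw(0x00))) {
    bytes <- bytes[-length(bytes)]
  }
  bytes
}

.decode_value <- function(vr, bytes) {
  if (length(bytes) == 0L) {
    return(switch(vr,
                  DS = numeric(0), IS = numeric(0), FD = numeric(0),
                  US = integer(0), UL = integer(0), CS = character(0), ""))
  }
  if (vr %in% c("UI", "LO", "SH", "PN", "DA", "TM", "ST", "UT")) {
    rawToChar(.strip_pad(bytes))
  } else if (vr == "CS") {
    s <- rawToChar(.strip_pad(bytes))
    trimws(strsplit(s, "\\", fixed = TRUE)[[1]])
  } else if (vr %in% c("DS", "IS")) {
    s <- rawToChar(.strip_pad(bytes))
    as.numeric(trimws(strsplit(s, "\\", fixed = TRUE)[[1]]))
  } else if (vr == "US") {
    readBin(bytes, integer(), n = length(bytes) %/% 2L, size = 2L,
            endian = "little", signed = FALSE)
  } else if (vr == "UL") {
    readBin(bytes, integer(), n = length(bytes) %/% 4L, size = 4L,
            endian = "little")
  } else if (vr == "FD") {
    readBin(bytes, double(), n = length(bytes) %/% 8L, size = 8L,
            endian = "little")
  } else {
    bytes
  }
}

.read_u16 <- function(bytes, at) {
  readBin(bytes[at:(at + 1L)], integer(), size = 2L, endian = "little",
          signed = FALSE)
}
.read_u32 <- function(bytes, at) {
  v <- readBin(bytes[at:(at + 3L)], integer(), size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

.not_dicom <- function(msg) {
  structure(class = c("seqsort_not_dicom", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Read the header of a DICOM Part-10 file
#'
#' Parses the file meta group and the dataset up to and including PixelData.
#' Only attributes present in [dicom_dictionary()] are decoded; others are
#' skipped.  Explicit and implicit VR little endian are supported.
#'
#' @param path Path to a DICOM file.
#' @return Named list of decoded values keyed by dictionary keyword, with the
#'   transfer syntax UID in attribute `"transfer_syntax"`.  Files without the
#'   `DICM` magic raise a condition of class `seqsort_not_dicom`.
#' @export
dicom_read <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140) stop(.not_dicom(paste0("not a DICOM file: ", path)))
  bytes <- readBin(path, raw(), n = n)
  if (rawToChar(bytes[129:132]) != "DICM") {
    stop(.not_dicom(paste0("missing DICM magic: ", path)))
  }
  dict <- .dicom_dict
  out <- list()
  pos <- 133L
  explicit <- TRUE     # file meta group is always explicit VR LE
  ts <- TS_EXPLICIT_LE
  in_meta <- TRUE

  while (pos + 7L <= n) {
    group <- .read_u16(bytes, pos)
    element <- .read_u16(bytes, pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      if (!(ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))) {
        stop("unsupported transfer syntax: ", ts, call. = FALSE)
      }
      explicit <- identical(ts, TS_EXPLICIT_LE)
    }
    key <- sprintf("%04X%04X", group, element)
    if (in_meta || explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- .read_u32(bytes, pos + 8L)
        hdr <- 12L
      } else {
        len <- .read_u16(bytes, pos + 6L)
        hdr <- 8L
      }
    } else {
      len <- .read_u32(bytes, pos + 4L)
      hdr <- 8L
      vr <- dict$vr[match(key, dict$key)]
      if (is.na(vr)) vr <- "UN"
    }
    if (len == 2^32 - 1) {
      stop("undefined-length element not supported at tag ", key,
           call. = FALSE)
    }
    vstart <- pos + hdr
    if (vstart + len - 1L > n) {
      stop("truncated DICOM element at tag ", key, call. = FALSE)
    }
    value_bytes <- if (len > 0L) bytes[vstart:(vstart + len - 1L)] else raw(0L)
    if (in_meta && group == 0x0002 && element == 0x0010) {
      ts <- .decode_value("UI", value_bytes)
    }
    kw <- dict$keyword[match(key, dict$key)]
    if (!in_meta && !is.na(kw)) {
      out[[kw]] <- .decode_value(vr, value_bytes)
    }
    pos <- vstart + as.integer(len)
    if (!in_meta && group == 0x7FE0 && element == 0x0010) break
  }
  attr(out, "transfer_syntax") <- ts
  out
}
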