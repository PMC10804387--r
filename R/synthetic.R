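# Synthetic multi-vendor DICOM archive generator.
#
# Emulates the heterogeneity of a stroke brain-MRI archive: vendor-style
# free-text series descriptions, class-conditional acquisition-parameter
# distributions, per-attribute missing tags, and a configurable fraction of
# "blank" series whose text fields carry no rule keyword.  Every series is
# recorded in a ground-truth manifest so that downstream stages (rule
# labeler, classifier, evaluation) can be tested without real data.
#
# Blankness is operational: a series is blank iff neither text field
# contains a keyword of the shipped default rule set.

GEN_UID_ROOT <- "1.2.826.0.1.3680043.9.7426.2"

# keyword-free text pools (checked against default_ruleset() by tests)
BLANK_TEXT_POOL <- c("", "unnamed", "series 01", "no name", "head routine",
                     "misc", "imaging study", "brain exam", "extra data",
                     "study 2")
OTHERS_TEXT_POOL <- c("screensave", "processing results", "report images",
                      "spectro 2d")
AMBIGUOUS_TEXT_POOL <- c("MIP_COR", "mip", "MIP images")

#' Vendor-style description templates per sequence label
#'
#' Returns the description texts the generator draws from, organised by
#' vendor naming style and true label.  Compound texts ("T1 FLAIR AX",
#' "ce_mra_t1_fl3d", "t2_gre_tra") are included deliberately to exercise the
#' rule set's precedence rules.  Every template maps to its intended label
#' under [default_ruleset()] (asserted by the test suite).
#'
#' @return A data.frame with columns `vendor`, `label`, `template`.
#' @export
describe_templates <- function() {
  tpl <- .vendor_templates()
  out <- do.call(rbind, lapply(names(tpl), function(v) {
    do.call(rbind, lapply(names(tpl[[v]]), function(lab) {
      data.frame(vendor = v, label = lab, template = tpl[[v]][[lab]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

.vendor_templates <- function() {
  list(
    philips = list(
      T1 = c("T1W_SE", "sT1W_3D_TFE", "T1 FLAIR AX", "T1W_IR_tra"),
      T2 = c("T2W_TSE", "AX T2W", "T2W_TSE_tra"),
      FLAIR = c("FLAIR_longTR_AX", "T2_FLAIR_SAG", "3D_FLAIR"),
      Diffusion = c("DWI_b1000_tra", "dADC_map", "DWI_SSh"),
      MRA = c("TOF_3D_multichunk", "MRA_COW", "3D_TOF_HEAD"),
      suscgre = c("SWIp_AX", "VenoBOLD", "FFE_T2*"),
      Scout = c("Survey_SHC", "3-plane loc", "SmartBrain"),
      Perfusion = c("Perfusion_DSC", "sDSC_PERF", "PRESTO_PWI")
    ),
    siemens = list(
      T1 = c("t1_se_tra", "t1_mprage_sag_p2", "t1_space_dark-fluid"),
      T2 = c("t2_tse_tra", "t2_spc_sag"),
      FLAIR = c("t2_tirm_tra_dark-fluid", "flair_2d_tra"),
      Diffusion = c("ep2d_diff_3scan_trace", "resolve_diff_tra",
                    "ep2d_diff_b0_1000"),
      MRA = c("tof_fl3d_tra_multi-slab", "ce_mra_t1_fl3d"),
      suscgre = c("swi_3d_tra", "t2_gre_tra"),
      Scout = c("localizer", "AAHead_Scout"),
      Perfusion = c("ep2d_perf", "perfusion_tra_dsc")
    ),
    ge = list(
      T1 = c("Ax T1 SE", "SAG T1 BRAVO", "Ax T1 SPGR"),
      T2 = c("Ax T2 FRFSE", "AX T2 PROPELLER"),
      FLAIR = c("Ax T2 FLAIR", "FLAIR SAG"),
      Diffusion = c("Ax DWI", "ADC map", "DWI 1000b"),
      MRA = c("3D TOF MRA", "TOF Head"),
      suscgre = c("Ax SWAN", "GRE T2* AX"),
      Scout = c("3 Plane Loc", "Scout Brain"),
      Perfusion = c("DSC Perfusion", "PWI EPI")
    )
  )
}

#' Per-label acquisition-parameter model
#'
#' Class-conditional parameter ranges emulating typical 1.5T/3T stroke
#' protocols: spin-echo T1 (short TR/TE), fast-spin-echo T2 (long TR, TE
#' 80-120 ms), FLAIR (long TR with inversion time 2200-2800 ms), EPI
#' diffusion (b = 0/1000 s/mm^2), 3D TOF MRA (TR 20-35 ms, low flip),
#' susceptibility-weighted gradient echo (long TE for a GRE), fast
#' low-resolution scouts (thick slices, small matrix), and EPI DSC
#' perfusion.  Ranges are uniform; `NULL` means the parameter is absent for
#' that class (e.g. InversionTime outside FLAIR).
#'
#' @return Named list (per label) of parameter specifications.
#' @export
default_param_model <- function() {
  list(
    T1 = list(tr = c(400, 750), te = c(8, 20), ti = NULL, flip = c(65, 90),
              thk = c(3, 5), matrix = c(256, 320), p3d = 0.25,
              ss = list("SE", "GR"), sv = list("NONE", "SP"),
              plane = c(axial = 0.7, sagittal = 0.2, coronal = 0.1)),
    T2 = list(tr = c(3000, 6000), te = c(80, 120), ti = NULL,
              flip = c(90, 150), thk = c(3, 5), matrix = c(320, 384, 512),
              p3d = 0.1, ss = list("SE"), sv = list("SK", "SS"),
              plane = c(axial = 0.8, sagittal = 0.1, coronal = 0.1)),
    FLAIR = list(tr = c(8000, 11000), te = c(80, 140), ti = c(2200, 2800),
                 flip = c(90, 150), thk = c(3, 5), matrix = c(256, 320),
                 p3d = 0.15, ss = list(c("SE", "IR"), "IR"),
                 sv = list("SK", "SP"),
                 plane = c(axial = 0.9, sagittal = 0.1)),
    Diffusion = list(tr = c(3000, 8000), te = c(60, 110), ti = NULL,
                     flip = c(90, 90), thk = c(3, 5),
                     matrix = c(128, 192, 256), p3d = 0,
                     ss = list(c("EP", "SE")), sv = list("NONE"),
                     bval = c(0, 1000),
                     plane = c(axial = 1)),
    MRA = list(tr = c(20, 35), te = c(3, 7), ti = NULL, flip = c(18, 25),
               thk = c(0.5, 1.4), matrix = c(384, 512), p3d = 0.95,
               ss = list("GR"), sv = list(c("SP", "OSP"), "SP"),
               plane = c(axial = 0.9, coronal = 0.1)),
    suscgre = list(tr = c(27, 60), te = c(20, 40), ti = NULL,
                   flip = c(12, 20), thk = c(1.5, 3),
                   matrix = c(256, 320, 384), p3d = 0.7, ss = list("GR"),
                   sv = list("SP"), plane = c(axial = 1)),
    Scout = list(tr = c(5, 25), te = c(1.5, 5), ti = NULL, flip = c(20, 30),
                 thk = c(6, 10), matrix = c(128, 256), p3d = 0.05,
                 ss = list("GR"), sv = list("SP"),
                 plane = c(axial = 0.4, sagittal = 0.3, coronal = 0.3)),
    Perfusion = list(tr = c(1500, 2000), te = c(30, 45), ti = NULL,
                     flip = c(60, 90), thk = c(4, 6), matrix = c(96, 128),
                     p3d = 0, ss = list(c("EP", "GR")), sv = list("SS"),
                     plane = c(axial = 1)),
    Others = list(tr = c(100, 12000), te = c(1, 150), ti = NULL,
                  flip = c(5, 90), thk = c(1, 10),
                  matrix = c(64, 128, 256, 512), p3d = 0.5,
                  ss = list("SE", "GR", c("EP", "SE")), sv = list("NONE"),
                  plane = c(axial = 0.6, sagittal = 0.2, coronal = 0.2))
  )
}

.default_class_mix <- function() {
  # hospital-archive per-class series proportions (dominant classes T1, MRA,
  # Diffusion; rare Scout and Perfusion), Others excluded by default
  counts <- c(T1 = 4071, T2 = 1496, FLAIR = 1422, suscgre = 1752,
              MRA = 3763, Scout = 308, Perfusion = 55, Diffusion = 3239)
  c(counts / sum(counts), Others = 0)
}

.default_missing_rates <- function() {
  c(protocol_name = 0.10, scanning_sequence = 0.02, sequence_variant = 0.05,
    mr_acquisition_type = 0.05, image_type = 0.01, repetition_time = 0.01,
    echo_time = 0.01, flip_angle = 0.02, imaging_frequency = 0.05,
    n_phase_encoding_steps = 0.08, rows = 0.0, columns = 0.0,
    slice_thickness = 0.03, scan_options = 0.25, body_part_examined = 0.15)
}

#' Configuration for the synthetic archive generator
#'
#' @param n_series Number of series to generate.
#' @param class_mix Named proportions over the eight trainable labels plus
#'   `"Others"`; must sum to 1.  Default: hospital-style mix with no Others.
#' @param blank_fraction Fraction of series (among trainable classes) whose
#'   text fields carry no rule keyword; exactly
#'   `round(blank_fraction * n_series)` series are made blank.
#' @param missing_attr_rates Named per-attribute probabilities of tag
#'   absence.
#' @param vendor_mix Named proportions over vendor naming styles
#'   (`philips`, `siemens`, `ge`).
#' @param param_model Per-label parameter distributions; see
#'   [default_param_model()].
#' @param seed Integer seed; identical `(config, seed)` gives a
#'   byte-identical manifest.
#' @param slice_range Range of slices per series (kept small; the slice
#'   count is a classifier feature but file counts dominate fixture cost).
#' @param ambiguity_rate Fraction of non-blank series that instead receive a
#'   rule-defeating text (e.g. `"MIP"` only), exercising conflict/blank
#'   paths.  Off (0) by default.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_series,
                             class_mix = .default_class_mix(),
                             blank_fraction = 0.129,
                             missing_attr_rates = .default_missing_rates(),
                             vendor_mix = c(philips = 933, siemens = 507,
                                            ge = 67) / 1507,
                             param_model = default_param_model(),
                             seed = 1L,
                             slice_range = c(2L, 12L),
                             ambiguity_rate = 0) {
  if (n_series < 1L) stop("n_series must be >= 1", call. = FALSE)
  labs <- c(trainable_labels(), "Others")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% labs)) {
    stop("class_mix must be named with trainable labels (plus Others)",
         call. = FALSE)
  }
  full_mix <- stats::setNames(numeric(length(labs)), labs)
  full_mix[names(class_mix)] <- class_mix
  if (any(full_mix < 0) || abs(sum(full_mix) - 1) > 1e-9) {
    stop("class_mix proportions must be >= 0 and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  if (blank_fraction < 0 || blank_fraction > 1) {
    stop("blank_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(vendor_mix) - 1) > 1e-9 ||
      !all(names(vendor_mix) %in% names(.vendor_templates()))) {
    stop("vendor_mix must sum to 1 over known vendor styles", call. = FALSE)
  }
  if (any(missing_attr_rates < 0) || any(missing_attr_rates > 1)) {
    stop("missing_attr_rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_series = as.integer(n_series), class_mix = full_mix,
    blank_fraction = blank_fraction,
    missing_attr_rates = missing_attr_rates, vendor_mix = vendor_mix,
    param_model = param_model, seed = as.integer(seed),
    slice_range = as.integer(slice_range),
    ambiguity_rate = ambiguity_rate
  ), class = "generator_config")
}

#' Preset generator configurations
#'
#' `hospital_archive_config()` mirrors a large single-center archive
#' (hospital-style class mix, blank fraction 0.129, Philips-dominated vendor
#' mix); `trial_archive_config()` mirrors a smaller multi-center trial
#' archive (MRA/Diffusion-heavy mix, blank fraction 0.11, Siemens/GE-heavier
#' vendor mix).
#'
#' @param n_series Number of series.
#' @param seed Integer seed.
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
hospital_archive_config <- function(n_series, seed = 1L, ...) {
  generator_config(n_series, seed = seed, ...)
}

#' @rdname hospital_archive_config
#' @export
trial_archive_config <- function(n_series, seed = 1L, ...) {
  counts <- c(T1 = 420, T2 = 146, FLAIR = 266, suscgre = 354, MRA = 1100,
              Scout = 127, Perfusion = 64, Diffusion = 669)
  args <- list(...)
  defaults <- list(
    n_series = n_series,
    class_mix = c(counts / sum(counts), Others = 0),
    blank_fraction = 0.11,
    vendor_mix = c(philips = 57, siemens = 110, ge = 87) / 254,
    seed = seed
  )
  do.call(generator_config, utils::modifyList(defaults, args))
}

.runif_range <- function(n, range) stats::runif(n, range[1], range[2])

.largest_remainder_counts <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    add <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  stats::setNames(as.integer(counts), names(p))
}

.plane_cosines <- function(plane) {
  switch(plane,
         axial = c(1, 0, 0, 0, 1, 0),
         sagittal = c(0, 1, 0, 0, 0, -1),
         coronal = c(1, 0, 0, 0, 0, -1))
}

#' Generate a ground-truth-annotated synthetic DICOM archive
#'
#' Draws a fully-specified archive (true labels, text fields, acquisition
#' parameters, missingness) from the generator configuration; optionally
#' writes one DICOM Part-10 file per slice under `out_dir` plus the manifest
#' as `manifest.csv`.  Exactly `round(blank_fraction * n_series)` series of
#' trainable classes receive keyword-free text; `Others` series always
#' receive keyword-free text (the rule table by design carries no Others
#' keywords), so they are additionally blank.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).  May be `NULL` when
#'   `write_files = FALSE`.
#' @param write_files Write the per-slice DICOM files (default `TRUE`).  The
#'   manifest draw is identical either way.
#' @return The ground-truth manifest: a data.frame of class `gt_manifest`
#'   with the full series-record columns plus `true_label`, `vendor`,
#'   `blank`, and `dir` (relative series directory).
#' @export
generate_archive <- function(config, out_dir = NULL, write_files = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  if (write_files && is.null(out_dir)) {
    stop("out_dir is required when write_files = TRUE", call. = FALSE)
  }
  n <- config$n_series
  rules <- default_ruleset()
  tpl <- .vendor_templates()

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  labels <- rep(names(config$class_mix),
                .largest_remainder_counts(config$class_mix, n))
  labels <- sample(labels)

  eligible <- which(labels != "Others")
  n_blank <- round(config$blank_fraction * n)
  if (n_blank > length(eligible)) {
    stop("blank_fraction too large for the non-Others series count",
         call. = FALSE)
  }
  blank_designated <- sort(sample(eligible, n_blank))
  is_blank <- seq_len(n) %in% blank_designated | labels == "Others"

  n_ambig <- round(config$ambiguity_rate * (n - sum(is_blank)))
  ambig_idx <- if (n_ambig > 0) {
    sample(which(!is_blank), n_ambig)
  } else integer(0)

  vendors <- sample(names(config$vendor_mix), n, replace = TRUE,
                    prob = config$vendor_mix)

  miss <- config$missing_attr_rates
  miss_draw <- function(attr) {
    p <- if (attr %in% names(miss)) miss[[attr]] else 0
    stats::runif(n) < p
  }
  missing_flags <- sapply(c("protocol_name", "scanning_sequence",
                            "sequence_variant", "mr_acquisition_type",
                            "image_type", "repetition_time", "echo_time",
                            "flip_angle", "imaging_frequency",
                            "n_phase_encoding_steps", "rows", "columns",
                            "slice_thickness", "scan_options",
                            "body_part_examined"),
                          miss_draw)

  rows_list <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    pm <- config$param_model[[lab]]
    vend <- vendors[i]

    # --- text fields -----------------------------------------------------
    desc <- NA_character_
    prot <- NA_character_
    if (i %in% ambig_idx) {
      desc <- sample(AMBIGUOUS_TEXT_POOL, 1)
      prot <- sample(c(BLANK_TEXT_POOL, NA), 1)
    } else if (lab == "Others") {
      desc <- sample(OTHERS_TEXT_POOL, 1)
      prot <- sample(c(BLANK_TEXT_POOL, NA), 1)
    } else if (is_blank[i]) {
      desc <- sample(c(BLANK_TEXT_POOL, NA), 1)
      prot <- sample(c(BLANK_TEXT_POOL, NA), 1)
    } else {
      template <- sample(tpl[[vend]][[lab]], 1)
      if (stats::runif(1) < 0.1) {
        # keyword only in ProtocolName: exercises the fallback search
        desc <- sample(c(BLANK_TEXT_POOL, NA), 1)
        prot <- template
      } else {
        desc <- template
        prot <- sample(c(template, BLANK_TEXT_POOL), 1)
        if (missing_flags[i, "protocol_name"]) prot <- NA_character_
      }
    }

    # --- acquisition parameters ------------------------------------------
    tr <- .runif_range(1, pm$tr)
    te <- .runif_range(1, pm$te)
    ti <- if (is.null(pm$ti)) NA_real_ else .runif_range(1, pm$ti)
    flip <- .runif_range(1, pm$flip)
    thk <- .runif_range(1, pm$thk)
    mat <- sample(rep(pm$matrix, 2), 1)
    acq <- if (stats::runif(1) < pm$p3d) "3D" else "2D"
    ss <- pm$ss[[sample.int(length(pm$ss), 1)]]
    sv <- pm$sv[[sample.int(length(pm$sv), 1)]]
    freq <- (if (stats::runif(1) < 0.6) 127.73 else 63.87) +
      stats::runif(1, -0.02, 0.02)
    pe <- round(mat * stats::runif(1, 0.6, 1))
    plane <- sample(rep(names(pm$plane), 2), 1, prob = rep(pm$plane, 2))
    orient <- .plane_cosines(plane)
    bval <- if (!is.null(pm$bval)) sample(rep(pm$bval, 2), 1) else NA_real_
    img_type <- if (lab == "Diffusion" && !is.na(bval) && bval == 0) {
      c("DERIVED", "SECONDARY", "ADC")
    } else {
      c("ORIGINAL", "PRIMARY", "M", "ND")
    }
    body <- if (vend == "ge") "HEAD" else "BRAIN"
    slices <- sample(config$slice_range[1]:config$slice_range[2], 1)

    row <- list(
      series_uid = sprintf("%s.%d.%d", GEN_UID_ROOT, config$seed, i),
      series_description = desc,
      protocol_name = prot,
      scanning_sequence = ss,
      sequence_variant = sv,
      mr_acquisition_type = acq,
      image_type = img_type,
      repetition_time = round(tr, 2),
      echo_time = round(te, 2),
      flip_angle = round(flip, 1),
      imaging_frequency = round(freq, 4),
      n_phase_encoding_steps = pe,
      rows = mat,
      columns = mat,
      inversion_time = if (is.na(ti)) NA_real_ else round(ti, 1),
      slice_thickness = round(thk, 2),
      scan_options = if (lab == "FLAIR") "IR" else "NONE",
      body_part_examined = body,
      slice_num = as.integer(slices),
      image_orientation = orient,
      b_value = bval
    )

    # --- missingness ------------------------------------------------------
    for (attr in colnames(missing_flags)) {
      if (attr == "protocol_name") next  # handled with the text logic
      if (missing_flags[i, attr]) {
        row[[attr]] <- if (attr %in% LIST_COLUMNS) NULL else
          if (attr %in% NUMERIC_COLUMNS) NA_real_ else NA_character_
      }
    }
    rows_list[[i]] <- row
  }

  manifest <- data.frame(
    series_uid = vapply(rows_list, `[[`, "", "series_uid"),
    true_label = labels,
    vendor = vendors,
    blank = NA,  # filled operationally below
    dir = sprintf("series_%05d", seq_len(n)),
    series_description = vapply(rows_list, `[[`, "", "series_description"),
    protocol_name = vapply(rows_list, `[[`, "", "protocol_name"),
    scanning_sequence = I(lapply(rows_list, `[[`, "scanning_sequence")),
    sequence_variant = I(lapply(rows_list, `[[`, "sequence_variant")),
    mr_acquisition_type = vapply(rows_list, function(r)
      r$mr_acquisition_type %||% NA_character_, ""),
    image_type = I(lapply(rows_list, `[[`, "image_type")),
    repetition_time = vapply(rows_list, `[[`, 0, "repetition_time"),
    echo_time = vapply(rows_list, `[[`, 0, "echo_time"),
    flip_angle = vapply(rows_list, `[[`, 0, "flip_angle"),
    imaging_frequency = vapply(rows_list, `[[`, 0, "imaging_frequency"),
    n_phase_encoding_steps = vapply(rows_list, `[[`, 0,
                                    "n_phase_encoding_steps"),
    rows = vapply(rows_list, `[[`, 0, "rows"),
    columns = vapply(rows_list, `[[`, 0, "columns"),
    inversion_time = vapply(rows_list, `[[`, 0, "inversion_time"),
    slice_thickness = vapply(rows_list, `[[`, 0, "slice_thickness"),
    scan_options = I(lapply(rows_list, `[[`, "scan_options")),
    body_part_examined = vapply(rows_list, `[[`, "", "body_part_examined"),
    slice_num = vapply(rows_list, `[[`, 0L, "slice_num"),
    image_orientation = I(lapply(rows_list, `[[`, "image_orientation")),
    b_value = vapply(rows_list, `[[`, 0, "b_value"),
    stringsAsFactors = FALSE
  )

  # operational blank flag: no default-rule keyword in either text field
  manifest$blank <- vapply(seq_len(n), function(i) {
    length(find_keywords(manifest$series_description[i], rules)) == 0L &&
      length(find_keywords(manifest$protocol_name[i], rules)) == 0L
  }, TRUE)

  class(manifest) <- c("gt_manifest", "data.frame")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir,
                                   call. = FALSE)
    if (write_files) .write_archive_files(manifest, out_dir)
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  manifest
}

.write_archive_files <- function(manifest, out_dir) {
  pixel <- as.raw(rep(0L, 4 * 4 * 2))  # fixed 4x4 uint16 placeholder raster
  for (i in seq_len(nrow(manifest))) {
    sdir <- file.path(out_dir, manifest$dir[i])
    dir.create(sdir, showWarnings = FALSE)
    m <- manifest[i, ]
    ts <- if (i %% 7 == 0) "implicit" else "explicit"
    for (s in seq_len(m$slice_num)) {
      tags <- list(
        ImageType = m$image_type[[1]],
        SOPClassUID = MR_SOP_CLASS,
        SOPInstanceUID = sprintf("%s.%d", m$series_uid, s),
        Modality = "MR",
        Manufacturer = toupper(m$vendor),
        SeriesDescription = if (is.na(m$series_description)) NULL else
          m$series_description,
        BodyPartExamined = if (is.na(m$body_part_examined)) NULL else
          m$body_part_examined,
        ScanningSequence = m$scanning_sequence[[1]],
        SequenceVariant = m$sequence_variant[[1]],
        ScanOptions = m$scan_options[[1]],
        MRAcquisitionType = if (is.na(m$mr_acquisition_type)) NULL else
          m$mr_acquisition_type,
        SliceThickness = if (is.na(m$slice_thickness)) NULL else
          m$slice_thickness,
        RepetitionTime = if (is.na(m$repetition_time)) NULL else
          m$repetition_time,
        EchoTime = if (is.na(m$echo_time)) NULL else m$echo_time,
        InversionTime = if (is.na(m$inversion_time)) NULL else
          m$inversion_time,
        ImagingFrequency = if (is.na(m$imaging_frequency)) NULL else
          m$imaging_frequency,
        NumberOfPhaseEncodingSteps =
          if (is.na(m$n_phase_encoding_steps)) NULL else
            m$n_phase_encoding_steps,
        ProtocolName = if (is.na(m$protocol_name)) NULL else m$protocol_name,
        FlipAngle = if (is.na(m$flip_angle)) NULL else m$flip_angle,
        DiffusionBValue = if (is.na(m$b_value)) NULL else m$b_value,
        StudyInstanceUID = sprintf("%s.0", GEN_UID_ROOT),
        SeriesInstanceUID = m$series_uid,
        SeriesNumber = i,
        InstanceNumber = s,
        ImageOrientationPatient = m$image_orientation[[1]],
        SamplesPerPixel = 1L,
        PhotometricInterpretation = "MONOCHROME2",
        Rows = if (is.na(m$rows)) NULL else as.integer(m$rows),
        Columns = if (is.na(m$columns)) NULL else as.integer(m$columns),
        BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L,
        PixelRepresentation = 0L,
        PixelData = pixel
      )
      dicom_write(file.path(sdir, sprintf("slice_%03d.dcm", s)), tags,
                  transfer_syntax = ts)
    }
  }
  invisible(NULL)
}

MANIFEST_EXTRA <- c("true_label", "vendor", "blank", "dir")

#' Write / read a ground-truth manifest
#'
#' Same delimited encoding as [write_records()] (missing as `\\N`,
#' multi-values joined with `|`), with the extra ground-truth columns first.
#'
#' @param manifest A `gt_manifest`.
#' @param path File path.
#' @return `read_manifest()` returns the restored `gt_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "gt_manifest"))
  enc <- as.data.frame(manifest)
  cols <- c("series_uid", MANIFEST_EXTRA,
            setdiff(RECORD_COLUMNS, "series_uid"))
  for (col in cols) {
    is_list <- col %in% LIST_COLUMNS
    vals <- if (is_list) manifest[[col]] else as.list(manifest[[col]])
    enc[[col]] <- vapply(vals, .encode_cell, "", is_list = is_list)
  }
  utils::write.csv(enc[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw_df <- utils::read.csv(path, colClasses = "character",
                            check.names = FALSE, na.strings = character(0))
  rec_part <- raw_df[, RECORD_COLUMNS]
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(rec_part, tmp, row.names = FALSE, quote = TRUE)
  records <- read_records(tmp)
  out <- cbind(
    records[, "series_uid", drop = FALSE],
    data.frame(true_label = raw_df$true_label, vendor = raw_df$vendor,
               blank = raw_df$blank == "TRUE", dir = raw_df$dir,
               stringsAsFactors = FALSE),
    records[, setdiff(RECORD_COLUMNS, "series_uid")]
  )
  class(out) <- c("gt_manifest", "data.frame")
  out
}

#' Extract the series records embedded in a ground-truth manifest
#'
#' The manifest stores every attribute the extractor would read from the
#' generated files, so records can be obtained without materialising DICOM
#' files (the draw is identical; the file round trip is covered by
#' [scan_archive()] tests).
#'
#' @param manifest A `gt_manifest`.
#' @return A `series_records` data.frame in manifest row order.
#' @export
manifest_records <- function(manifest) {
  stopifnot(inherits(manifest, "gt_manifest"))
  as_series_records(as.data.frame(manifest)[, RECORD_COLUMNS])
}
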