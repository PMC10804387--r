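write_series <- function(dir, uid, n_files, tags = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(n_files)) {
    base <- list(
      SOPInstanceUID = sprintf("%s.%d", uid, s),
      Modality = "MR",
      SeriesInstanceUID = uid,
      InstanceNumber = s,
      ImageType = c("ORIGINAL", "PRIMARY", "M"),
      Rows = 256L, Columns = 256L,
      PixelData = as.raw(rep(0, 8))
    )
    dicom_write(file.path(dir, sprintf("f%03d.dcm", s)),
                utils::modifyList(base, tags))
  }
}

test_that("one series of 24 files yields one record with copied attributes", {
  root <- withr::local_tempdir()
  write_series(file.path(root, "s1"), "1.2.3.100", 24,
               list(RepetitionTime = 9000, EchoTime = 81,
                    SeriesDescription = "t2_tse_tra"))
  rec <- scan_archive(root)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$slice_num, 24L)
  expect_equal(rec$repetition_time, 9000)
  expect_equal(rec$echo_time, 81)
  expect_identical(rec$series_description, "t2_tse_tra")
  # InversionTime tag absent -> missing, not zero
  expect_true(is.na(rec$inversion_time))
  expect_true(is.na(rec$body_part_examined))
  expect_null(rec$scanning_sequence[[1]])
})

test_that("grouping partitions readable files and skips non-DICOM content", {
  root <- withr::local_tempdir()
  write_series(file.path(root, "a"), "1.2.3.1", 3)
  write_series(file.path(root, "b"), "1.2.3.2", 5)
  writeLines(strrep("junk ", 100), file.path(root, "notes.txt"))
  expect_warning(rec <- scan_archive(root), "skipped")
  expect_identical(nrow(rec), 2L)
  expect_identical(sum(rec$slice_num), 8L)
  expect_error(suppressWarnings(scan_archive(withr::local_tempdir())),
               "no readable DICOM")
})

test_that("extraction is order-independent", {
  root1 <- withr::local_tempdir()
  write_series(file.path(root1, "s"), "1.2.3.9", 4,
               list(SeriesDescription = "Ax DWI", RepetitionTime = 5000))
  # same files discovered under shuffled names
  root2 <- withr::local_tempdir()
  files <- list.files(root1, full.names = TRUE, recursive = TRUE)
  for (i in seq_along(files)) {
    file.copy(files[i], file.path(root2, sprintf("zz_%d.dcm", 5 - i)))
  }
  r1 <- scan_archive(root1)
  r2 <- scan_archive(root2)
  attr(r1, "files") <- attr(r2, "files") <- NULL
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("records scanned from a generated archive match the manifest field-for-field", {
  root <- withr::local_tempdir()
  cfg <- generator_config(30, blank_fraction = 0.1, seed = 3)
  manifest <- generate_archive(cfg, out_dir = root)
  rec <- suppressWarnings(scan_archive(root))  # manifest.csv is skipped
  expect_identical(nrow(rec), 30L)
  rec <- rec[match(manifest$series_uid, rec$series_uid), ]
  expected <- manifest_records(manifest)
  expect_equal(as.data.frame(rec), as.data.frame(expected),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_identical(sum(rec$slice_num), sum(manifest$slice_num))
})

test_that("records survive a CSV round trip with missingness and lists intact", {
  ds <- make_dataset(50, seed = 19)
  rec <- ds$records
  # force the tricky cases: empty string vs missing, 3-element list
  rec$series_description[1] <- ""
  rec$series_description[2] <- NA_character_
  rec$image_type[[3]] <- c("ORIGINAL", "PRIMARY", "M")
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(back$series_description[1], "")
  expect_true(is.na(back$series_description[2]))
  expect_identical(back$image_type[[3]], c("ORIGINAL", "PRIMARY", "M"))
  expect_error(read_records(withr::local_tempfile()), "not found")
})

test_that("detail descriptors derive scheme, plane and b-value", {
  expect_identical(detail_descriptors(orientation = c(1, 0, 0, 0, 1, 0))$plane,
                   "axial")
  expect_identical(
    detail_descriptors(orientation = c(0, 1, 0, 0, 0, -1))$plane, "sagittal")
  expect_identical(
    detail_descriptors(orientation = c(1, 0, 0, 0, 0, -1))$plane, "coronal")
  tilted <- c(cos(pi / 4), sin(pi / 4), 0, 0, 0, -1)
  expect_identical(detail_descriptors(orientation = tilted)$plane, "oblique")
  expect_error(detail_descriptors(orientation = c(1, 0, 0)), "six")

  rec <- list(mr_acquisition_type = NA_character_, image_orientation = NULL,
              b_value = 1000)
  d <- detail_descriptors(rec)
  expect_identical(d$scheme, "unknown")
  expect_identical(d$plane, "unknown")
  expect_equal(d$b_value, 1000)
  d2 <- detail_descriptors(list(mr_acquisition_type = "3D",
                                image_orientation = NULL,
                                b_value = NA_real_))
  expect_identical(d2$scheme, "3D")
  expect_true(is.na(d2$b_value))
})
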