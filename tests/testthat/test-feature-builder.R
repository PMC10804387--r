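test_that("numeric features are min-max normalized with the degenerate-range convention", {
  ds <- make_dataset(12, seed = 2)
  rec <- ds$records
  rec$repetition_time <- c(500, 5000, 9500, rep(5000, 9))
  rec$flip_angle <- rep(3, 12)  # constant column
  schema <- fit_schema(rec)
  expect_equal(unname(schema$numeric_features$repetition_time),
               c(500, 9500))
  x <- apply_schema(rec, schema)
  expect_equal(unname(x[1:3, "repetition_time"]), c(0, 0.5, 1))
  expect_equal(unname(x[, "flip_angle"]), rep(0, 12))
})

test_that("multi-valued attributes one-hot encode their token vocabulary", {
  ds <- make_dataset(6, seed = 4)
  rec <- ds$records
  rec$image_type <- I(list(c("ORIGINAL", "PRIMARY"), list("DERIVED")[[1]],
                           c("ORIGINAL"), c("DERIVED", "PRIMARY"),
                           c("ORIGINAL", "PRIMARY"), c("ORIGINAL")))
  schema <- fit_schema(rec)
  expect_identical(schema$vocabularies$image_type,
                   c("DERIVED", "ORIGINAL", "PRIMARY"))
  x <- apply_schema(rec, schema)
  expect_equal(unname(x[1, c("image_type=ORIGINAL", "image_type=PRIMARY",
                             "image_type=DERIVED")]), c(1, 1, 0))
  expect_equal(unname(x[2, "image_type=DERIVED"]), 1)
})

test_that("missing numerics become sentinel -1 with an indicator; unseen tokens are all-zero", {
  ds <- make_dataset(10, seed = 6)
  rec <- ds$records
  rec$echo_time[4] <- NA
  schema <- fit_schema(rec)
  x <- apply_schema(rec, schema)
  expect_equal(unname(x[4, "echo_time"]), -1)
  expect_equal(unname(x[4, "echo_time_missing"]), 1)
  expect_true(all(x[-4, "echo_time_missing"] == 0))

  rec2 <- ds$records[1, , drop = FALSE]
  rec2$body_part_examined <- "KNEE"  # unseen at fit time
  x2 <- apply_schema(rec2, schema)
  bp_cols <- grep("^body_part_examined=", colnames(x2), value = TRUE)
  expect_true(length(bp_cols) > 0 && all(x2[, bp_cols] == 0))
})

test_that("out-of-range inference values are clipped to [-0.5, 1.5]", {
  ds <- make_dataset(8, seed = 8)
  schema <- fit_schema(ds$records)
  rec <- ds$records[1, , drop = FALSE]
  rec$repetition_time <- 1e7
  rec$echo_time <- -1e7
  x <- apply_schema(rec, schema)
  expect_equal(unname(x[1, "repetition_time"]), 1.5)
  expect_equal(unname(x[1, "echo_time"]), -0.5)
})

test_that("training-data features are defined everywhere and lie in [0,1] when observed", {
  ds <- make_dataset(150, seed = 10)
  schema <- fit_schema(ds$records)
  x <- apply_schema(ds$records, schema)
  expect_false(any(is.na(x)))
  for (attr in names(schema$numeric_features)) {
    observed <- !is.na(ds$records[[attr]])
    expect_true(all(x[observed, attr] >= 0 & x[observed, attr] <= 1),
                label = attr)
    expect_true(all(x[!observed, attr] == -1), label = attr)
  }
  ind_cols <- grep("_missing$|=", colnames(x), value = TRUE)
  expect_true(all(x[, ind_cols] %in% c(0, 1)))
})

test_that("header text never leaks into the feature columns", {
  ds <- make_dataset(40, seed = 12)
  schema <- fit_schema(ds$records)
  expect_false(any(grepl("description|protocol", schema$column_order,
                         ignore.case = TRUE)))
  expect_false(any(grepl("series_uid", schema$column_order)))
})

test_that("schema application is deterministic and row-wise independent", {
  ds <- make_dataset(30, seed = 14)
  schema <- fit_schema(ds$records)
  x <- apply_schema(ds$records, schema)
  perm <- sample(nrow(ds$records))
  xp <- apply_schema(ds$records[perm, , drop = FALSE], schema)
  expect_identical(xp, {
    y <- x[perm, , drop = FALSE]
    attr(y, "schema") <- schema
    y
  })
  expect_identical(x, apply_schema(ds$records, schema))
})

test_that("schemas serialize to JSON and back; degenerate fits are handled", {
  ds <- make_dataset(20, seed = 16)
  schema <- fit_schema(ds$records)
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(schema, path)
  back <- read_schema(path)
  expect_equal(back, schema, tolerance = 1e-12)
  expect_identical(
    apply_schema(ds$records, back), apply_schema(ds$records, schema))

  expect_error(fit_schema(ds$records[0, , drop = FALSE]), "empty")
  rec <- ds$records
  rec$inversion_time <- NA_real_
  expect_warning(s2 <- fit_schema(rec), "inversion_time")
  expect_false("inversion_time" %in% s2$column_order)
})
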