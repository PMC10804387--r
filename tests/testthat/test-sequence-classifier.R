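# shared small separable fixture (computed once per test run)
cls_ds <- make_dataset(500, seed = 101, blank_fraction = 0.15)
cls_keep <- cls_ds$partition$labeled
cls_schema <- fit_schema(cls_ds$records[cls_keep, , drop = FALSE])
cls_x <- apply_schema(cls_ds$records[cls_keep, , drop = FALSE], cls_schema)
cls_labels <- cls_ds$decisions$label[cls_keep]

test_that("training preconditions are enforced", {
  expect_error(train_classifier(cls_x, rep("BLANK", nrow(cls_x))), "BLANK")
  expect_error(
    train_classifier(cls_x, rep("T1", nrow(cls_x))), "two classes")
  small <- cls_x[1:3, , drop = FALSE]
  attr(small, "schema") <- cls_schema
  expect_error(
    train_classifier(small, c("T1", "T2", "T1"),
                     train_config(cv_folds = 5)), "fewer training rows")
  expect_error(train_config(estimator_grid = c(0, 10)), "1, 1000")
  expect_error(train_config(cv_folds = 1), "cv_folds")
  x_noschema <- unclass(cls_x[, ])
  attr(x_noschema, "schema") <- NULL
  expect_error(train_classifier(x_noschema, cls_labels), "schema")
})

test_that("Others rows are excluded from training with a message", {
  labs <- cls_labels
  labs[1:5] <- "Others"
  expect_message(
    model <- train_classifier(cls_x, labs,
                              train_config(estimator_grid = c(5, 25),
                                           seed = 3)),
    "Others")
  expect_false("Others" %in% model$class_list)
  expect_identical(model$provenance$n_train, nrow(cls_x) - 5L)
})

test_that("tree-count selection maximizes CV accuracy with ties to the smaller forest", {
  cfg <- train_config(estimator_grid = c(50, 100), seed = 5)
  model <- train_classifier(cls_x, cls_labels, cfg)
  curve <- model$cv_curve
  expect_identical(curve$n_estimators, c(50L, 100L))
  best <- max(curve$mean_accuracy)
  smallest_best <- curve$n_estimators[which(curve$mean_accuracy == best)][1]
  expect_identical(model$selected_n_estimators, smallest_best)
  expect_true(model$selected_n_estimators %in% cfg$estimator_grid)
})

test_that("the selected grid point is never worse than a single tree", {
  model <- train_classifier(
    cls_x, cls_labels,
    train_config(estimator_grid = c(1, 10, 100), seed = 7))
  curve <- model$cv_curve
  sel <- curve$mean_accuracy[curve$n_estimators ==
                               model$selected_n_estimators]
  expect_gte(sel, curve$mean_accuracy[curve$n_estimators == 1L])
})

test_that("training and prediction are seed-deterministic and total", {
  cfg <- train_config(estimator_grid = c(5, 50), seed = 11)
  m1 <- train_classifier(cls_x, cls_labels, cfg)
  m2 <- train_classifier(cls_x, cls_labels, cfg)
  expect_identical(m1$selected_n_estimators, m2$selected_n_estimators)
  expect_identical(m1$cv_curve, m2$cv_curve)
  blanks <- cls_ds$records[cls_ds$partition$blank, , drop = FALSE]
  expect_identical(predict(m1, blanks), predict(m2, blanks))
  expect_true(all(predict(m1, blanks) %in% m1$class_list))

  # a record with every numeric attribute missing still gets a valid label
  ghost <- cls_ds$records[1, , drop = FALSE]
  for (col in c("repetition_time", "echo_time", "flip_angle",
                "imaging_frequency", "n_phase_encoding_steps", "rows",
                "columns", "inversion_time", "slice_thickness")) {
    ghost[[col]] <- NA_real_
  }
  expect_true(predict(m1, ghost) %in% m1$class_list)
})

test_that("a separable synthetic corpus reaches high CV accuracy", {
  model <- train_classifier(cls_x, cls_labels,
                            train_config(seed = 13))
  sel_acc <- model$cv_curve$mean_accuracy[
    model$cv_curve$n_estimators == model$selected_n_estimators]
  expect_gte(sel_acc, 0.95)
})

test_that("final labels pass rule labels through and fill blanks from the model", {
  model <- train_classifier(cls_x, cls_labels,
                            train_config(estimator_grid = c(50), seed = 17))
  dec <- cls_ds$decisions
  rec <- cls_ds$records
  final <- compose_final_labels(dec, model, rec)
  expect_false(any(final == "BLANK"))
  p <- cls_ds$partition
  expect_identical(final[p$labeled], dec$label[p$labeled])
  expect_identical(final[p$blank],
                   predict(model, rec[p$blank, , drop = FALSE]))
})

test_that("retraining concatenates datasets, refits the schema, and keeps provenance", {
  a <- make_dataset(300, seed = 23)
  b <- make_dataset(80, seed = 29, preset = "trial")
  cfg <- train_config(estimator_grid = c(25, 100), seed = 31)
  combined <- retrain_classifier(
    list(list(records = a$records, decisions = a$decisions, id = "A"),
         list(records = b$records, decisions = b$decisions, id = "B")),
    cfg)
  expect_identical(combined$provenance$dataset_ids, c("A", "B"))
  n_expected <- sum(!(a$decisions$label %in% c("BLANK", "Others"))) +
    sum(!(b$decisions$label %in% c("BLANK", "Others")))
  expect_identical(combined$provenance$n_train, n_expected)

  # one dataset alone is identical to plain training on it
  solo <- retrain_classifier(
    list(list(records = a$records, decisions = a$decisions, id = "A")), cfg)
  keep <- !(a$decisions$label %in% c("BLANK", "Others"))
  schema <- fit_schema(a$records[keep, , drop = FALSE])
  direct <- train_classifier(
    apply_schema(a$records[keep, , drop = FALSE], schema),
    a$decisions$label[keep], cfg, dataset_ids = "A")
  expect_identical(solo$selected_n_estimators, direct$selected_n_estimators)
  expect_identical(solo$cv_curve, direct$cv_curve)
  blanks_a <- a$records[a$partition$blank, , drop = FALSE]
  expect_identical(predict(solo, blanks_a), predict(direct, blanks_a))
})

test_that("models persist with a JSON provenance sidecar", {
  model <- train_classifier(cls_x, cls_labels,
                            train_config(estimator_grid = c(25), seed = 37))
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(model, path)
  back <- load_model(path)
  blanks <- cls_ds$records[cls_ds$partition$blank, , drop = FALSE]
  expect_identical(predict(back, blanks), predict(model, blanks))
  sidecar <- jsonlite::read_json(paste0(path, ".manifest.json"),
                                 simplifyVector = TRUE)
  expect_identical(as.integer(sidecar$selected_n_estimators),
                   model$selected_n_estimators)
  expect_identical(sidecar$provenance$label_source, "virtual")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(), bad)
  expect_error(load_model(bad), "not a seqsort model")
})
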