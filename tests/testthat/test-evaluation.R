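test_that("confusion matrices tally truth-by-prediction counts", {
  truth <- c("T1", "T1", "T2", "FLAIR")
  expect_identical(
    confusion_matrix(truth, truth),
    matrix(c(1L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 1L), 3, byrow = TRUE,
           dimnames = list(truth = c("FLAIR", "T1", "T2"),
                           pred = c("FLAIR", "T1", "T2"))))
  m <- confusion_matrix("T1", "T2", classes = c("T1", "T2"))
  expect_identical(m["T1", "T2"], 1L)
  expect_identical(sum(m), 1L)
  expect_error(confusion_matrix(c("a", "b"), "a"), "equal length")
  expect_error(confusion_matrix("a", "b", classes = "a"), "outside")
})

test_that("confusion, metrics and accuracy equal brute-force oracles on random data", {
  set.seed(77)
  for (rep in 1:20) {
    rc <- random_confusion(k = sample(2:6, 1), n = 200)
    expect_identical(rc$confusion,
                     oracle_confusion(rc$truth, rc$pred, rc$classes))
    metrics <- class_metrics(rc$confusion)
    for (j in seq_along(rc$classes)) {
      o <- oracle_metrics(rc$truth, rc$pred, rc$classes[j])
      expect_equal(metrics$precision[j], o[["precision"]], tolerance = 1e-12)
      expect_equal(metrics$recall[j], o[["recall"]], tolerance = 1e-12)
      expect_equal(metrics$f1[j], o[["f1"]], tolerance = 1e-12)
    }
    expect_equal(overall_accuracy(rc$confusion),
                 mean(rc$truth == rc$pred), tolerance = 1e-12)
  }
})

test_that("metric formulas reproduce hand-computed values", {
  # TP=9, FP=1, FN=0 for class A
  conf <- matrix(c(9L, 1L, 0L, 5L), 2,
                 dimnames = list(truth = c("A", "B"), pred = c("A", "B")))
  m <- class_metrics(conf)
  expect_equal(m$precision[m$class == "A"], 0.9)
  expect_equal(m$recall[m$class == "A"], 1.0)
  expect_equal(m$f1[m$class == "A"], 2 * 0.9 / 1.9)
  # P = R = 0.8 is an F1 fixed point
  conf2 <- matrix(c(8L, 2L, 2L, 8L), 2,
                  dimnames = list(truth = c("A", "B"), pred = c("A", "B")))
  m2 <- class_metrics(conf2)
  expect_equal(m2$f1, c(0.8, 0.8))
})

test_that("undefined metrics are NA and excluded (with a count) from macro averages", {
  conf <- matrix(0L, 3, 3, dimnames = list(truth = c("A", "B", "C"),
                                           pred = c("A", "B", "C")))
  conf["A", "A"] <- 5L
  conf["B", "A"] <- 1L
  # class C never true and never predicted: all three metrics undefined
  m <- class_metrics(conf)
  expect_true(all(is.na(m[m$class == "C", c("precision", "recall", "f1")])))
  # class B true once but never predicted: recall 0 defined, precision NA
  expect_true(is.na(m$precision[m$class == "B"]))
  expect_identical(m$recall[m$class == "B"], 0)

  rep <- seqsort:::.build_report(c("A", "A", "B"), c("A", "A", "A"),
                                 classes = c("A", "B", "C"))
  expect_identical(rep$macro$precision$n_undefined, 2L)
  expect_identical(rep$macro$f1$n_undefined, 2L)
  expect_false(is.na(rep$macro$precision$mean))
})

test_that("micro averages collapse to overall accuracy and metrics are permutation-invariant", {
  set.seed(5)
  rc <- random_confusion(5, 300)
  expect_equal(seqsort:::.micro_average(rc$confusion)$precision,
               overall_accuracy(rc$confusion), tolerance = 1e-15)
  perm <- sample(length(rc$truth))
  expect_identical(confusion_matrix(rc$truth[perm], rc$pred[perm],
                                    rc$classes), rc$confusion)
  expect_error(overall_accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("the comparative report scores rules on non-blanks and models on blanks", {
  ds <- make_dataset(250, seed = 41)
  p <- ds$partition
  truth <- ds$manifest$true_label
  perfect_ml <- truth[p$blank]
  reports <- evaluate_system(truth, ds$decisions,
                             ml_virtual_pred = perfect_ml)
  expect_identical(reports$rule$blank_count, length(p$blank))
  expect_identical(reports$rule$n, length(p$labeled))
  expect_equal(reports$rule$overall_accuracy, 1.0)
  defined_f1 <- reports$rule$per_class$f1
  expect_true(all(defined_f1[!is.na(defined_f1)] == 1.0))
  expect_equal(reports$ml_virtual$overall_accuracy, 1.0)
  expect_null(reports$ml_human)

  # full-length prediction vectors are subset to the blank partition
  full <- character(length(truth))
  full[p$blank] <- perfect_ml
  full[p$labeled] <- "T1"
  r2 <- evaluate_system(truth, ds$decisions, ml_virtual_pred = full)
  expect_equal(r2$ml_virtual$overall_accuracy, 1.0)
  expect_error(evaluate_system(truth, ds$decisions,
                               ml_virtual_pred = "T1"), "length")
})

test_that("reports write per-class and confusion CSVs", {
  ds <- make_dataset(100, seed = 43)
  reports <- evaluate_system(ds$manifest$true_label, ds$decisions)
  stem <- file.path(withr::local_tempdir(), "rule")
  write_report(reports$rule, stem)
  per_class <- utils::read.csv(paste0(stem, "_per_class.csv"))
  expect_identical(sort(per_class$class),
                   sort(reports$rule$per_class$class))
  conf <- utils::read.csv(paste0(stem, "_confusion.csv"))
  expect_identical(sum(conf[, -1]), as.integer(reports$rule$n))
})
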