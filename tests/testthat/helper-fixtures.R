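# Shared fixtures, all generated in code at test time.

# manifest + records + rule decisions for a synthetic archive (no files)
make_dataset <- function(n, seed, preset = c("hospital", "trial"), ...) {
  preset <- match.arg(preset)
  cfg_fun <- if (preset == "trial") trial_archive_config else
    hospital_archive_config
  cfg <- cfg_fun(n, seed = seed, ...)
  manifest <- generate_archive(cfg, write_files = FALSE)
  records <- manifest_records(manifest)
  decisions <- label_dataset(records)
  list(manifest = manifest, records = records, decisions = decisions,
       partition = attr(decisions, "partition"))
}

# a single-row record list for label_series()
text_record <- function(description, protocol = NA_character_) {
  list(series_description = description, protocol_name = protocol)
}

# random confusion matrix with k classes and n observations
random_confusion <- function(k, n) {
  classes <- paste0("C", seq_len(k))
  truth <- sample(classes, n, replace = TRUE)
  pred <- sample(classes, n, replace = TRUE)
  list(truth = truth, pred = pred, classes = classes,
       confusion = confusion_matrix(truth, pred, classes))
}

# brute-force metric oracles (naive loops, independent of the package path)
oracle_confusion <- function(truth, pred, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(truth = classes, pred = classes))
  for (i in seq_along(truth)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

oracle_metrics <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else
    NA_real_
  c(precision = p, recall = r, f1 = f1)
}
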