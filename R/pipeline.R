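# Pipeline orchestration: pre-processing -> training preparation ->
# training, plus inference, evaluation, sorting and retraining, as callable
# modes with on-disk artifacts.  Every run writes a small JSON run manifest
# (mode, seed, rule-set hash, model provenance) so a run can be replayed;
# artifact files contain no timestamps, so replaying a seeded run
# reproduces them byte for byte.

ruleset_hash <- function(rules) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  save_ruleset(rules, tmp)
  s <- paste(readLines(tmp), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' @param mode One of `"simulate"`, `"extract"`, `"label"`, `"train"`,
#'   `"infer"`, `"evaluate"`, `"sort"`, `"retrain"`.
#' @param input Input directory (archive or prior artifact directory) or,
#'   for `retrain`, a character vector of artifact directories.
#' @param out Output directory (created if needed).
#' @param rules Path to a rule file, or `"default"`.
#' @param model Path to a persisted model (`infer`, `sort`).
#' @param seed Integer seed, recorded in every run manifest.
#' @param n_series,blank_fraction,preset Generator settings (`simulate`):
#'   preset is `"hospital"` or `"trial"`.
#' @param move For `sort`: move files instead of the default copy.
#' @param full_sweep For `train`/`retrain`: exhaustive 1..1000 tree sweep.
#' @return A `run_config` list.
#' @export
run_config <- function(mode, input = NULL, out = NULL, rules = "default",
                       model = NULL, seed = 1L, n_series = 200L,
                       blank_fraction = NULL,
                       preset = c("hospital", "trial"), move = FALSE,
                       full_sweep = FALSE) {
  modes <- c("simulate", "extract", "label", "train", "infer", "evaluate",
             "sort", "retrain")
  if (!(mode %in% modes)) {
    stop("mode must be one of: ", paste(modes, collapse = ", "),
         call. = FALSE)
  }
  preset <- match.arg(preset)
  structure(list(mode = mode, input = input, out = out, rules = rules,
                 model = model, seed = as.integer(seed),
                 n_series = as.integer(n_series),
                 blank_fraction = blank_fraction, preset = preset,
                 move = isTRUE(move), full_sweep = isTRUE(full_sweep)),
            class = "run_config")
}

.resolve_rules <- function(spec) {
  if (inherits(spec, "seq_ruleset")) return(spec)
  if (is.null(spec) || identical(spec, "default")) return(default_ruleset())
  load_ruleset(spec)
}

.write_run_manifest <- function(out, config, rules, extra = list()) {
  jsonlite::write_json(
    c(list(mode = config$mode, seed = config$seed,
           ruleset_hash = ruleset_hash(rules)), extra),
    file.path(out, paste0(config$mode, "_run.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read back a decisions CSV written by the pipeline
#'
#' @param path Path to `decisions.csv`.
#' @return A `label_decisions` data.frame with its blank/labeled partition
#'   attribute restored.
#' @export
read_decisions <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    series_uid = "character", label = "character",
    source_attribute = "character", matched_keywords = "character",
    rule_id = "integer"))
  blank <- which(df$label == "BLANK")
  attr(df, "partition") <- list(labeled = setdiff(seq_len(nrow(df)), blank),
                                blank = blank)
  class(df) <- c("label_decisions", class(df))
  df
}

#' Run one pipeline mode
#'
#' Each mode reads its inputs, runs the corresponding package functions,
#' and writes its artifacts under `config$out`:
#' \describe{
#'   \item{simulate}{synthetic archive + `manifest.csv`}
#'   \item{extract}{`records.csv` from a DICOM archive}
#'   \item{label}{`decisions.csv` (rule labels with audit columns)}
#'   \item{train}{`model.rds` + JSON manifest, from records + decisions}
#'   \item{infer}{`predictions.csv` (rule labels passed through, blanks
#'     filled by the model)}
#'   \item{evaluate}{per-class/confusion CSVs against `manifest.csv` truth}
#'   \item{sort}{copies (default) or moves series files into per-label
#'     directories}
#'   \item{retrain}{`model.rds` retrained on several artifact directories}
#' }
#'
#' @param config A [run_config()].
#' @return Mode-dependent main result, invisibly (e.g. the manifest,
#'   records, decisions, model, predictions data.frame, or report list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rules <- .resolve_rules(config$rules)
  out <- config$out
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  result <- switch(
    config$mode,
    simulate = {
      gc_fun <- if (config$preset == "trial") trial_archive_config else
        hospital_archive_config
      args <- list(n_series = config$n_series, seed = config$seed)
      if (!is.null(config$blank_fraction)) {
        args$blank_fraction <- config$blank_fraction
      }
      cfg <- do.call(gc_fun, args)
      generate_archive(cfg, out_dir = out)
    },
    extract = {
      records <- scan_archive(config$input)
      write_records(records, file.path(out, "records.csv"))
      records
    },
    label = {
      records <- read_records(file.path(config$input, "records.csv"))
      decisions <- label_dataset(records, rules)
      utils::write.csv(as.data.frame(decisions),
                       file.path(out, "decisions.csv"), row.names = FALSE)
      decisions
    },
    train = {
      records <- read_records(file.path(config$input, "records.csv"))
      decisions <- read_decisions(file.path(config$input, "decisions.csv"))
      keep <- !(decisions$label %in% c("BLANK", "Others"))
      schema <- fit_schema(records[keep, , drop = FALSE])
      x <- apply_schema(records[keep, , drop = FALSE], schema)
      model <- train_classifier(
        x, decisions$label[keep],
        train_config(seed = config$seed, full_sweep = config$full_sweep),
        dataset_ids = config$input)
      save_model(model, file.path(out, "model.rds"))
      model
    },
    infer = {
      model <- load_model(config$model)
      records <- read_records(file.path(config$input, "records.csv"))
      dec_path <- file.path(config$input, "decisions.csv")
      labels <- if (file.exists(dec_path)) {
        compose_final_labels(read_decisions(dec_path), model, records)
      } else {
        predict(model, records)
      }
      pred <- data.frame(series_uid = records$series_uid, label = labels,
                         stringsAsFactors = FALSE)
      utils::write.csv(pred, file.path(out, "predictions.csv"),
                       row.names = FALSE)
      pred
    },
    evaluate = {
      manifest <- read_manifest(file.path(config$input, "manifest.csv"))
      decisions <- read_decisions(file.path(config$input, "decisions.csv"))
      ord <- match(decisions$series_uid, manifest$series_uid)
      if (anyNA(ord)) {
        stop("decisions contain series absent from the truth manifest",
             call. = FALSE)
      }
      manifest <- manifest[ord, , drop = FALSE]
      pred_path <- file.path(config$input, "predictions.csv")
      mlv <- if (file.exists(pred_path)) {
        pred <- utils::read.csv(pred_path, colClasses = "character")
        stopifnot(identical(pred$series_uid, manifest$series_uid))
        pred$label
      } else NULL
      reports <- evaluate_system(manifest$true_label, decisions,
                                 ml_virtual_pred = mlv)
      if (!is.null(reports$rule)) {
        write_report(reports$rule, file.path(out, "rule"))
      }
      if (!is.null(reports$ml_virtual)) {
        write_report(reports$ml_virtual, file.path(out, "ml_virtual"))
      }
      reports
    },
    sort = {
      records <- scan_archive(config$input)
      files <- attr(records, "files")
      decisions <- label_dataset(records, rules)
      labels <- if (!is.null(config$model)) {
        compose_final_labels(decisions, load_model(config$model), records)
      } else {
        decisions$label
      }
      dirs <- c(trainable_labels(),
                if (any(labels == "BLANK")) "BLANK",
                if (any(labels == "Others")) "Others")
      for (d in dirs) {
        dir.create(file.path(out, d), recursive = TRUE,
                   showWarnings = FALSE)
      }
      for (i in seq_len(nrow(records))) {
        dest <- file.path(out, labels[i], records$series_uid[i])
        dir.create(dest, recursive = TRUE, showWarnings = FALSE)
        src <- files[[records$series_uid[i]]]
        file.copy(src, dest)
        if (config$move) file.remove(src)
      }
      data.frame(series_uid = records$series_uid, label = labels,
                 stringsAsFactors = FALSE)
    },
    retrain = {
      datasets <- lapply(config$input, function(dir) {
        list(records = read_records(file.path(dir, "records.csv")),
             decisions = read_decisions(file.path(dir, "decisions.csv")),
             id = dir)
      })
      model <- retrain_classifier(
        datasets,
        train_config(seed = config$seed, full_sweep = config$full_sweep))
      save_model(model, file.path(out, "model.rds"))
      model
    }
  )
  if (!is.null(out)) {
    extra <- list()
    if (inherits(result, "seq_model")) {
      extra$model_provenance <- result$provenance
    }
    .write_run_manifest(out, config, rules, extra)
  }
  invisible(result)
}
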