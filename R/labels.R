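#' Sequence-type label vocabulary
#'
#' The closed label vocabulary used throughout the package.  Eight trainable
#' pulse-sequence families plus two bookkeeping values: `"Others"` (series a
#' human would exclude from training, e.g. spectroscopy or screenshots) and
#' `"BLANK"` (series the rule-based labeler could not decide; filled in later
#' by the classifier).  `"Others"` and `"BLANK"` are never training classes.
#'
#' @return `sequence_labels()` returns all ten label strings;
#'   `trainable_labels()` returns the eight classifier classes.
#' @examples
#' trainable_labels()
#' @export
sequence_labels <- function() {
  c(trainable_labels(), "Others", "BLANK")
}

#' @rdname sequence_labels
#' @export
trainable_labels <- function() {
  c("T1", "T2", "FLAIR", "suscgre", "MRA", "Scout", "Perfusion", "Diffusion")
}

is_sequence_label <- function(x) {
  is.character(x) && all(x %in% sequence_labels())
}

assert_labels <- function(x, what = "labels") {
  bad <- setdiff(unique(x), sequence_labels())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s: %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
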