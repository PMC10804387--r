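# Two-step rule-based labeler: search SeriesDescription for rule-table
# keywords; only if that yields nothing, search ProtocolName.  Multi-keyword
# hits are resolved by the rule set's precedence rules; anything unresolvable
# is BLANK and left for the classifier, never guessed.

#' Normalize free text for keyword matching
#'
#' Lower-cases and unifies the separator characters vendors use in protocol
#' text (space, underscore, hyphen, slash, dot) into single spaces.
#'
#' @param text A character scalar (`NA` allowed).
#' @return Normalized string; `""` for `NA` input.
#' @export
normalize_text <- function(text) {
  if (length(text) != 1L || is.na(text)) return("")
  s <- tolower(text)
  s <- gsub("[ _/.-]+", " ", s)
  trimws(s)
}

#' Find rule-table keywords in one text field
#'
#' Matching is substring-based on the normalized text (vendor strings
#' concatenate keywords, e.g. `"ep2d_diff"`), except for keywords the rule
#' set marks token-only, which must appear as a whole delimiter-bounded
#' token.  Excluded keywords are never returned.
#'
#' @param text Character scalar, `NA`, or missing text.
#' @param rules A [ruleset()].
#' @return Character vector of matched keywords (longest first), with the
#'   corresponding labels as names.  Empty for empty/missing text.
#' @examples
#' find_keywords("SWI_MIP_COR", default_ruleset())   # "swi"; "mip" excluded
#' @export
find_keywords <- function(text, rules) {
  stopifnot(inherits(rules, "seq_ruleset"))
  s <- normalize_text(text)
  if (!nzchar(s)) return(character(0))
  kws <- setdiff(names(rules$keywords), rules$exclusions)
  tokens <- strsplit(s, " ", fixed = TRUE)[[1]]
  hit <- vapply(kws, function(k) {
    if (k %in% rules$token_only) k %in% tokens
    else grepl(k, s, fixed = TRUE)
  }, TRUE)
  matched <- kws[hit]
  matched <- matched[order(-nchar(matched), matched)]
  labs <- unname(rules$keywords[matched])
  stats::setNames(unname(matched), labs)
}

#' Resolve a multi-keyword candidate set to one label
#'
#' A single distinct candidate label wins outright.  Otherwise precedence
#' rules are tried in order; the first rule whose pattern is a subset of the
#' candidate set names the winner.  If no rule applies the decision is
#' `"BLANK"` with a warning: an unresolved conflict is recoverable by the
#' classifier, a wrong virtual label is not.
#'
#' @param candidates Character vector of candidate labels (typically the
#'   `names()` of a [find_keywords()] result); must be non-empty.
#' @param rules A [ruleset()].
#' @return List with `label` and `rule_id` (precedence rule index used, or
#'   `NA`).
#' @export
resolve_conflict <- function(candidates, rules) {
  stopifnot(inherits(rules, "seq_ruleset"), length(candidates) > 0L)
  labs <- unique(candidates)
  if (length(labs) == 1L) return(list(label = labs, rule_id = NA_integer_))
  for (i in seq_along(rules$precedence)) {
    p <- rules$precedence[[i]]
    if (all(p$pattern %in% labs)) {
      return(list(label = p$winner, rule_id = i))
    }
  }
  warning("unresolved keyword conflict {", paste(labs, collapse = ", "),
          "}; deferring to BLANK", call. = FALSE)
  list(label = "BLANK", rule_id = NA_integer_)
}

#' Label one series from its header text
#'
#' Step 1 searches `SeriesDescription`; only if it is missing, empty, or
#' yields no keyword does step 2 search `ProtocolName`.  No keyword anywhere
#' means `"BLANK"`.
#'
#' @param record A single-row series-record data.frame (see
#'   [scan_archive()]), or anything with `series_description` and
#'   `protocol_name` entries.
#' @param rules A [ruleset()].
#' @return A list of class `label_decision`: `label`, `source_attribute`
#'   (`"series_description"`, `"protocol_name"` or `"none"`),
#'   `matched_keywords`, `rule_id`.
#' @export
label_series <- function(record, rules) {
  desc <- record$series_description
  prot <- record$protocol_name
  if (is.list(desc)) desc <- desc[[1]]
  if (is.list(prot)) prot <- prot[[1]]

  hits <- find_keywords(desc %||% NA_character_, rules)
  source <- "series_description"
  if (length(hits) == 0L) {
    hits <- find_keywords(prot %||% NA_character_, rules)
    source <- "protocol_name"
  }
  if (length(hits) == 0L) {
    out <- list(label = "BLANK", source_attribute = "none",
                matched_keywords = character(0), rule_id = NA_integer_)
  } else {
    res <- resolve_conflict(names(hits), rules)
    if (res$label == "BLANK") {
      out <- list(label = "BLANK", source_attribute = "none",
                  matched_keywords = unname(hits), rule_id = NA_integer_)
    } else {
      out <- list(label = res$label, source_attribute = source,
                  matched_keywords = unname(hits), rule_id = res$rule_id)
    }
  }
  class(out) <- "label_decision"
  out
}

#' Convenience: label a single free-text string
#'
#' @param text Character scalar.
#' @param rules A [ruleset()].
#' @return A single label string (possibly `"BLANK"`).
#' @export
label_text <- function(text, rules = default_ruleset()) {
  label_series(list(series_description = text, protocol_name = NA_character_),
               rules)$label
}

#' Label every series of a dataset and partition into labeled vs blank
#'
#' @param records A series-record data.frame from [scan_archive()] or
#'   [read_records()].
#' @param rules A [ruleset()].
#' @return A data.frame of class `label_decisions` with columns `series_uid`,
#'   `label`, `source_attribute`, `matched_keywords` (keywords joined with
#'   `"+"`), `rule_id`; the index partition is in attribute `partition`, a
#'   list with integer vectors `labeled` and `blank` (exact complements).
#' @export
label_dataset <- function(records, rules = default_ruleset()) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  n <- nrow(records)
  label <- character(n)
  source <- character(n)
  kws <- character(n)
  rule_id <- integer(n)
  for (i in seq_len(n)) {
    d <- label_series(records[i, , drop = FALSE], rules)
    label[i] <- d$label
    source[i] <- d$source_attribute
    kws[i] <- paste(d$matched_keywords, collapse = "+")
    rule_id[i] <- d$rule_id
  }
  out <- data.frame(
    series_uid = records$series_uid,
    label = label,
    source_attribute = source,
    matched_keywords = kws,
    rule_id = rule_id,
    stringsAsFactors = FALSE
  )
  blank <- which(label == "BLANK")
  attr(out, "partition") <- list(labeled = setdiff(seq_len(n), blank),
                                 blank = blank)
  class(out) <- c("label_decisions", class(out))
  out
}
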