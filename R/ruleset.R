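# Rule table: keyword -> label mapping plus exclusions and precedence rules.
#
# The shipped default table is this package's reconstruction of a working
# stroke-MRI rule table from keywords in common vendor protocol text; sites
# with local naming conventions are expected to edit the rule file.

#' Construct a rule set for the rule-based labeler
#'
#' A rule set holds the keyword table (keyword -> sequence label), the
#' exclusion list (tokens that must never drive a decision, e.g. `"mip"`,
#' which appears in maximum-intensity-projection reconstructions of several
#' sequence families), and ordered precedence rules that resolve multi-label
#' keyword hits (e.g. a "T1 FLAIR" description hits both T1 and FLAIR and is
#' classed as T1).
#'
#' @param keywords Named character vector: names are keywords (matched on
#'   normalized text), values are labels from [trainable_labels()] or
#'   `"Others"`.  Never `"BLANK"`.
#' @param exclusions Character vector of excluded keywords.
#' @param precedence List of lists with elements `pattern` (character vector
#'   of labels) and `winner` (single label, member of `pattern`).  Rules are
#'   tried in order; a rule applies when its pattern is a subset of the
#'   candidate label set.
#' @param token_only Character vector of keywords that match only as whole
#'   delimiter-bounded tokens (short, collision-prone keywords like `"loc"`);
#'   all other keywords match as substrings of the normalized text.
#' @return An object of class `seq_ruleset`.
#' @seealso [default_ruleset()], [load_ruleset()], [save_ruleset()]
#' @export
ruleset <- function(keywords, exclusions = character(0),
                    precedence = list(), token_only = character(0)) {
  if (length(keywords) == 0L || is.null(names(keywords)) ||
      any(!nzchar(names(keywords)))) {
    stop("keywords must be a non-empty named character vector", call. = FALSE)
  }
  kw <- vapply(names(keywords), normalize_text, "")
  if (any(!nzchar(kw))) {
    stop("keyword empty after normalization: ",
         paste(sQuote(names(keywords)[!nzchar(kw)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(kw)) {
    stop("duplicate keyword after normalization: ",
         paste(unique(kw[duplicated(kw)]), collapse = ", "), call. = FALSE)
  }
  labels <- unname(keywords)
  bad <- !(labels %in% setdiff(sequence_labels(), "BLANK"))
  if (any(bad)) {
    stop("invalid label for keyword ",
         paste(sprintf("'%s' -> '%s'", kw[bad], labels[bad]), collapse = ", "),
         " (BLANK and unknown labels are not allowed)", call. = FALSE)
  }
  names(labels) <- kw
  for (i in seq_along(precedence)) {
    p <- precedence[[i]]
    if (!is.list(p) || is.null(p$pattern) || is.null(p$winner) ||
        length(p$winner) != 1L || !(p$winner %in% p$pattern) ||
        !all(p$pattern %in% setdiff(sequence_labels(), "BLANK"))) {
      stop(sprintf(
        "precedence rule %d invalid: winner must be one label inside its pattern",
        i), call. = FALSE)
    }
  }
  # exclusions/token_only are sets; store sorted so that save/load round
  # trips compare equal regardless of listing order
  structure(
    list(
      keywords = labels,
      exclusions = sort(vapply(exclusions, normalize_text, "",
                               USE.NAMES = FALSE)),
      precedence = precedence,
      token_only = sort(vapply(token_only, normalize_text, "",
                               USE.NAMES = FALSE))
    ),
    class = "seq_ruleset"
  )
}

#' @export
print.seq_ruleset <- function(x, ...) {
  cat(sprintf("<seq_ruleset> %d keywords, %d exclusions, %d precedence rules\n",
              length(x$keywords), length(x$exclusions), length(x$precedence)))
  for (lab in unique(unname(x$keywords))) {
    cat(sprintf("  %-9s: %s\n", lab,
                paste(names(x$keywords)[x$keywords == lab], collapse = ", ")))
  }
  invisible(x)
}

#' Default rule table for stroke brain MRI
#'
#' Keywords commonly found in brain-MRI `SeriesDescription` / `ProtocolName`
#' strings across Philips, Siemens, and GE naming styles.  Precedence rules
#' encode the compound-text conventions: T1-FLAIR counts as T1, T2-FLAIR as
#' FLAIR, contrast-enhanced MRA texts carrying "t1" as MRA, and "t2*"
#' gradient-echo texts (which also contain the bare "t2") as suscgre.
#' `"mip"` is excluded: MIP reconstructions occur in MRA as well as suscgre
#' series, so the token is ambiguous by construction.
#'
#' @return A `seq_ruleset`.
#' @examples
#' label_text("ep2d_diff_3scan_trace", default_ruleset())
#' @export
default_ruleset <- function() {
  ruleset(
    keywords = c(
      dw = "Diffusion", dwi = "Diffusion", diff = "Diffusion",
      adc = "Diffusion", diffusion = "Diffusion",
      t1 = "T1", mprage = "T1", spgr = "T1", bravo = "T1",
      t2 = "T2", tse = "T2", frfse = "T2",
      flair = "FLAIR", "dark fluid" = "FLAIR", tirm = "FLAIR",
      mra = "MRA", tof = "MRA", angio = "MRA", cow = "MRA",
      swi = "suscgre", gre = "suscgre", susc = "suscgre",
      swan = "suscgre", "t2*" = "suscgre", veno = "suscgre",
      scout = "Scout", localizer = "Scout", survey = "Scout",
      loc = "Scout", "3 plane" = "Scout", smartbrain = "Scout",
      perf = "Perfusion", perfusion = "Perfusion", dsc = "Perfusion",
      dce = "Perfusion", pwi = "Perfusion"
    ),
    exclusions = c("mip"),
    precedence = list(
      list(pattern = c("T1", "FLAIR"), winner = "T1"),
      list(pattern = c("T2", "FLAIR"), winner = "FLAIR"),
      list(pattern = c("T1", "MRA"), winner = "MRA"),
      list(pattern = c("suscgre", "MRA"), winner = "suscgre"),
      list(pattern = c("T2", "suscgre"), winner = "suscgre"),
      list(pattern = c("T2", "Diffusion"), winner = "Diffusion"),
      list(pattern = c("T2", "Perfusion"), winner = "Perfusion"),
      list(pattern = c("T1", "Perfusion"), winner = "Perfusion"),
      list(pattern = c("T2", "Scout"), winner = "Scout"),
      list(pattern = c("T1", "Scout"), winner = "Scout")
    ),
    token_only = c("loc", "dw", "cow")
  )
}

#' Read / write a rule set in the plain-text rule-file format
#'
#' The rule file is a line-oriented text format with three sections:
#' ```
#' [keywords]
#' dwi = Diffusion
#' loc = Scout ; token
#' [exclusions]
#' mip
#' [precedence]
#' T1 + FLAIR -> T1
#' ```
#' `; token` marks a keyword that matches only as a whole token.  Blank lines
#' and lines starting with `#` are ignored.  `save_ruleset()` writes a
#' canonical form; `load_ruleset(save_ruleset(...))` reproduces the rule set
#' exactly.
#'
#' @param path File path.
#' @param rules A `seq_ruleset`.
#' @return `load_ruleset()` returns a `seq_ruleset`; `save_ruleset()` returns
#'   `path` invisibly.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kws <- character(0)
  token_only <- character(0)
  exclusions <- character(0)
  precedence <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl("^\\[.+\\]$", line)) {
      section <- tolower(gsub("\\[|\\]", "", line))
      if (!section %in% c("keywords", "exclusions", "precedence")) {
        stop(sprintf("rule file line %d: unknown section '%s'", i, section),
             call. = FALSE)
      }
      next
    }
    if (section == "keywords") {
      m <- regmatches(line, regexec("^(.*?)=([^;]*)(;(.*))?$", line))[[1]]
      if (length(m) == 0L || !nzchar(trimws(m[2]))) {
        stop(sprintf("rule file line %d: expected 'keyword = Label': %s",
                     i, line), call. = FALSE)
      }
      kw <- trimws(m[2]); lab <- trimws(m[3])
      kws[kw] <- lab
      if (nzchar(trimws(m[5] %||% "")) && trimws(m[5]) == "token") {
        token_only <- c(token_only, kw)
      }
    } else if (section == "exclusions") {
      exclusions <- c(exclusions, line)
    } else if (section == "precedence") {
      m <- regmatches(line, regexec("^(.*)->(.*)$", line))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("rule file line %d: expected 'A + B -> A': %s", i, line),
             call. = FALSE)
      }
      pattern <- trimws(strsplit(m[2], "+", fixed = TRUE)[[1]])
      precedence[[length(precedence) + 1L]] <-
        list(pattern = pattern, winner = trimws(m[3]))
    } else {
      stop(sprintf("rule file line %d: content before any section: %s",
                   i, line), call. = FALSE)
    }
  }
  ruleset(kws, exclusions = exclusions, precedence = precedence,
          token_only = token_only)
}

#' @rdname load_ruleset
#' @export
save_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "seq_ruleset"))
  out <- c("# seqsort rule table", "[keywords]")
  for (i in seq_along(rules$keywords)) {
    kw <- names(rules$keywords)[i]
    line <- sprintf("%s = %s", kw, rules$keywords[[i]])
    if (kw %in% rules$token_only) line <- paste(line, "; token")
    out <- c(out, line)
  }
  out <- c(out, "[exclusions]", rules$exclusions, "[precedence]")
  for (p in rules$precedence) {
    out <- c(out, sprintf("%s -> %s", paste(p$pattern, collapse = " + "),
                          p$winner))
  }
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
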