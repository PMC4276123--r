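#' Case-record corpora of acupoints and diagnostic patterns
#'
#' A corpus is a collection of treatment case records. Each case pairs the
#' acupoints prescribed for a disorder with the diagnostic pattern terms
#' implicated for that disorder. Acupoint codes follow the WHO-style meridian
#' alphanumeric convention (e.g. \code{"CV4"}, \code{"ST36"}); validation is
#' by the code shape only, no lookup of the classical point list is attempted.
#'
#' @param cases list of case records, each a list with elements
#'   \code{case_id}, \code{subchapter}, \code{acupoints} (character vector)
#'   and \code{patterns} (character vector).
#' @param canonicalized logical; have raw pattern terms been replaced by
#'   canonical patterns of a taxonomy?
#' @return An object of class \code{acu_corpus}: a list with elements
#'   \code{cases} and \code{canonicalized}.
#' @seealso [load_corpus()], [canonicalize_corpus()], [summarize_corpus()]
#' @export
new_corpus <- function(cases = list(), canonicalized = FALSE) {
  corpus <- structure(list(cases = cases, canonicalized = canonicalized),
                      class = "acu_corpus")
  validate_corpus(corpus)
  corpus
}

ACUPOINT_CODE_RE <- "^[A-Z]{2,3}[0-9]{1,2}$"

validate_corpus <- function(corpus) {
  ids <- vapply(corpus$cases, function(cs) as.character(cs$case_id)[1],
                character(1))
  if (any(is.na(ids) | !nzchar(ids)))
    stop("every case needs a nonempty case_id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate case_id: ", paste(dup, collapse = ", "), call. = FALSE)
  for (cs in corpus$cases) {
    if (length(cs$acupoints) == 0L)
      stop("case '", cs$case_id, "': empty acupoint list", call. = FALSE)
    if (length(cs$patterns) == 0L)
      stop("case '", cs$case_id, "': empty pattern list", call. = FALSE)
    bad <- cs$acupoints[!grepl(ACUPOINT_CODE_RE, cs$acupoints)]
    if (length(bad))
      stop("case '", cs$case_id, "': malformed acupoint code: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(corpus)
}

#' @export
print.acu_corpus <- function(x, ...) {
  cat("<acu_corpus> ", length(x$cases), " cases, canonicalized=",
      x$canonicalized, "\n", sep = "")
  invisible(x)
}

new_case <- function(case_id, subchapter, acupoints, patterns) {
  list(case_id = as.character(case_id),
       subchapter = as.character(subchapter),
       acupoints = as.character(acupoints),
       patterns = as.character(patterns))
}

#' Read a corpus of case records
#'
#' Supports two dialects. JSON-Lines: one object per line with keys
#' \code{case_id}, \code{subchapter}, \code{acupoints} (array),
#' \code{patterns} (array). TSV: header row required, columns
#' \code{case_id}, \code{subchapter}, \code{acupoints}, \code{patterns},
#' multi-valued fields separated by \code{";"}.
#'
#' Input order is preserved and the result is not canonicalized. Within-case
#' duplicate acupoints or pattern terms are allowed in raw files (a warning
#' is emitted); they are collapsed by [canonicalize_corpus()].
#'
#' @param path path to the input file.
#' @param format \code{"jsonl"} or \code{"tsv"}; defaults from the file
#'   extension.
#' @return An [new_corpus()] object with \code{canonicalized = FALSE}.
#' @export
load_corpus <- function(path, format = c("jsonl", "tsv")) {
  if (missing(format)) {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cases <- if (format == "jsonl") read_cases_jsonl(path) else read_cases_tsv(path)
  has_dup <- vapply(cases, function(cs) {
    anyDuplicated(cs$acupoints) > 0L || anyDuplicated(cs$patterns) > 0L
  }, logical(1))
  if (any(has_dup))
    warning("within-case duplicate entries in ", sum(has_dup),
            " case(s); they will be collapsed at canonicalization",
            call. = FALSE)
  new_corpus(cases, canonicalized = FALSE)
}

read_cases_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("line ", i, ": invalid JSON: ",
                                             conditionMessage(e), call. = FALSE))
    for (key in c("case_id", "acupoints", "patterns"))
      if (is.null(rec[[key]]))
        stop("line ", i, ": missing field '", key, "'", call. = FALSE)
    bad <- rec$acupoints[!grepl(ACUPOINT_CODE_RE, rec$acupoints)]
    if (length(bad))
      stop("line ", i, ": malformed acupoint code: ",
           paste(bad, collapse = ", "), call. = FALSE)
    new_case(rec$case_id, rec$subchapter %||% "", rec$acupoints, rec$patterns)
  })
}

read_cases_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8",
                           check.names = FALSE)
  need <- c("case_id", "subchapter", "acupoints", "patterns")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("TSV corpus missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    acu <- strsplit(tab$acupoints[i], ";", fixed = TRUE)[[1]]
    pat <- strsplit(tab$patterns[i], ";", fixed = TRUE)[[1]]
    acu <- trimws(acu[nzchar(trimws(acu))])
    pat <- trimws(pat[nzchar(trimws(pat))])
    bad <- acu[!grepl(ACUPOINT_CODE_RE, acu)]
    if (length(bad))
      stop("line ", i + 1L, ": malformed acupoint code: ",
           paste(bad, collapse = ", "), call. = FALSE)
    new_case(tab$case_id[i], tab$subchapter[i], acu, pat)
  })
}

#' Write a corpus to disk
#'
#' Inverse of [load_corpus()]; a written corpus reloads field-for-field.
#'
#' @param corpus an \code{acu_corpus}.
#' @param path output path.
#' @param format \code{"jsonl"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "acu_corpus"))
  if (format == "jsonl") {
    lines <- vapply(corpus$cases, function(cs) {
      jsonlite::toJSON(list(case_id = jsonlite::unbox(cs$case_id),
                            subchapter = jsonlite::unbox(cs$subchapter),
                            acupoints = cs$acupoints,
                            patterns = cs$patterns))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    tab <- data.frame(
      case_id = vapply(corpus$cases, `[[`, character(1), "case_id"),
      subchapter = vapply(corpus$cases, `[[`, character(1), "subchapter"),
      acupoints = vapply(corpus$cases,
                         function(cs) paste(cs$acupoints, collapse = ";"),
                         character(1)),
      patterns = vapply(corpus$cases,
                        function(cs) paste(cs$patterns, collapse = ";"),
                        character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pattern taxonomy
#'
#' The taxonomy maps raw pattern terms, as they occur in curated case
#' records, to canonical patterns, and each canonical pattern to one of the
#' pattern-identification categories. The packaged default
#' (\code{default_taxonomy()}) carries 25 canonical patterns in 3 categories:
#' 5 essential components of the body (essence, qi, spirit, blood, phlegm),
#' 12 viscera and bowels, and 8 internal/external causes; a few raw synonyms
#' (e.g. "sovereign fire", "ministerial fire", "heat") fold into "fire".
#'
#' @param path TSV file with columns \code{raw_term},
#'   \code{canonical_pattern}, \code{category}.
#' @return An object of class \code{pattern_taxonomy}: a list with named
#'   character vectors \code{raw_to_canonical} (raw term -> canonical
#'   pattern) and \code{canonical_to_category} (canonical pattern ->
#'   category), plus \code{patterns}, the canonical patterns in taxonomy
#'   (file) order.
#' @export
load_taxonomy <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  need <- c("raw_term", "canonical_pattern", "category")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("taxonomy missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  # conflicting duplicate raw terms
  by_raw <- split(tab$canonical_pattern, tab$raw_term)
  conflict <- names(by_raw)[vapply(by_raw, function(v) length(unique(v)) > 1L,
                                   logical(1))]
  if (length(conflict))
    stop("raw term(s) mapped to multiple canonical patterns: ",
         paste(conflict, collapse = ", "), call. = FALSE)
  by_canon <- split(tab$category, tab$canonical_pattern)
  conflict <- names(by_canon)[vapply(by_canon,
                                     function(v) length(unique(v)) > 1L,
                                     logical(1))]
  if (length(conflict))
    stop("canonical pattern(s) assigned to multiple categories: ",
         paste(conflict, collapse = ", "), call. = FALSE)
  keep <- !duplicated(tab$raw_term)
  raw_to_canonical <- stats::setNames(tab$canonical_pattern[keep],
                                      tab$raw_term[keep])
  keep <- !duplicated(tab$canonical_pattern)
  canonical_to_category <- stats::setNames(tab$category[keep],
                                           tab$canonical_pattern[keep])
  structure(list(raw_to_canonical = raw_to_canonical,
                 canonical_to_category = canonical_to_category,
                 patterns = unname(tab$canonical_pattern[keep])),
            class = "pattern_taxonomy")
}

#' @rdname load_taxonomy
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "pattern_taxonomy.tsv",
                            package = "acumine", mustWork = TRUE))
}

#' @export
print.pattern_taxonomy <- function(x, ...) {
  cat("<pattern_taxonomy> ", length(x$raw_to_canonical), " raw terms -> ",
      length(x$patterns), " canonical patterns in ",
      length(unique(x$canonical_to_category)), " categories\n", sep = "")
  invisible(x)
}

#' Replace raw pattern terms by canonical patterns
#'
#' Maps every raw pattern term of every case through the taxonomy and
#' collapses within-case duplicates (both duplicates present in the raw data
#' and duplicates created by the mapping, e.g. "sovereign fire" and
#' "ministerial fire" both folding into "fire") to a single occurrence.
#' Duplicate acupoints within a case are collapsed at the same time, so that
#' downstream frequencies are case-level counts.
#'
#' @param corpus an \code{acu_corpus} with \code{canonicalized = FALSE}.
#' @param taxonomy a [load_taxonomy()] object.
#' @param unknown_policy what to do with a raw term absent from the
#'   taxonomy: \code{"error"} (default; silent drops corrupt frequencies),
#'   \code{"drop"} (remove it, with a warning), or \code{"keep"} (pass it
#'   through unchanged).
#' @return The canonicalized corpus (\code{canonicalized = TRUE}).
#' @export
canonicalize_corpus <- function(corpus, taxonomy,
                                unknown_policy = c("error", "drop", "keep")) {
  stopifnot(inherits(corpus, "acu_corpus"),
            inherits(taxonomy, "pattern_taxonomy"))
  unknown_policy <- match.arg(unknown_policy)
  if (isTRUE(corpus$canonicalized))
    stop("corpus is already canonicalized", call. = FALSE)
  map <- taxonomy$raw_to_canonical
  dropped <- character(0)
  cases <- lapply(corpus$cases, function(cs) {
    known <- cs$patterns %in% names(map)
    if (!all(known)) {
      unk <- unique(cs$patterns[!known])
      if (unknown_policy == "error")
        stop("unknown pattern term(s) in case '", cs$case_id, "': ",
             paste(unk, collapse = ", "), call. = FALSE)
      if (unknown_policy == "drop") {
        dropped <<- c(dropped, unk)
        cs$patterns <- cs$patterns[known]
        known <- rep(TRUE, length(cs$patterns))
      }
    }
    mapped <- ifelse(cs$patterns %in% names(map),
                     unname(map[cs$patterns]), cs$patterns)
    if (length(mapped) == 0L)
      stop("case '", cs$case_id,
           "' has no patterns left after canonicalization", call. = FALSE)
    cs$patterns <- unique(mapped)
    cs$acupoints <- unique(cs$acupoints)
    cs
  })
  if (length(dropped))
    warning("dropped unknown pattern term(s): ",
            paste(unique(dropped), collapse = ", "), call. = FALSE)
  new_corpus(cases, canonicalized = TRUE)
}

#' Summary counts for a corpus
#'
#' Mention counts respect within-case multiplicity as stored: for a raw
#' corpus they count the raw lists, for a canonicalized corpus the collapsed
#' per-case lists.
#'
#' @param corpus an \code{acu_corpus}.
#' @return A list of class \code{corpus_summary} with \code{n_cases},
#'   \code{n_unique_acupoints}, \code{n_acupoint_mentions},
#'   \code{n_unique_pattern_terms}, \code{n_pattern_mentions}.
#' @export
summarize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "acu_corpus"))
  acu <- unlist(lapply(corpus$cases, `[[`, "acupoints"), use.names = FALSE)
  pat <- unlist(lapply(corpus$cases, `[[`, "patterns"), use.names = FALSE)
  structure(list(n_cases = length(corpus$cases),
                 n_unique_acupoints = length(unique(acu)),
                 n_acupoint_mentions = length(acu),
                 n_unique_pattern_terms = length(unique(pat)),
                 n_pattern_mentions = length(pat)),
            class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("cases:            ", x$n_cases, "\n",
      "acupoints:        ", x$n_unique_acupoints, " unique, ",
      x$n_acupoint_mentions, " mentions\n",
      "pattern terms:    ", x$n_unique_pattern_terms, " unique, ",
      x$n_pattern_mentions, " mentions\n", sep = "")
  invisible(x)
}
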