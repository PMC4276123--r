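#' Case-level entity frequencies
#'
#' Counts, for every acupoint or canonical pattern, the number of cases that
#' contain it. Each case contributes at most once per entity, matching the
#' case-level reading of usage frequencies (an acupoint "used 16 times" means
#' it appears in 16 cases).
#'
#' @param corpus a canonicalized \code{acu_corpus}.
#' @param kind \code{"acupoint"} or \code{"pattern"}.
#' @return A named integer vector of class \code{frequency_table}, sorted by
#'   decreasing count then label; attribute \code{kind} records the entity
#'   kind.
#' @export
count_frequencies <- function(corpus, kind = c("acupoint", "pattern")) {
  kind <- match.arg(kind)
  stopifnot(inherits(corpus, "acu_corpus"))
  if (!isTRUE(corpus$canonicalized))
    stop("corpus must be canonicalized before counting frequencies",
         call. = FALSE)
  field <- if (kind == "acupoint") "acupoints" else "patterns"
  ent <- unlist(lapply(corpus$cases, function(cs) unique(cs[[field]])),
                use.names = FALSE)
  tab <- table(ent)
  counts <- stats::setNames(as.integer(tab), names(tab))
  ord <- order(-counts, names(counts))
  structure(counts[ord], class = "frequency_table", kind = kind)
}

#' Acupoint-by-pattern co-occurrence matrix
#'
#' Cell (a, p) is the number of cases in which acupoint \code{a} and pattern
#' \code{p} occur together. Co-occurrence is case-level (binary per case),
#' not mention-level. Row and column margins (case counts per acupoint and
#' per pattern) and the case total are attached.
#'
#' @param corpus a canonicalized, nonempty \code{acu_corpus}.
#' @return An object of class \code{cooccurrence_matrix}: a list with an
#'   integer matrix \code{counts} (rows = acupoints, columns = patterns),
#'   margins \code{acupoint_freq} and \code{pattern_freq}, and
#'   \code{n_cases}. Rows and columns are ordered by decreasing margin, ties
#'   by label.
#' @export
build_cooccurrence <- function(corpus) {
  stopifnot(inherits(corpus, "acu_corpus"))
  if (!isTRUE(corpus$canonicalized))
    stop("corpus must be canonicalized", call. = FALSE)
  if (length(corpus$cases) == 0L)
    stop("empty corpus", call. = FALSE)
  afreq <- count_frequencies(corpus, "acupoint")
  pfreq <- count_frequencies(corpus, "pattern")
  counts <- matrix(0L, nrow = length(afreq), ncol = length(pfreq),
                   dimnames = list(names(afreq), names(pfreq)))
  for (cs in corpus$cases) {
    a <- unique(cs$acupoints)
    p <- unique(cs$patterns)
    counts[a, p] <- counts[a, p] + 1L
  }
  structure(list(counts = counts,
                 acupoint_freq = afreq,
                 pattern_freq = pfreq,
                 n_cases = length(corpus$cases)),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat("<cooccurrence_matrix> ", nrow(x$counts), " acupoints x ",
      ncol(x$counts), " patterns over ", x$n_cases, " cases",
      if (!is.null(x$parent)) " (filtered)", "\n", sep = "")
  invisible(x)
}

#' Drop rarely used acupoints
#'
#' Removes acupoint rows whose case-level margin is below \code{min_count};
#' pattern columns are never removed. The retained rows keep their original
#' case-level margins, and the full pre-filter matrix stays attached as
#' \code{$parent} so downstream weighting can compute document frequencies
#' over either the retained acupoints or all of them (see
#' [compute_tfidf()]'s \code{document_universe}).
#'
#' @param matrix a \code{cooccurrence_matrix}.
#' @param min_count minimum number of cases (inclusive) an acupoint must
#'   appear in; the default 3 mirrors the usual "used at least three times"
#'   cut for sparse classical corpora.
#' @return The filtered \code{cooccurrence_matrix}.
#' @export
filter_min_count <- function(matrix, min_count = 3L) {
  stopifnot(inherits(matrix, "cooccurrence_matrix"))
  if (min_count < 1L) stop("min_count must be >= 1", call. = FALSE)
  keep <- matrix$acupoint_freq >= min_count
  if (!any(keep))
    stop("min_count = ", min_count, " removes every acupoint", call. = FALSE)
  parent <- matrix
  parent$parent <- NULL
  out <- matrix
  out$counts <- matrix$counts[keep, , drop = FALSE]
  out$acupoint_freq <- structure(matrix$acupoint_freq[keep],
                                 class = "frequency_table",
                                 kind = "acupoint")
  out$parent <- parent
  out$min_count <- min_count
  out
}

#' Write / read a co-occurrence matrix as TSV
#'
#' First column \code{acupoint}, header row of pattern names, integer cells.
#' Margins are recoverable only approximately from the cells, so the margins
#' and case total are stored in comment lines at the top of the file.
#'
#' @param matrix a \code{cooccurrence_matrix}.
#' @param path output path.
#' @return \code{path} invisibly (writer); a \code{cooccurrence_matrix}
#'   (reader).
#' @export
write_cooccurrence <- function(matrix, path) {
  stopifnot(inherits(matrix, "cooccurrence_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# n_cases=", matrix$n_cases), con)
  writeLines(paste0("# acupoint_freq=", paste(names(matrix$acupoint_freq),
                                              matrix$acupoint_freq,
                                              sep = ":", collapse = ",")), con)
  writeLines(paste0("# pattern_freq=", paste(names(matrix$pattern_freq),
                                             matrix$pattern_freq,
                                             sep = ":", collapse = ",")), con)
  tab <- data.frame(acupoint = rownames(matrix$counts), matrix$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  parse_kv <- function(prefix) {
    ln <- sub(paste0("# ", prefix, "="), "",
              hdr[startsWith(hdr, paste0("# ", prefix, "="))], fixed = TRUE)
    pairs <- strsplit(strsplit(ln, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(as.integer(vapply(pairs, `[`, character(1), 2L)),
                    vapply(pairs, `[`, character(1), 1L))
  }
  n_cases <- as.integer(sub("# n_cases=", "",
                            hdr[startsWith(hdr, "# n_cases=")], fixed = TRUE))
  tab <- utils::read.delim(text = body, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$acupoint
  structure(list(counts = counts,
                 acupoint_freq = structure(
                   parse_kv("acupoint_freq")[rownames(counts)],
                   class = "frequency_table", kind = "acupoint"),
                 pattern_freq = structure(
                   parse_kv("pattern_freq")[colnames(counts)],
                   class = "frequency_table", kind = "pattern"),
                 n_cases = n_cases),
            class = "cooccurrence_matrix")
}
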