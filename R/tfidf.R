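#' Bidirectional tf-idf weighting of the co-occurrence matrix
#'
#' The co-occurrence table is weighted as in information retrieval: the term
#' frequency tf(t, d) is the number of cases in which term t co-occurs with
#' document d (a cell of the matrix), the document frequency df(t) is the
#' number of documents whose cell for t is positive, and
#' \deqn{w(d, t) = tf(t, d) \cdot \log(N / df(t)),}
#' with N the number of documents. Two directions are supported:
#' \describe{
#'   \item{\code{pattern_as_term}}{documents are acupoints, terms are
#'     patterns: each acupoint becomes a weight vector over the canonical
#'     patterns, quantifying which patterns characterize it.}
#'   \item{\code{acupoint_as_term}}{documents are patterns, terms are
#'     acupoints: each pattern becomes a weight vector over acupoints,
#'     ranking the points most specifically tied to it.}
#' }
#'
#' When the matrix has been filtered by [filter_min_count()],
#' \code{document_universe} chooses the universe that defines N and df:
#' \code{"filtered"} uses the retained acupoints only, \code{"all"} the full
#' pre-filter matrix. The default follows the two dimensionalities natural to
#' each direction: \code{"filtered"} for \code{pattern_as_term} (profiles of
#' the analyzable points) and \code{"all"} for \code{acupoint_as_term}
#' (patterns as vectors over every recorded acupoint).
#'
#' @param matrix a \code{cooccurrence_matrix}.
#' @param direction \code{"pattern_as_term"} or \code{"acupoint_as_term"}.
#' @param document_universe \code{"filtered"} or \code{"all"}; see Details.
#' @param log_base base of the idf logarithm, \code{"e"} (default) or
#'   \code{"10"}. The base rescales every weight by one constant, so
#'   rankings, cosine-normalized vectors and profile correlations do not
#'   depend on it.
#' @return An object of class \code{weight_matrix}: a list with the numeric
#'   \code{weights} matrix (rows = documents, columns = terms),
#'   \code{direction}, \code{normalized} (\code{FALSE}), \code{n_documents}
#'   and \code{log_base}.
#' @export
compute_tfidf <- function(matrix,
                          direction = c("pattern_as_term", "acupoint_as_term"),
                          document_universe = NULL,
                          log_base = c("e", "10")) {
  stopifnot(inherits(matrix, "cooccurrence_matrix"))
  direction <- match.arg(direction)
  log_base <- match.arg(log_base)
  if (is.null(document_universe))
    document_universe <- if (direction == "pattern_as_term") "filtered" else "all"
  document_universe <- match.arg(document_universe, c("filtered", "all"))
  use <- if (document_universe == "all") matrix$parent %||% matrix else matrix
  # orient: rows = documents, columns = terms
  tf <- if (direction == "pattern_as_term") use$counts else t(use$counts)
  if (nrow(tf) == 0L || ncol(tf) == 0L) stop("empty matrix", call. = FALSE)
  n_doc <- nrow(tf)
  df <- colSums(tf > 0L)
  if (any(df == 0L)) {
    warning("dropping term(s) absent from every document: ",
            paste(colnames(tf)[df == 0L], collapse = ", "), call. = FALSE)
    tf <- tf[, df > 0L, drop = FALSE]
    df <- df[df > 0L]
  }
  idf <- log(n_doc / df)
  if (log_base == "10") idf <- idf / log(10)
  w <- sweep(tf, 2L, idf, `*`)
  if (document_universe == "all" && direction == "pattern_as_term") {
    # df/N from the full universe, profiles reported for retained rows only
    w <- w[rownames(matrix$counts), , drop = FALSE]
  }
  structure(list(weights = w,
                 direction = direction,
                 normalized = FALSE,
                 n_documents = n_doc,
                 log_base = log_base),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("<weight_matrix> ", x$direction, ", ", nrow(x$weights), " documents x ",
      ncol(x$weights), " terms, normalized=", x$normalized, "\n", sep = "")
  invisible(x)
}

#' Cosine normalization of weight vectors
#'
#' Rescales each document's weight vector to unit Euclidean length so that
#' documents of different total frequency become comparable in the same
#' vector space. All-zero rows are left at zero with a warning.
#'
#' @param weights an unnormalized \code{weight_matrix}.
#' @return The \code{weight_matrix} with unit-norm rows and
#'   \code{normalized = TRUE}.
#' @export
cosine_normalize <- function(weights) {
  stopifnot(inherits(weights, "weight_matrix"))
  if (isTRUE(weights$normalized))
    stop("weights are already normalized", call. = FALSE)
  norms <- sqrt(rowSums(weights$weights^2))
  zero <- norms == 0
  if (any(zero))
    warning("all-zero weight row(s) left unnormalized: ",
            paste(rownames(weights$weights)[zero], collapse = ", "),
            call. = FALSE)
  norms[zero] <- 1
  weights$weights <- weights$weights / norms
  weights$normalized <- TRUE
  weights
}

#' Top-k terms characterizing one document
#'
#' @param weights a \code{weight_matrix}.
#' @param document a row label (an acupoint for \code{pattern_as_term}, a
#'   pattern for \code{acupoint_as_term}).
#' @param k maximum number of terms returned.
#' @return A data.frame with columns \code{term} and \code{weight}, sorted
#'   by decreasing weight (ties broken by term label, ascending); zero-weight
#'   terms are excluded, so fewer than \code{k} rows may come back.
#' @export
top_k_ranked <- function(weights, document, k = 5L) {
  stopifnot(inherits(weights, "weight_matrix"), k >= 1L)
  if (!document %in% rownames(weights$weights))
    stop("unknown document: ", document, call. = FALSE)
  row <- weights$weights[document, ]
  row <- row[row > 0]
  ord <- order(-row, names(row), method = "radix")
  top <- utils::head(row[ord], k)
  data.frame(term = names(top), weight = unname(top),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a weight matrix as TSV
#'
#' First column \code{document}, header row of term labels, float cells at 6
#' decimal places.
#'
#' @param weights a \code{weight_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "weight_matrix"))
  w <- format(round(weights$weights, 6), nsmall = 6, trim = TRUE,
              scientific = FALSE)
  tab <- data.frame(document = rownames(weights$weights), w,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
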