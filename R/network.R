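#' Correlation distance between two profile vectors
#'
#' One minus the Pearson correlation coefficient, ranging over [0, 2]:
#' 0 for perfectly correlated profiles, 1 for uncorrelated, 2 for perfectly
#' anticorrelated. Undefined when either vector has zero variance; the
#' undefined case returns \code{NA} rather than an error, matching how
#' constant profiles are masked in [distance_matrix()].
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return A single number in [0, 2], or \code{NA} if either vector is
#'   constant.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("profile vectors differ in length", call. = FALSE)
  if (length(x) < 2L)
    stop("profile vectors must have length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  1 - stats::cor(x, y)
}

#' All pairwise correlation distances between acupoint profiles
#'
#' @param weights a \code{weight_matrix} with direction
#'   \code{pattern_as_term} (rows are acupoint profiles over the canonical
#'   patterns). Cosine normalization does not change these distances
#'   (Pearson correlation is invariant under positive rescaling), so either
#'   a raw or a normalized matrix gives the same result.
#' @return An object of class \code{acu_distance}: a list with the symmetric
#'   numeric matrix \code{d} (diagonal 0, \code{NA} where a profile has zero
#'   variance) and the logical vector \code{defined} flagging rows with
#'   positive variance.
#' @export
distance_matrix <- function(weights) {
  stopifnot(inherits(weights, "weight_matrix"))
  if (weights$direction != "pattern_as_term")
    stop("distances are defined over acupoint profiles ",
         "(direction pattern_as_term)", call. = FALSE)
  w <- weights$weights
  if (nrow(w) < 2L)
    stop("need at least 2 profiles", call. = FALSE)
  if (ncol(w) < 2L)
    stop("profiles must span at least 2 patterns", call. = FALSE)
  defined <- apply(w, 1L, stats::sd) > 0
  if (any(!defined))
    warning("zero-variance profile(s) masked: ",
            paste(rownames(w)[!defined], collapse = ", "), call. = FALSE)
  d <- 1 - suppressWarnings(stats::cor(t(w)))
  d[!defined, ] <- NA_real_
  d[, !defined] <- NA_real_
  diag(d)[defined] <- 0
  structure(list(d = d, defined = defined), class = "acu_distance")
}

#' @export
print.acu_distance <- function(x, ...) {
  cat("<acu_distance> ", nrow(x$d), " acupoints (",
      sum(x$defined), " with defined profiles)\n", sep = "")
  invisible(x)
}

#' Choose the linkage threshold
#'
#' Either a fixed correlation distance, or an empirical percentile of the
#' distribution of pairwise distances. A fixed cut near 0.1 corresponds to
#' roughly the lower 1 percentile of that distribution in corpora of this
#' kind, which is how the two modes relate.
#'
#' @param distances an \code{acu_distance}.
#' @param mode \code{"fixed"} or \code{"percentile"}.
#' @param value the fixed distance (> 0), or the percentile in (0, 100).
#' @return The threshold distance (numeric scalar). Percentiles use the
#'   linear-interpolation empirical quantile
#'   (\code{stats::quantile(type = 7)}) over the defined off-diagonal
#'   distances, each unordered pair counted once.
#' @export
select_threshold <- function(distances, mode = c("fixed", "percentile"),
                             value = 0.1) {
  stopifnot(inherits(distances, "acu_distance"))
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (value <= 0) stop("fixed threshold must be > 0", call. = FALSE)
    return(value)
  }
  if (value <= 0 || value >= 100)
    stop("percentile must be in (0, 100)", call. = FALSE)
  offdiag <- distances$d[upper.tri(distances$d)]
  offdiag <- offdiag[!is.na(offdiag)]
  if (length(offdiag) == 0L)
    stop("no defined pairwise distances", call. = FALSE)
  unname(stats::quantile(offdiag, probs = value / 100, type = 7))
}

#' Build the acupoint association network
#'
#' Links two acupoints when their correlation distance is strictly below the
#' threshold. Every acupoint with a defined profile is kept as a node, so
#' isolated points remain visible; masked (zero-variance) profiles carry no
#' edges but are kept as nodes too.
#'
#' @param distances an \code{acu_distance}.
#' @param threshold linkage threshold (> 0), e.g. from [select_threshold()].
#' @return An object of class \code{association_network}: a list with an
#'   undirected \pkg{igraph} \code{graph} whose edges carry the distance as
#'   attribute \code{distance}, plus \code{threshold}.
#' @export
build_network <- function(distances, threshold) {
  stopifnot(inherits(distances, "acu_distance"))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  d <- distances$d
  nodes <- rownames(d)
  idx <- which(upper.tri(d) & !is.na(d) & d < threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(idx)) {
    ends <- rbind(nodes[idx[, 1]], nodes[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(ends),
                           distance = d[idx])
  }
  structure(list(graph = g, threshold = threshold),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat("<association_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges, threshold < ", x$threshold, "\n",
      sep = "")
  invisible(x)
}

#' Edge list of an association network
#'
#' @param network an \code{association_network}.
#' @return A data.frame with columns \code{node_a}, \code{node_b},
#'   \code{distance}, sorted by increasing distance.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "association_network"))
  e <- igraph::as_data_frame(network$graph, what = "edges")
  if (nrow(e) == 0L)
    return(data.frame(node_a = character(0), node_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  out <- data.frame(node_a = e$from, node_b = e$to, distance = e$distance,
                    stringsAsFactors = FALSE)
  out[order(out$distance, out$node_a, out$node_b, method = "radix"), ,
      drop = FALSE]
}

#' Extract modules (connected components) from the network
#'
#' A module is a connected component with at least two members; isolated
#' acupoints are not modules. The hub of a module is its member of maximal
#' degree, ties broken by the lexicographically smallest label. Modules come
#' back ordered by decreasing size, ties by smallest member label.
#'
#' @param network an \code{association_network}.
#' @return A list of objects of class \code{acu_module}, each a list with
#'   \code{members} (sorted labels), \code{hub} and \code{edges} (data.frame
#'   as in [network_edges()] restricted to the module).
#' @export
extract_modules <- function(network) {
  stopifnot(inherits(network, "association_network"))
  g <- network$graph
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2L)
  if (length(keep) == 0L) return(list())
  names_g <- igraph::V(g)$name
  deg <- igraph::degree(g)
  mods <- lapply(keep, function(ci) {
    members <- sort(names_g[comp$membership == ci], method = "radix")
    mdeg <- deg[members]
    hub <- members[order(-mdeg, members, method = "radix")][1]
    sub <- igraph::induced_subgraph(g, members)
    e <- igraph::as_data_frame(sub, what = "edges")
    swap <- e$from > e$to
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
    edges <- data.frame(node_a = e$from, node_b = e$to,
                        distance = e$distance, stringsAsFactors = FALSE)
    structure(list(members = members, hub = hub, edges = edges),
              class = "acu_module")
  })
  sizes <- vapply(mods, function(m) length(m$members), integer(1))
  first <- vapply(mods, function(m) m$members[1], character(1))
  mods[order(-sizes, first, method = "radix")]
}

#' @export
print.acu_module <- function(x, ...) {
  cat("<acu_module> {", paste(x$members, collapse = ", "), "} hub=", x$hub,
      "\n", sep = "")
  invisible(x)
}
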