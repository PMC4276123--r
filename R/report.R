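#' Mean pattern profile of a module
#'
#' The characteristic profile of a module is the elementwise arithmetic mean
#' of its members' cosine-normalized tf-idf vectors over the canonical
#' patterns — the vector drawn on the module's radar chart.
#'
#' @param module an \code{acu_module} from [extract_modules()].
#' @param weights a normalized \code{weight_matrix}, direction
#'   \code{pattern_as_term}, containing every module member as a row.
#' @param taxonomy optional [load_taxonomy()] object used to annotate each
#'   pattern with its category.
#' @return An object of class \code{module_profile}: a list with the named
#'   numeric vector \code{profile} (one entry per pattern column), the
#'   \code{module}, and \code{category} (named character vector, or
#'   \code{NULL} when no taxonomy is given).
#' @export
module_mean_profile <- function(module, weights, taxonomy = NULL) {
  stopifnot(inherits(module, "acu_module"),
            inherits(weights, "weight_matrix"))
  if (!isTRUE(weights$normalized))
    stop("profiles are means of normalized weight vectors", call. = FALSE)
  if (weights$direction != "pattern_as_term")
    stop("profiles are over patterns (direction pattern_as_term)",
         call. = FALSE)
  missing <- setdiff(module$members, rownames(weights$weights))
  if (length(missing))
    stop("module member(s) absent from weight matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  prof <- colMeans(weights$weights[module$members, , drop = FALSE])
  category <- NULL
  if (!is.null(taxonomy))
    category <- taxonomy$canonical_to_category[names(prof)]
  structure(list(profile = prof, module = module, category = category),
            class = "module_profile")
}

#' Top-k acupoints for one pattern
#'
#' The reverse-direction ranking: which acupoints are most specifically
#' associated with a given pattern, by acupoint-as-term tf-idf weight.
#'
#' @param weights a \code{weight_matrix} with direction
#'   \code{acupoint_as_term} (rows are patterns).
#' @param pattern a canonical pattern present in the matrix.
#' @param k maximum number of acupoints.
#' @return A data.frame with columns \code{term} (acupoint) and
#'   \code{weight}; zero weights excluded, ties broken by label.
#' @export
rank_for_pattern <- function(weights, pattern, k = 5L) {
  stopifnot(inherits(weights, "weight_matrix"))
  if (weights$direction != "acupoint_as_term")
    stop("pattern rankings need direction acupoint_as_term", call. = FALSE)
  top_k_ranked(weights, pattern, k)
}

open_figure_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = width, height = height),
         png = grDevices::png(path, width = width * 96, height = height * 96,
                              res = 96),
         stop("unsupported figure format: .", ext, " (use .svg or .png)",
              call. = FALSE))
}

#' Heatmap of the normalized weight matrix
#'
#' Draws the acupoint-by-pattern weight matrix with patterns grouped into
#' their three category bands and acupoints ordered by descending case
#' frequency (the conventional layout for these matrices; the source data
#' carry no intrinsic order).
#'
#' @param weights a normalized \code{weight_matrix}, direction
#'   \code{pattern_as_term}.
#' @param taxonomy a [load_taxonomy()] object supplying the category bands.
#' @param path output file (\code{.svg} or \code{.png}).
#' @param acupoint_freq optional named frequency vector used to order the
#'   acupoint axis; matrix row order is kept when absent.
#' @return The \pkg{ggplot2} object, invisibly (the file is the primary
#'   output).
#' @export
render_heatmap <- function(weights, taxonomy, path, acupoint_freq = NULL) {
  stopifnot(inherits(weights, "weight_matrix"),
            inherits(taxonomy, "pattern_taxonomy"))
  if (!isTRUE(weights$normalized))
    stop("heatmap expects normalized weights", call. = FALSE)
  w <- weights$weights
  acu_order <- rownames(w)
  if (!is.null(acupoint_freq)) {
    f <- acupoint_freq[acu_order]
    acu_order <- acu_order[order(-f, acu_order, method = "radix")]
  }
  cat_of <- taxonomy$canonical_to_category[colnames(w)]
  cat_levels <- unique(unname(taxonomy$canonical_to_category))
  pat_order <- colnames(w)[order(match(cat_of, cat_levels),
                                 match(colnames(w), taxonomy$patterns))]
  df <- data.frame(
    acupoint = factor(rep(rownames(w), times = ncol(w)), levels = acu_order),
    pattern = factor(rep(colnames(w), each = nrow(w)), levels = pat_order),
    category = factor(rep(unname(cat_of), each = nrow(w)),
                      levels = cat_levels),
    weight = as.vector(w))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$acupoint,
                                        y = .data$pattern,
                                        fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(category ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "acupoint (by descending frequency)",
                  y = "canonical pattern", fill = "weight") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
  open_figure_device(path, width = max(6, nrow(w) * 0.15), height = 5)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(p)
}

#' Radar chart of a module profile
#'
#' One axis per canonical pattern, in taxonomy order, with the module's mean
#' normalized weight as the radius.
#'
#' @param profile a \code{module_profile}.
#' @param path output file (\code{.svg} or \code{.png}).
#' @param pattern_order optional character vector fixing the axis order;
#'   defaults to the profile's own pattern order.
#' @return The \pkg{ggplot2} object, invisibly.
#' @export
render_radar <- function(profile, path, pattern_order = NULL) {
  stopifnot(inherits(profile, "module_profile"))
  pats <- pattern_order %||% names(profile$profile)
  vals <- profile$profile[pats]
  df <- data.frame(pattern = factor(pats, levels = pats),
                   weight = unname(vals))
  closed <- rbind(df, df[1, ])
  closed$step <- c(seq_len(nrow(df)), nrow(df) + 1L)
  p <- ggplot2::ggplot(closed, ggplot2::aes(x = .data$step,
                                            y = .data$weight,
                                            group = 1)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.4,
                          color = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(df)),
                                labels = levels(df$pattern),
                                limits = c(1, nrow(df) + 1L)) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, max(0.01, max(df$weight))) +
    ggplot2::labs(title = paste0("module {",
                                 paste(profile$module$members,
                                       collapse = ", "),
                                 "}"),
                  x = NULL, y = "mean normalized weight") +
    ggplot2::theme_minimal(base_size = 7)
  open_figure_device(path, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(p)
}

format_rank_table <- function(weights, docs, freq, k = 5L) {
  rows <- lapply(docs, function(d) {
    top <- top_k_ranked(weights, d, k)
    cells <- sprintf("%s (%.2f)", top$term, top$weight)
    length(cells) <- k
    cells[is.na(cells)] <- ""
    c(document = d, frequency = as.character(freq[[d]]),
      stats::setNames(cells, paste0("rank_", seq_len(k))))
  })
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes corpus loading (or synthetic generation), canonicalization,
#' frequency filtering, bidirectional tf-idf with cosine normalization,
#' network construction, module extraction and reporting, writing every
#' artifact into one directory:
#' \code{corpus_summary.tsv}, \code{acupoint_frequencies.tsv},
#' \code{pattern_frequencies.tsv}, \code{weights_pattern_as_term.tsv},
#' \code{weights_acupoint_as_term.tsv}, \code{top_patterns_per_acupoint.tsv},
#' \code{top_acupoints_per_pattern.tsv}, \code{network_edges.tsv},
#' \code{module_membership.tsv}, plus \code{module_profiles.tsv}, a heatmap,
#' one radar chart per module, and \code{run_log.txt} recording all
#' parameters and the seed. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   \code{corpus} (path) or \code{simulate} (a list of [synthetic_config()]
#'   arguments), \code{taxonomy} (path; packaged default when absent),
#'   \code{min_count} (default 3), \code{log_base} (default \code{"e"}),
#'   \code{threshold_mode} (\code{"fixed"} or \code{"percentile"}; default
#'   \code{"fixed"}), \code{threshold_value} (default 0.1), \code{top_k}
#'   (default 5), \code{unknown_policy} (default \code{"error"}),
#'   \code{outdir} (required), \code{seed} (used only with \code{simulate};
#'   default 1), \code{figures} (logical, default \code{TRUE}).
#' @return Invisibly, a list with the intermediate objects (\code{corpus},
#'   \code{cooccurrence}, \code{weights_pa}, \code{weights_ap},
#'   \code{network}, \code{modules}, \code{profiles}) and \code{outdir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$outdir))
  cfg <- utils::modifyList(
    list(min_count = 3L, log_base = "e", threshold_mode = "fixed",
         threshold_value = 0.1, top_k = 5L, unknown_policy = "error",
         seed = 1L, figures = TRUE),
    config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  taxonomy <- stage("taxonomy", {
    if (is.null(cfg$taxonomy)) default_taxonomy() else load_taxonomy(cfg$taxonomy)
  })
  truth <- NULL
  corpus <- stage("corpus", {
    if (!is.null(cfg$simulate)) {
      sim_cfg <- do.call(synthetic_config,
                         c(cfg$simulate, list(seed = cfg$seed)))
      sim <- generate_corpus(sim_cfg)
      truth <- sim$truth
      sim$corpus
    } else {
      load_corpus(cfg$corpus)
    }
  })
  if (!isTRUE(corpus$canonicalized))
    corpus <- stage("canonicalize",
                    canonicalize_corpus(corpus, taxonomy, cfg$unknown_policy))

  cooc <- stage("cooccurrence", build_cooccurrence(corpus))
  filt <- stage("filter", filter_min_count(cooc, cfg$min_count))
  w_pa <- stage("tfidf", cosine_normalize(
    compute_tfidf(filt, "pattern_as_term", log_base = cfg$log_base)))
  w_ap <- stage("tfidf", cosine_normalize(
    compute_tfidf(filt, "acupoint_as_term", log_base = cfg$log_base)))
  dmat <- stage("network", distance_matrix(w_pa))
  thr <- stage("network", select_threshold(dmat, cfg$threshold_mode,
                                           cfg$threshold_value))
  net <- stage("network", build_network(dmat, thr))
  modules <- stage("modules", extract_modules(net))
  profiles <- stage("profiles", lapply(modules, module_mean_profile,
                                       weights = w_pa, taxonomy = taxonomy))

  out <- function(f) file.path(cfg$outdir, f)
  wt <- function(x, f) utils::write.table(x, out(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          fileEncoding = "UTF-8")
  s <- summarize_corpus(corpus)
  wt(data.frame(quantity = names(unclass(s)),
                value = unlist(unclass(s), use.names = FALSE)),
     "corpus_summary.tsv")
  wt(data.frame(acupoint = names(cooc$acupoint_freq),
                n_cases = as.integer(cooc$acupoint_freq)),
     "acupoint_frequencies.tsv")
  wt(data.frame(pattern = names(cooc$pattern_freq),
                n_cases = as.integer(cooc$pattern_freq)),
     "pattern_frequencies.tsv")
  write_weights(w_pa, out("weights_pattern_as_term.tsv"))
  write_weights(w_ap, out("weights_acupoint_as_term.tsv"))
  wt(format_rank_table(w_pa, rownames(w_pa$weights), filt$acupoint_freq,
                       cfg$top_k),
     "top_patterns_per_acupoint.tsv")
  wt(format_rank_table(w_ap, rownames(w_ap$weights), cooc$pattern_freq,
                       cfg$top_k),
     "top_acupoints_per_pattern.tsv")
  edges <- network_edges(net)
  edges$distance <- sprintf("%.6f", edges$distance)
  wt(edges, "network_edges.tsv")
  wt(do.call(rbind, c(list(data.frame(module = integer(0),
                                      acupoint = character(0),
                                      hub = character(0))),
                      lapply(seq_along(modules), function(i)
                        data.frame(module = i,
                                   acupoint = modules[[i]]$members,
                                   hub = modules[[i]]$hub)))),
     "module_membership.tsv")
  prof_tab <- do.call(rbind, c(
    list(data.frame(module = integer(0), pattern = character(0),
                    category = character(0), mean_weight = character(0))),
    lapply(seq_along(profiles), function(i) {
      pr <- profiles[[i]]
      data.frame(module = i, pattern = names(pr$profile),
                 category = unname(pr$category),
                 mean_weight = sprintf("%.6f", unname(pr$profile)))
    })))
  wt(prof_tab, "module_profiles.tsv")

  if (isTRUE(cfg$figures)) {
    render_heatmap(w_pa, taxonomy, out("heatmap.svg"),
                   acupoint_freq = filt$acupoint_freq)
    for (i in seq_along(profiles))
      render_radar(profiles[[i]], out(sprintf("module_%02d_radar.svg", i)),
                   pattern_order = intersect(taxonomy$patterns,
                                             names(profiles[[i]]$profile)))
  }

  log_lines <- c(
    "acumine pipeline run",
    paste0("seed: ", cfg$seed),
    paste0("min_count: ", cfg$min_count),
    paste0("log_base: ", cfg$log_base),
    paste0("threshold_mode: ", cfg$threshold_mode),
    paste0("threshold_value: ", cfg$threshold_value),
    paste0("threshold_used: ", format(thr, digits = 10)),
    paste0("n_cases: ", s$n_cases),
    paste0("n_acupoints_retained: ", nrow(filt$counts)),
    paste0("n_edges: ", igraph::ecount(net$graph)),
    paste0("n_modules: ", length(modules)))
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(corpus = corpus, cooccurrence = cooc, filtered = filt,
                 weights_pa = w_pa, weights_ap = w_ap, distances = dmat,
                 threshold = thr, network = net, modules = modules,
                 profiles = profiles, truth = truth, outdir = cfg$outdir))
}
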