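# Acupoint code pool: WHO meridian codes in classical order, enough for the
# default 114-point universe.
meridian_codes <- function(n) {
  meridians <- c(LU = 11L, LI = 20L, ST = 45L, SP = 21L, HT = 9L, SI = 19L,
                 BL = 67L, KI = 27L, PC = 9L, TE = 23L, GB = 44L, LR = 14L,
                 CV = 24L, GV = 28L)
  codes <- unlist(lapply(names(meridians), function(m)
    paste0(m, seq_len(meridians[[m]]))), use.names = FALSE)
  if (n > length(codes))
    stop("at most ", length(codes), " acupoints supported", call. = FALSE)
  codes[seq_len(n)]
}

#' Configuration of the synthetic case-record generator
#'
#' The generator emulates a curated corpus of classical acupuncture case
#' records at the scale typical of one chapter of a classical text: 114
#' cases, about 3 acupoint mentions and 9.5 pattern mentions per case
#' (roughly 341 and 1082 mentions in total), a skewed acupoint popularity
#' distribution, and planted acupoint-pattern association modules that the
#' analysis pipeline is expected to recover.
#'
#' Each planted module is a disjoint set of acupoints sharing a preferred
#' set of 3-5 canonical patterns. A case is module-driven with probability
#' \code{p_module_case}: its acupoints are drawn from the module's members
#' with probability \code{p_module_acupoint} per draw (otherwise from the
#' background popularity distribution), and its patterns from the module's
#' preferred set with probability \code{alpha} per draw (otherwise uniformly
#' over all canonical patterns). Background cases draw acupoints from a
#' Zipf-like distribution with weight rank^(-zipf_exponent) over the
#' non-module acupoints and patterns uniformly. The default exponent 0.75 is
#' calibrated so that the standard minimum-frequency filter (3 cases) keeps
#' roughly 43 of the 114 acupoints, the retention observed in corpora of
#' this kind, while keeping the most-used points near the observed 12-16
#' case range.
#'
#' @param n_cases number of cases (default 114).
#' @param n_acupoints size of the acupoint universe (default 114).
#' @param taxonomy a [load_taxonomy()] object (packaged default when
#'   \code{NULL}).
#' @param n_modules number of planted modules (default 7).
#' @param module_size acupoints per module (default 5).
#' @param alpha concentration of module pattern draws on the preferred set,
#'   in (0, 1] (default 0.7).
#' @param acupoints_per_case_mean Poisson mean m of the per-case acupoint
#'   draw count 1 + Poisson(m) (default 2.0, i.e. 3 mentions/case).
#' @param patterns_per_case_mean as above for patterns (default 8.5, i.e.
#'   9.5 mentions/case).
#' @param zipf_exponent exponent of the background popularity weights
#'   rank^(-exponent) (default 0.75; see Details).
#' @param p_module_case probability a case is module-driven (default 0.6).
#' @param p_module_acupoint probability an acupoint draw of a module-driven
#'   case comes from the module (default 0.8).
#' @param seed integer seed making generation deterministic.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_cases = 114L,
                             n_acupoints = 114L,
                             taxonomy = NULL,
                             n_modules = 7L,
                             module_size = 5L,
                             alpha = 0.7,
                             acupoints_per_case_mean = 2.0,
                             patterns_per_case_mean = 8.5,
                             zipf_exponent = 0.75,
                             p_module_case = 0.6,
                             p_module_acupoint = 0.8,
                             seed = 1L) {
  if (is.null(taxonomy)) taxonomy <- default_taxonomy()
  stopifnot(inherits(taxonomy, "pattern_taxonomy"))
  cfg <- list(n_cases = as.integer(n_cases),
              n_acupoints = as.integer(n_acupoints),
              taxonomy = taxonomy,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              alpha = alpha,
              acupoints_per_case_mean = acupoints_per_case_mean,
              patterns_per_case_mean = patterns_per_case_mean,
              zipf_exponent = zipf_exponent,
              p_module_case = p_module_case,
              p_module_acupoint = p_module_acupoint,
              seed = as.integer(seed))
  if (cfg$n_cases < 1L || cfg$n_acupoints < 1L)
    stop("n_cases and n_acupoints must be positive", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)
  if (cfg$acupoints_per_case_mean <= 0 || cfg$patterns_per_case_mean <= 0)
    stop("per-case means must be positive", call. = FALSE)
  if (cfg$n_modules * cfg$module_size > cfg$n_acupoints)
    stop("module members exceed the acupoint universe", call. = FALSE)
  if (cfg$n_modules > 0L && length(taxonomy$patterns) < 3L)
    stop("taxonomy too small for preferred pattern sets", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic corpus with planted modules
#'
#' See [synthetic_config()] for the generative model. Per-case duplicate
#' draws are collapsed in the stored corpus; the pre-collapse draw totals
#' are reported separately because corpus-scale mention counts are quoted
#' before deduplication.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements \code{corpus} (a canonicalized
#'   \code{acu_corpus}), \code{truth} (a \code{planted_structure}: list with
#'   \code{module_of}, named map acupoint -> module id with \code{0} for
#'   background, and \code{preferred}, list of per-module preferred pattern
#'   sets), \code{n_acupoint_mentions_raw} and \code{n_pattern_mentions_raw}
#'   (pre-collapse draw totals).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  acupoints <- meridian_codes(config$n_acupoints)
  patterns <- config$taxonomy$patterns

  n_mod_members <- config$n_modules * config$module_size
  module_members <- sample(acupoints, n_mod_members)
  module_of <- stats::setNames(integer(length(acupoints)), acupoints)
  members_by_module <- split(module_members,
                             rep(seq_len(config$n_modules),
                                 each = config$module_size))
  for (k in seq_along(members_by_module))
    module_of[members_by_module[[k]]] <- k
  background <- acupoints[module_of == 0L]
  bg_weights <- seq_along(background)^(-config$zipf_exponent)

  preferred <- lapply(seq_len(config$n_modules), function(k)
    sample(patterns, sample(3:5, 1)))

  n_acu_raw <- 0L
  n_pat_raw <- 0L
  cases <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    driven <- config$n_modules > 0L &&
      stats::runif(1) < config$p_module_case
    mod <- if (driven) sample.int(config$n_modules, 1) else 0L
    n_acu <- 1L + stats::rpois(1, config$acupoints_per_case_mean)
    n_pat <- 1L + stats::rpois(1, config$patterns_per_case_mean)
    n_acu_raw <- n_acu_raw + n_acu
    n_pat_raw <- n_pat_raw + n_pat
    acu <- vapply(seq_len(n_acu), function(j) {
      if (driven && stats::runif(1) < config$p_module_acupoint)
        sample(members_by_module[[mod]], 1)
      else
        sample(background, 1, prob = bg_weights)
    }, character(1))
    pat <- vapply(seq_len(n_pat), function(j) {
      if (driven && stats::runif(1) < config$alpha)
        sample(preferred[[mod]], 1)
      else
        sample(patterns, 1)
    }, character(1))
    cases[[i]] <- new_case(sprintf("case%03d", i),
                           sprintf("subchapter%02d", mod + 1L),
                           unique(acu), unique(pat))
  }
  truth <- structure(list(module_of = module_of, preferred = preferred),
                     class = "planted_structure")
  list(corpus = new_corpus(cases, canonicalized = TRUE),
       truth = truth,
       n_acupoint_mentions_raw = n_acu_raw,
       n_pattern_mentions_raw = n_pat_raw)
}

#' Planted module labels
#'
#' @param structure a \code{planted_structure} from [generate_corpus()].
#' @return A named character vector mapping every acupoint to
#'   \code{"module<k>"} or \code{"background"}; the labels partition the
#'   acupoint universe.
#' @export
planted_labels <- function(structure) {
  stopifnot(inherits(structure, "planted_structure"))
  m <- structure$module_of
  stats::setNames(ifelse(m == 0L, "background", paste0("module", m)),
                  names(m))
}

#' Recovery score of detected modules against the planted truth
#'
#' Adjusted Rand index between the detected module memberships and the
#' planted labels, computed over the acupoints that appear in at least one
#' detected module; acupoints in no detected module are excluded, since a
#' thresholded network deliberately leaves weakly associated points
#' unassigned.
#'
#' @param modules list of \code{acu_module} from [extract_modules()].
#' @param truth a \code{planted_structure}.
#' @return The ARI in [-1, 1]; defined as 0 (with a warning) when no module
#'   was detected.
#' @export
recovery_ari <- function(modules, truth) {
  stopifnot(inherits(truth, "planted_structure"))
  if (length(modules) == 0L) {
    warning("no detected modules; recovery ARI defined as 0", call. = FALSE)
    return(0)
  }
  detected <- unlist(lapply(seq_along(modules), function(i)
    stats::setNames(rep(i, length(modules[[i]]$members)),
                    modules[[i]]$members)))
  labels <- planted_labels(truth)[names(detected)]
  if (is.null(names(detected)) || anyNA(labels))
    stop("detected module member absent from planted structure",
         call. = FALSE)
  tab <- table(detected, labels)
  if (nrow(tab) == 1L && ncol(tab) == 1L) return(1)
  unname(e1071::classAgreement(tab)$crand)
}
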