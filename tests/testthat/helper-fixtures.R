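# Shared fixtures: a 4-case hand-enumerable corpus, random small corpora,
# and independent brute-force oracles for tf-idf, connected components and
# the adjusted Rand index.

toy_taxonomy_path <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("raw_term\tcanonical_pattern\tcategory",
               "fire\tfire\tcauses",
               "qi\tqi\tcauses",
               "blood\tblood\tcauses"),
             path)
  path
}

toy_corpus_path <- function() {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"case_id":"c1","subchapter":"s1","acupoints":["LI1","LI2"],"patterns":["fire","qi"]}',
    '{"case_id":"c2","subchapter":"s1","acupoints":["LI1"],"patterns":["fire"]}',
    '{"case_id":"c3","subchapter":"s2","acupoints":["LI2","LI3"],"patterns":["qi","blood"]}',
    '{"case_id":"c4","subchapter":"s2","acupoints":["LI3"],"patterns":["blood"]}'),
    path)
  path
}

toy_corpus <- function() {
  canonicalize_corpus(load_corpus(toy_corpus_path()),
                      load_taxonomy(toy_taxonomy_path()))
}

# random already-canonical corpus over a small universe
random_corpus <- function(seed, max_cases = 8,
                          acupoints = paste0("LI", 1:6),
                          patterns = c("blood", "cold", "fire", "qi", "wind")) {
  set.seed(seed)
  n <- sample.int(max_cases, 1)
  cases <- lapply(seq_len(n), function(i) {
    list(case_id = paste0("c", i), subchapter = "s",
         acupoints = sample(acupoints,
                            sample.int(min(3L, length(acupoints)), 1)),
         patterns = sample(patterns, sample.int(3L, 1)))
  })
  new_corpus(cases, canonicalized = TRUE)
}

# brute-force tf-idf straight from the case list: triple loop over
# (document, term, case), natural log
oracle_tfidf <- function(corpus, direction) {
  cases <- corpus$cases
  acus <- sort(unique(unlist(lapply(cases, `[[`, "acupoints"))))
  pats <- sort(unique(unlist(lapply(cases, `[[`, "patterns"))))
  docs <- if (direction == "pattern_as_term") acus else pats
  terms <- if (direction == "pattern_as_term") pats else acus
  tf <- matrix(0, length(docs), length(terms), dimnames = list(docs, terms))
  for (d in docs) for (t in terms) for (cs in cases) {
    a <- if (direction == "pattern_as_term") d else t
    p <- if (direction == "pattern_as_term") t else d
    if (a %in% cs$acupoints && p %in% cs$patterns) tf[d, t] <- tf[d, t] + 1
  }
  w <- tf
  for (t in terms) {
    df_t <- sum(tf[, t] > 0)
    w[, t] <- if (df_t > 0) tf[, t] * log(length(docs) / df_t) else 0
  }
  w
}

# brute-force case-level co-occurrence: double loop over cells, inner loop
# over cases
oracle_cooccurrence <- function(corpus) {
  cases <- corpus$cases
  acus <- sort(unique(unlist(lapply(cases, `[[`, "acupoints"))))
  pats <- sort(unique(unlist(lapply(cases, `[[`, "patterns"))))
  m <- matrix(0L, length(acus), length(pats), dimnames = list(acus, pats))
  for (a in acus) for (p in pats)
    m[a, p] <- sum(vapply(cases, function(cs)
      a %in% cs$acupoints && p %in% cs$patterns, logical(1)))
  m
}

# connected components by boolean transitive closure; returns membership ids
oracle_components <- function(adj) {
  stopifnot(isSymmetric(adj))
  reach <- adj | diag(TRUE, nrow(adj))
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  keys <- apply(reach, 1, paste, collapse = "")
  match(keys, unique(keys))
}

# adjusted Rand index by the pair-counting formula
oracle_ari <- function(x, y) {
  stopifnot(length(x) == length(y))
  ct <- table(x, y)
  sij <- sum(choose(ct, 2))
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  stot <- choose(length(x), 2)
  expected <- si * sj / stot
  (sij - expected) / ((si + sj) / 2 - expected)
}

# build a weight_matrix object directly (for normalization / ranking tests
# that need a specific numeric layout)
make_weights <- function(w, direction = "pattern_as_term",
                         normalized = FALSE) {
  structure(list(weights = w, direction = direction,
                 normalized = normalized, n_documents = nrow(w),
                 log_base = "e"),
            class = "weight_matrix")
}

# build an acu_distance object directly
make_distances <- function(d) {
  structure(list(d = d, defined = rep(TRUE, nrow(d))), class = "acu_distance")
}

run_recovery <- function(seed, alpha = 0.7, percentile = 1) {
  sim <- generate_corpus(synthetic_config(seed = seed, alpha = alpha))
  m <- filter_min_count(build_cooccurrence(sim$corpus), 3)
  w <- cosine_normalize(compute_tfidf(m, "pattern_as_term"))
  dm <- distance_matrix(w)
  thr <- select_threshold(dm, "percentile", percentile)
  mods <- extract_modules(build_network(dm, thr))
  list(sim = sim, filtered = m, weights = w, distances = dm,
       modules = mods, ari = recovery_ari(mods, sim$truth))
}
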