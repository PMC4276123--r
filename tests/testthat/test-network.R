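test_that("correlation distance covers the identity, inversion and fixture", {
  x <- c(1, 2, 3, 5)
  expect_equal(correlation_distance(x, x), 0, tolerance = 1e-12)
  expect_equal(correlation_distance(x, -x + 7), 2, tolerance = 1e-12)
  expect_error(correlation_distance(x, x[1:3]), "length")
  expect_true(is.na(correlation_distance(x, rep(1, 4))))

  a1 <- c(1, 0, 0)
  a2 <- c(0.70711, 0, 0.70711)
  a3 <- c(0, 0, 1)
  expect_equal(correlation_distance(a1, a2), 0.5, tolerance = 1e-5)
  expect_equal(correlation_distance(a1, a3), 1.5, tolerance = 1e-12)
})

test_that("the distance matrix is symmetric, bounded and masks constants", {
  wn <- cosine_normalize(compute_tfidf(build_cooccurrence(toy_corpus()),
                                       "pattern_as_term"))
  dm <- distance_matrix(wn)
  expect_equal(unname(dm$d["LI1", "LI2"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(dm$d["LI1", "LI3"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(dm$d["LI2", "LI3"]), 0.5, tolerance = 1e-9)
  expect_true(all(diag(dm$d) == 0))

  # duplicated profile rows sit at distance zero
  w <- make_weights(matrix(c(1, 2, 3,
                             2, 4, 6,
                             3, 1, 2), nrow = 3, byrow = TRUE,
                           dimnames = list(c("a", "b", "c"), NULL)))
  dm2 <- distance_matrix(w)
  expect_equal(unname(dm2$d["a", "b"]), 0, tolerance = 1e-12)

  # constant rows are masked, not errors
  wc <- make_weights(matrix(c(1, 2, 3,
                              5, 5, 5), nrow = 2, byrow = TRUE,
                            dimnames = list(c("a", "k"), NULL)))
  expect_warning(dm3 <- distance_matrix(wc), "k")
  expect_false(dm3$defined["k"])
  expect_true(all(is.na(dm3$d["k", ])))

  expect_error(distance_matrix(make_weights(matrix(1:3, nrow = 1))),
               "at least 2")
  expect_error(
    distance_matrix(make_weights(matrix(1:4, 2), "acupoint_as_term")),
    "pattern_as_term")

  for (seed in 1:20) {
    m <- build_cooccurrence(random_corpus(seed, max_cases = 6))
    if (nrow(m$counts) < 2 || ncol(m$counts) < 2) next
    w <- suppressWarnings(cosine_normalize(compute_tfidf(m, "pattern_as_term")))
    d <- suppressWarnings(distance_matrix(w))$d
    ok <- !is.na(d)
    expect_true(all(d[ok] >= -1e-9 & d[ok] <= 2 + 1e-9))
    expect_equal(d, t(d), tolerance = 1e-12)
  }
})

test_that("distances ignore positive rescaling of profile rows", {
  set.seed(7)
  w <- make_weights(matrix(stats::rexp(30), nrow = 5,
                           dimnames = list(paste0("d", 1:5), NULL)))
  scaled <- w
  scaled$weights <- w$weights * stats::runif(5, 0.1, 9)
  expect_equal(distance_matrix(scaled)$d, distance_matrix(w)$d,
               tolerance = 1e-12)
})

test_that("threshold selection supports fixed values and interpolated percentiles", {
  wn <- cosine_normalize(compute_tfidf(build_cooccurrence(toy_corpus()),
                                       "pattern_as_term"))
  dm <- distance_matrix(wn)
  expect_identical(select_threshold(dm, "fixed", 0.1), 0.1)
  expect_error(select_threshold(dm, "fixed", 0), "> 0")
  expect_error(select_threshold(dm, "percentile", 0), "percentile")
  expect_error(select_threshold(dm, "percentile", 100), "percentile")

  # all off-diagonals equal -> any percentile returns that value
  deq <- make_distances(matrix(c(0, 0.3, 0.3,
                                 0.3, 0, 0.3,
                                 0.3, 0.3, 0), nrow = 3, byrow = TRUE,
                               dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(select_threshold(deq, "percentile", 1), 0.3)

  # ten equally spaced off-diagonals: interpolated median is 0.55
  vals <- seq(0.1, 1.0, by = 0.1)
  d5 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  d5[upper.tri(d5)] <- vals
  d5 <- d5 + t(d5)
  expect_equal(select_threshold(make_distances(d5), "percentile", 50), 0.55,
               tolerance = 1e-12)
})

test_that("linkage is strict and keeps isolated nodes", {
  wn <- cosine_normalize(compute_tfidf(build_cooccurrence(toy_corpus()),
                                       "pattern_as_term"))
  dm <- distance_matrix(wn)
  net01 <- build_network(dm, 0.1)
  expect_identical(nrow(network_edges(net01)), 0L)
  expect_equal(igraph::vcount(net01$graph), 3)

  net06 <- build_network(dm, 0.6)
  e <- network_edges(net06)
  expect_identical(paste(e$node_a, e$node_b), c("LI1 LI2", "LI2 LI3"))

  # a distance exactly at the threshold is not an edge (strict inequality)
  exact <- make_distances(matrix(c(0, 0.5, 0.5, 0), 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
  expect_identical(nrow(network_edges(build_network(exact, 0.5))), 0L)
  expect_identical(nrow(network_edges(build_network(exact, 0.5 + 1e-9))), 1L)
})

test_that("modules are >=2-node components with max-degree hubs", {
  path <- make_distances(matrix(
    c(0, 0.1, 0.9, 0.9,
      0.1, 0, 0.1, 0.9,
      0.9, 0.1, 0, 0.9,
      0.9, 0.9, 0.9, 0),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))))
  mods <- extract_modules(build_network(path, 0.2))
  expect_length(mods, 1)
  expect_identical(mods[[1]]$members, c("A", "B", "C"))
  expect_identical(mods[[1]]$hub, "B")

  expect_length(extract_modules(build_network(path, 0.05)), 0)

  # complete graph: three-way degree tie resolved lexicographically
  k3 <- make_distances(matrix(0.05, 3, 3,
                              dimnames = list(c("C", "A", "B"),
                                              c("C", "A", "B"))))
  diag(k3$d) <- 0
  mods <- extract_modules(build_network(k3, 0.1))
  expect_identical(mods[[1]]$hub, "A")
})

test_that("modules come back ordered by size then smallest member", {
  d <- matrix(2, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
  diag(d) <- 0
  d["E", "F"] <- d["F", "E"] <- 0.01
  d["A", "B"] <- d["B", "A"] <- 0.01
  d["B", "C"] <- d["C", "B"] <- 0.01
  mods <- extract_modules(build_network(make_distances(d), 0.1))
  expect_identical(lapply(mods, `[[`, "members"),
                   list(c("A", "B", "C"), c("E", "F")))
})

test_that("components agree with the transitive-closure oracle", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(2:12, 1)
    labels <- sprintf("N%02d", seq_len(n))
    d <- matrix(stats::runif(n * n, 0, 2), n, n,
                dimnames = list(labels, labels))
    d <- (d + t(d)) / 2
    diag(d) <- 0
    thr <- stats::runif(1, 0.05, 1)
    net <- build_network(make_distances(d), thr)
    comp <- igraph::components(net$graph)$membership
    adj <- d < thr & upper.tri(d) | t(d < thr & upper.tri(d))
    oracle <- oracle_components(adj)
    # same partition after canonical renumbering by first occurrence
    canon <- function(v) match(v, unique(v))
    expect_identical(canon(unname(comp)), canon(oracle),
                     label = paste("seed", seed))
  }
})

test_that("raising the threshold coarsens the network monotonically", {
  sim <- generate_corpus(synthetic_config(seed = 3))
  m <- filter_min_count(build_cooccurrence(sim$corpus), 3)
  dm <- distance_matrix(cosine_normalize(compute_tfidf(m, "pattern_as_term")))
  thresholds <- c(0.05, 0.1, 0.3, 0.6, 1.0, 1.5)
  edges <- comps <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    net <- build_network(dm, thresholds[i])
    edges[i] <- igraph::ecount(net$graph)
    comps[i] <- igraph::components(net$graph)$no
  }
  expect_true(all(diff(edges) >= 0))
  expect_true(all(diff(comps) <= 0))
})
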