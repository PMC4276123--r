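toy_normalized <- function() {
  cosine_normalize(compute_tfidf(build_cooccurrence(toy_corpus()),
                                 "pattern_as_term"))
}

test_that("module mean profiles average member rows exactly", {
  wn <- toy_normalized()
  single <- structure(list(members = "LI1", hub = "LI1",
                           edges = data.frame()), class = "acu_module")
  pr <- module_mean_profile(single, wn)
  expect_equal(pr$profile, wn$weights["LI1", ], tolerance = 1e-12)

  two <- structure(list(members = c("LI1", "LI2"), hub = "LI1",
                        edges = data.frame()), class = "acu_module")
  pr <- module_mean_profile(two, wn)
  expect_equal(unname(pr$profile[c("fire", "qi", "blood")]),
               c(0.85355, 0, 0.35355), tolerance = 1e-5)
  expect_equal(pr$profile,
               colMeans(wn$weights[c("LI1", "LI2"), ]), tolerance = 1e-12)

  w <- make_weights(matrix(c(1, 0, 0,
                             0, 0, 1), nrow = 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("x", "y", "z"))),
                    normalized = TRUE)
  m <- structure(list(members = c("a", "b"), hub = "a",
                      edges = data.frame()), class = "acu_module")
  expect_equal(unname(module_mean_profile(m, w)$profile), c(0.5, 0, 0.5))

  missing <- structure(list(members = c("LI1", "GB20"), hub = "LI1",
                            edges = data.frame()), class = "acu_module")
  expect_error(module_mean_profile(missing, wn), "GB20")
  raw <- compute_tfidf(build_cooccurrence(toy_corpus()), "pattern_as_term")
  expect_error(module_mean_profile(single, raw), "normalized")
})

test_that("profiles carry taxonomy categories and stay in [0, 1]", {
  res <- run_recovery(5)
  tax <- default_taxonomy()
  for (mod in res$modules) {
    pr <- module_mean_profile(mod, res$weights, tax)
    expect_length(pr$profile, 25)
    expect_true(all(pr$profile >= 0 & pr$profile <= 1))
    expect_setequal(unique(unname(pr$category)),
                    intersect(unique(unname(tax$canonical_to_category)),
                              pr$category))
  }
})

test_that("reverse-direction ranking finds pattern-specific acupoints", {
  w_ap <- cosine_normalize(compute_tfidf(build_cooccurrence(toy_corpus()),
                                         "acupoint_as_term"))
  top <- rank_for_pattern(w_ap, "fire", 5)
  expect_identical(top$term[1], "LI1")
  expect_error(rank_for_pattern(w_ap, "dampness", 5), "unknown document")
  expect_error(rank_for_pattern(toy_normalized(), "fire", 5),
               "acupoint_as_term")
  # k larger than the number of nonzero weights shortens the list
  expect_lte(nrow(rank_for_pattern(w_ap, "fire", 50)), 3)
  # an all-zero document yields an empty ranking
  wz <- make_weights(matrix(c(0, 0, 1, 2), nrow = 2, byrow = TRUE,
                            dimnames = list(c("p0", "p1"), c("a", "b"))),
                     direction = "acupoint_as_term")
  expect_identical(nrow(rank_for_pattern(wz, "p0", 5)), 0L)
})

test_that("heatmap renders deterministically with category bands", {
  res <- run_recovery(2)
  tax <- default_taxonomy()
  fs <- tempfile(fileext = ".svg")
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  p <- render_heatmap(res$weights, tax, fs,
                      acupoint_freq = res$filtered$acupoint_freq)
  render_heatmap(res$weights, tax, f1,
                 acupoint_freq = res$filtered$acupoint_freq)
  render_heatmap(res$weights, tax, f2,
                 acupoint_freq = res$filtered$acupoint_freq)
  expect_true(file.exists(fs) && file.size(fs) > 0)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(nlevels(p$data$pattern), 25L)
  expect_identical(nlevels(p$data$category), 3L)
  expect_equal(as.vector(table(p$data$category)) / nlevels(p$data$acupoint),
               c(5, 12, 8))
})

test_that("radar charts expose one axis per canonical pattern", {
  wn <- toy_normalized()
  mod <- structure(list(members = c("LI1", "LI2"), hub = "LI1",
                        edges = data.frame()), class = "acu_module")
  pr <- module_mean_profile(mod, wn)
  f <- tempfile(fileext = ".svg")
  p <- render_radar(pr, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_identical(nlevels(p$data$pattern), 3L)

  # one-hot profile renders a single spike without error
  hot <- pr
  hot$profile[] <- 0
  hot$profile["fire"] <- 1
  f2 <- tempfile(fileext = ".png")
  render_radar(hot, f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
})

test_that("the pipeline writes every artifact and is reproducible", {
  out1 <- file.path(tempfile(), "run1")
  cfg <- list(simulate = list(), seed = 11, min_count = 3,
              threshold_mode = "percentile", threshold_value = 1,
              outdir = out1, figures = FALSE)
  res <- run_pipeline(cfg)
  artifacts <- c("corpus_summary.tsv", "acupoint_frequencies.tsv",
                 "pattern_frequencies.tsv", "weights_pattern_as_term.tsv",
                 "weights_acupoint_as_term.tsv",
                 "top_patterns_per_acupoint.tsv",
                 "top_acupoints_per_pattern.tsv", "network_edges.tsv",
                 "module_membership.tsv", "module_profiles.tsv",
                 "run_log.txt")
  expect_true(all(file.exists(file.path(out1, artifacts))))

  out2 <- file.path(tempfile(), "run2")
  cfg$outdir <- out2
  run_pipeline(cfg)
  for (a in setdiff(artifacts, "run_log.txt"))
    expect_identical(readLines(file.path(out1, a)),
                     readLines(file.path(out2, a)), label = a)

  # frequency columns in the rank tables match count_frequencies exactly
  t1 <- utils::read.delim(file.path(out1, "top_patterns_per_acupoint.tsv"),
                          check.names = FALSE)
  af <- count_frequencies(res$corpus, "acupoint")
  expect_identical(t1$frequency,
                   unname(as.integer(af[t1$document])))
  t2 <- utils::read.delim(file.path(out1, "top_acupoints_per_pattern.tsv"),
                          check.names = FALSE)
  pf <- count_frequencies(res$corpus, "pattern")
  expect_identical(t2$frequency, unname(as.integer(pf[t2$document])))

  # every module member appears in exactly one membership row
  mm <- utils::read.delim(file.path(out1, "module_membership.tsv"))
  if (nrow(mm)) {
    expect_false(any(duplicated(mm$acupoint)))
    expect_identical(sort(mm$acupoint),
                     sort(unlist(lapply(res$modules, `[[`, "members"))))
  }
})

test_that("the pipeline handles a plain corpus file and reports its shape", {
  out <- tempfile()
  cfg <- list(corpus = toy_corpus_path(), taxonomy = toy_taxonomy_path(),
              min_count = 1, threshold_mode = "fixed", threshold_value = 0.6,
              outdir = out, figures = FALSE)
  run_pipeline(cfg)
  t1 <- utils::read.delim(file.path(out, "top_patterns_per_acupoint.tsv"),
                          check.names = FALSE)
  expect_identical(nrow(t1), 3L)  # one row per retained acupoint
  expect_identical(names(t1)[1:2], c("document", "frequency"))
  expect_true(all(paste0("rank_", 1:5) %in% names(t1)))
  mm <- utils::read.delim(file.path(out, "module_membership.tsv"))
  expect_identical(sort(mm$acupoint), c("LI1", "LI2", "LI3"))
  expect_true(all(mm$hub == "LI2"))
})

test_that("pipeline errors name the failing stage", {
  expect_error(run_pipeline(list(corpus = tempfile(fileext = ".jsonl"),
                                 outdir = tempfile(), figures = FALSE)),
               "\\[corpus\\]")
})
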