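test_that("two drugs with identical features and labels predict each other", {
  # both drug terms are children of the same parent, so each fold's single
  # training drug transfers its labels to the held-out query
  g <- parse_obo(obo_file(term_stanza("P"), term_stanza("T1", "P"),
                          term_stanza("T2", "P")))
  ds <- benchmark_dataset(c("a", "b"), c("CCO", "CCO"), c("T1", "T2"),
                          list(c(1L, 3L), c(1L, 3L)), n_classes = 4L)
  m <- jackknife(ds, 1 / 36, method = "do", graph = g)
  expect_equal(m$absolute_true, 1)
  expect_equal(m$absolute_false, 0)
})

test_that("all-zero features (ontology islands) still yield defined metrics", {
  g <- parse_obo(obo_file(term_stanza("T1"), term_stanza("T2"),
                          term_stanza("T3")))
  ds <- benchmark_dataset(c("a", "b", "c"), "CCO", c("T1", "T2", "T3"),
                          list(1L, 2L, 3L), n_classes = 3L)
  m <- jackknife(ds, 1 / 36, method = "do", graph = g,
                 return_predictions = TRUE)
  expect_true(all(lengths(m$predicted) > 0L))
  expect_true(all(unlist(m$metrics[1:5]) >= 0))
  expect_error(jackknife(ds[1L], 1 / 36, method = "do", graph = g),
               class = "mlatc_evaluation_error")
})

test_that("jackknife is invariant under record order", {
  gen <- generate_benchmark(synthetic_config(n_classes = 5L,
                                             drugs_per_class = 6L,
                                             multi_label_fraction = 0.2))
  ds <- gen$benchmark
  base <- jackknife(ds, 1 / 36, method = "do", graph = gen$ontology,
                    return_predictions = TRUE)
  set.seed(77)
  perm <- sample.int(length(ds))
  shuf <- jackknife(ds[perm], 1 / 36, method = "do", graph = gen$ontology,
                    return_predictions = TRUE)
  expect_identical(shuf$predicted[ds$drug_id], base$predicted[ds$drug_id])
  expect_equal(unclass(shuf$metrics), unclass(base$metrics), tolerance = 1e-12)
})

test_that("hybrid jackknife equals routing each held-out drug end-to-end", {
  gen <- generate_benchmark(synthetic_config(n_classes = 3L,
                                             drugs_per_class = 4L,
                                             multi_label_fraction = 0.25,
                                             seed = 6L))
  ds <- gen$benchmark
  ds$chebi_id[c(2L, 5L, 9L)] <- NA_character_
  res <- jackknife(ds, 1 / 36, method = "hybrid", graph = gen$ontology,
                   return_predictions = TRUE)
  for (k in seq_len(length(ds))) {
    rest <- ds[-k]
    hyb <- build_hybrid(rest, gen$ontology, theta = 1 / 36)
    p <- predict_hybrid(get_record(ds, k), hyb)
    expect_identical(res$predicted[[k]], p$labels)
    covered <- isTRUE(term_exists(gen$ontology, ds$chebi_id[[k]]))
    expect_identical(p$sub_predictor, if (covered) "DO" else "FALLBACK")
  }
})

test_that("theta grid search maximizes absolute true and is reproducible", {
  gen <- generate_benchmark(synthetic_config(n_classes = 4L,
                                             drugs_per_class = 5L,
                                             multi_label_fraction = 0.2))
  ds <- gen$benchmark

  single <- optimize_theta(ds, grid = 0.5, method = "do", graph = gen$ontology)
  expect_identical(single$best_theta, 0.5)

  curve <- optimize_theta(ds, grid = c(1, 1 / 4, 1 / 36), method = "do",
                          graph = gen$ontology)
  expect_true(all(curve$best_rate >= curve$absolute_true_at))
  rerun <- jackknife(ds, curve$best_theta, method = "do", graph = gen$ontology)
  expect_identical(rerun$absolute_true, curve$best_rate)

  expect_true(any(abs(default_theta_grid() - 1 / 36) < 1e-15))
  expect_error(optimize_theta(ds, grid = numeric(), method = "do",
                              graph = gen$ontology),
               class = "mlatc_config_error")
})

test_that("extreme grid picks the nearest-neighbour regime when it is perfect", {
  # two tight clusters with opposite labels: the nearest neighbour is always
  # right, while the global label mean predicts the majority class everywhere
  g <- parse_obo(obo_file(
    term_stanza("R"), term_stanza("P1", "R"), term_stanza("P2", "R"),
    unlist(lapply(1:5, function(i) term_stanza(sprintf("A%d", i), "P1"))),
    unlist(lapply(1:3, function(i) term_stanza(sprintf("B%d", i), "P2")))))
  ds <- benchmark_dataset(
    sprintf("d%d", 1:8), "CCO",
    c(sprintf("A%d", 1:5), sprintf("B%d", 1:3)),
    c(as.list(rep(1L, 5)), as.list(rep(2L, 3))), n_classes = 2L)
  curve <- optimize_theta(ds, grid = c(1e-6, 1e6), method = "do", graph = g)
  expect_identical(curve$best_theta, 1e-6)
  expect_gt(curve$absolute_true_at[[1L]], curve$absolute_true_at[[2L]])
})

test_that("theta curves serialize to a two-column TSV", {
  gen <- generate_benchmark(synthetic_config(n_classes = 3L, drugs_per_class = 3L))
  curve <- optimize_theta(gen$benchmark, grid = c(0.1, 1), method = "do",
                          graph = gen$ontology)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_theta_curve(curve, path)
  tab <- utils::read.delim(path)
  expect_equal(names(tab), c("theta", "absolute_true"))
  expect_equal(tab$theta, curve$grid)
  expect_equal(tab$absolute_true, curve$absolute_true_at)
})
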