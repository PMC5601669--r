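write_bench_text <- function(lines, n_classes = 14L) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  header <- paste(c("drug_id", "smiles", "chebi_id",
                    paste0("ATC", seq_len(n_classes))), collapse = "\t")
  writeLines(c(header, lines), path)
  path
}

bits <- function(on, n = 14L) {
  v <- rep(0L, n)
  v[on] <- 1L
  paste(v, collapse = "\t")
}

test_that("read_benchmark decodes 0/1 label columns into label sets", {
  path <- write_bench_text(c(
    paste("d1", "CCO", "CHEBI:1", bits(c(3, 5, 9)), sep = "\t"),
    paste("d2", "CCN", "", bits(3), sep = "\t")
  ))
  ds <- read_benchmark(path)
  expect_equal(length(ds), 2L)
  expect_equal(ds$labels[[1L]], c(3L, 5L, 9L))
  expect_equal(ds$labels[[2L]], 3L)
  expect_true(is.na(ds$chebi_id[[2L]]))
  expect_equal(ds$n_classes, 14L)
})

test_that("read_benchmark rejects malformed input", {
  expect_error(read_benchmark(write_bench_text(
    paste("d1", "CCO", "", bits(integer()), sep = "\t"))),
    class = "mlatc_format_error")  # all-zero label row
  expect_error(read_benchmark(write_bench_text(c(
    paste("d1", "CCO", "", bits(1), sep = "\t"),
    paste("d1", "CCN", "", bits(2), sep = "\t")))),
    class = "mlatc_format_error")  # duplicate id
  expect_error(read_benchmark(write_bench_text(
    paste("d1", "CCO", "", "2", paste(rep("0", 13), collapse = "\t"), sep = "\t"))),
    class = "mlatc_format_error")  # cell not in {0,1}
  expect_error(read_benchmark(tempfile()), class = "mlatc_io_error")
})

test_that("write_benchmark / read_benchmark round-trips records exactly", {
  gen <- generate_benchmark(synthetic_config(n_classes = 5L, drugs_per_class = 4L,
                                             multi_label_fraction = 0.5))
  ds <- gen$benchmark
  ds$chebi_id[[2L]] <- NA_character_  # include an unmapped drug
  path <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(ds, path)
  back <- read_benchmark(path)
  expect_identical(back$drug_id, ds$drug_id)
  expect_identical(back$smiles, ds$smiles)
  expect_identical(back$chebi_id, ds$chebi_id)
  expect_identical(back$labels, ds$labels)
  # a second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("class_breakdown counts one virtual drug per class membership", {
  ds <- benchmark_dataset(c("a", "b"), c("C", "C"), NA,
                          list(c(1L, 2L), 2L))
  bd <- class_breakdown(ds)
  expect_equal(bd$counts, c(1L, 2L, rep(0L, 12)))
  expect_equal(bd$total_virtual, 3L)
  expect_equal(bd$total_distinct, 2L)

  empty <- benchmark_dataset(character(), character(), character(), list())
  bd0 <- class_breakdown(empty)
  expect_equal(bd0$counts, rep(0L, 14))
  expect_equal(bd0$total_virtual, 0L)
})

test_that("multiplicity distribution and breakdown totals are consistent", {
  ds <- benchmark_dataset(c("a", "b"), c("C", "C"), NA,
                          list(c(1L, 2L), 2L))
  expect_equal(multiplicity_distribution(ds), c("1" = 1L, "2" = 1L))
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(2:40, 1L)
    labels <- lapply(seq_len(n), function(i) sample.int(14L, sample.int(6L, 1L)))
    ds <- benchmark_dataset(sprintf("d%d", seq_len(n)), "C", NA, labels)
    bd <- class_breakdown(ds)
    mult <- multiplicity_distribution(ds)
    ks <- as.integer(names(mult))
    expect_equal(sum(mult), bd$total_distinct)
    expect_equal(sum(ks * mult), bd$total_virtual)
  }
})

test_that("split_by_coverage partitions on resolvable ontology terms", {
  g <- parse_obo(obo_file(term_stanza("A"), term_stanza("B", "A"),
                          term_stanza("OLD", "A", obsolete = TRUE)))
  ds <- benchmark_dataset(c("a", "b", "c", "d"), "C",
                          c("B", NA, "OLD", "UNKNOWN"),
                          list(1L, 2L, 3L, 4L))
  parts <- split_by_coverage(ds, g)
  expect_equal(parts$covered$drug_id, "a")
  expect_equal(parts$uncovered$drug_id, c("b", "c", "d"))
  expect_equal(length(parts$covered) + length(parts$uncovered), length(ds))
})
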