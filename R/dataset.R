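#' Multi-label drug benchmarks
#'
#' A `benchmark_dataset` holds an ordered collection of drug records. Each
#' record has a unique drug identifier, a SMILES string (carried verbatim;
#' validity is checked only when fingerprints are computed), an optional
#' ontology term identifier (ChEBI-style; `NA` when the drug is unmapped),
#' and a non-empty set of class labels over the label universe `1..n_classes`
#' (14 for the main ATC classes). Class indexing is 1-based on every
#' external surface.
#'
#' @name benchmark
NULL

#' @describeIn benchmark Construct a dataset from parallel vectors.
#'   `labels` is a list of integer vectors, one per drug.
#' @param drug_id Character vector of unique drug identifiers.
#' @param smiles Character vector of SMILES strings.
#' @param chebi_id Character vector of ontology term identifiers
#'   (`NA` = unmapped).
#' @param labels List of integer vectors; each must be a non-empty subset of
#'   `1..n_classes`.
#' @param n_classes Size of the label universe (default 14).
#' @export
benchmark_dataset <- function(drug_id, smiles, chebi_id = NA_character_,
                              labels, n_classes = 14L) {
  drug_id <- as.character(drug_id)
  n <- length(drug_id)
  smiles <- rep_len(as.character(smiles), n)
  chebi_id <- rep_len(as.character(chebi_id), n)
  chebi_id[!is.na(chebi_id) & !nzchar(chebi_id)] <- NA_character_
  n_classes <- as.integer(n_classes)
  if (!is.list(labels) || length(labels) != n) {
    format_error("labels must be a list with one element per drug")
  }
  labels <- lapply(labels, function(l) sort(unique(as.integer(l))))
  if (anyDuplicated(drug_id)) {
    format_error(sprintf("duplicate drug_id '%s'", drug_id[duplicated(drug_id)][[1L]]))
  }
  for (i in seq_len(n)) {
    l <- labels[[i]]
    if (length(l) == 0L) {
      format_error(sprintf("drug '%s' has an empty label set", drug_id[[i]]))
    }
    if (any(l < 1L | l > n_classes)) {
      format_error(sprintf("drug '%s' has a label outside 1..%d", drug_id[[i]], n_classes))
    }
  }
  structure(
    list(drug_id = drug_id, smiles = smiles, chebi_id = chebi_id,
         labels = labels, n_classes = n_classes),
    class = "benchmark_dataset"
  )
}

#' @export
length.benchmark_dataset <- function(x) length(x$drug_id)

#' @export
`[.benchmark_dataset` <- function(x, i) {
  benchmark_dataset(x$drug_id[i], x$smiles[i], x$chebi_id[i],
                    x$labels[i], x$n_classes)
}

#' @describeIn benchmark Extract the `i`-th record as a `drug_record` list
#'   with fields `drug_id`, `smiles`, `chebi_id`, `labels`.
#' @param ds A `benchmark_dataset`.
#' @param i Record index.
#' @export
get_record <- function(ds, i) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  drug_record(ds$drug_id[[i]], ds$smiles[[i]], ds$chebi_id[[i]], ds$labels[[i]])
}

#' @describeIn benchmark Construct a single drug record.
#' @export
drug_record <- function(drug_id, smiles, chebi_id = NA_character_,
                        labels = integer()) {
  chebi_id <- as.character(chebi_id)
  if (length(chebi_id) == 0L || (!is.na(chebi_id) && !nzchar(chebi_id))) {
    chebi_id <- NA_character_
  }
  structure(
    list(drug_id = as.character(drug_id), smiles = as.character(smiles),
         chebi_id = chebi_id, labels = sort(unique(as.integer(labels)))),
    class = "drug_record"
  )
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("<benchmark_dataset> %d drugs, %d classes, %d multi-label\n",
              length(x), x$n_classes, sum(lengths(x$labels) > 1L)))
  invisible(x)
}

#' @describeIn benchmark 0/1 membership matrix (drugs in rows, classes in
#'   columns; `dimnames` carry drug ids).
#' @export
label_matrix <- function(ds) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  m <- matrix(0L, length(ds), ds$n_classes,
              dimnames = list(ds$drug_id, NULL))
  for (i in seq_len(length(ds))) m[i, ds$labels[[i]]] <- 1L
  m
}

#' Read a multi-label benchmark table
#'
#' The benchmark file is tab-separated with a header row and columns
#' `drug_id`, `smiles`, `chebi_id` (empty allowed), followed by one 0/1
#' column per class: a `1` in class column *m* means the drug occurs in
#' class *m*. Every drug must carry at least one class, drug ids must be
#' unique, and label cells must be exactly `0` or `1`.
#'
#' @param path Path to a benchmark TSV file.
#' @return A `benchmark_dataset`.
#' @export
read_benchmark <- function(path) {
  if (!file.exists(path)) io_error(sprintf("cannot read benchmark file '%s'", path))
  tab <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "", comment.char = "")
  if (ncol(tab) < 4L) {
    format_error("benchmark file needs drug_id, smiles, chebi_id plus label columns")
  }
  n_classes <- ncol(tab) - 3L
  cells <- as.matrix(tab[, -(1:3), drop = FALSE])
  bad <- which(!(cells %in% c("0", "1")))
  if (length(bad) > 0L) {
    format_error(sprintf("label cell not in {0,1}: '%s' (drug '%s')",
                         cells[bad[[1L]]], tab[[1L]][(bad[[1L]] - 1L) %% nrow(tab) + 1L]))
  }
  labels <- apply(cells == "1", 1L, which, simplify = FALSE)
  empty <- lengths(labels) == 0L
  if (any(empty)) {
    format_error(sprintf("drug '%s' has all-zero labels", tab[[1L]][which(empty)[[1L]]]))
  }
  benchmark_dataset(tab[[1L]], tab[[2L]], tab[[3L]], labels, n_classes)
}

#' Write a multi-label benchmark table
#'
#' Emits the dialect [read_benchmark()] consumes: tab-separated, UTF-8,
#' Unix newlines, label cells written as `0`/`1`, unmapped `chebi_id` as an
#' empty field — so a write/read cycle is the identity on records.
#'
#' @param ds A `benchmark_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(ds, path) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  m <- label_matrix(ds)
  header <- paste(c("drug_id", "smiles", "chebi_id",
                    paste0("ATC", seq_len(ds$n_classes))), collapse = "\t")
  chebi <- ifelse(is.na(ds$chebi_id), "", ds$chebi_id)
  rows <- paste(ds$drug_id, ds$smiles, chebi,
                apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Per-class breakdown of a benchmark
#'
#' Counts the size of every class subset. A drug occurring in several
#' classes is counted once per class, so the sum of the per-class counts
#' (the number of "virtual" drugs) exceeds the number of structurally
#' distinct drugs whenever the dataset is multi-label.
#'
#' @param ds A `benchmark_dataset`.
#' @return List with `counts` (integer vector of length `n_classes`),
#'   `total_virtual` and `total_distinct`.
#' @export
class_breakdown <- function(ds) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  counts <- integer(ds$n_classes)
  tab <- tabulate(as.integer(unlist(ds$labels)), nbins = ds$n_classes)
  counts[] <- tab
  list(counts = counts, total_virtual = sum(counts),
       total_distinct = length(ds))
}

#' Label-multiplicity distribution of a benchmark
#'
#' @param ds A `benchmark_dataset`.
#' @return Named integer vector: entry `"k"` is the number of drugs carrying
#'   exactly `k` labels (only occupied multiplicities are reported).
#' @export
multiplicity_distribution <- function(ds) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  k <- lengths(ds$labels)
  tab <- table(factor(k, levels = sort(unique(k))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Split a benchmark by ontology coverage
#'
#' Partitions the dataset into the drugs whose `chebi_id` resolves to a
#' (non-obsolete) term of the ontology — the subset the ontology-based
#' predictor can formulate — and the rest, preserving record order.
#'
#' @param ds A `benchmark_dataset`.
#' @param graph An `ontology_graph`.
#' @return List with `covered` and `uncovered` benchmark datasets.
#' @export
split_by_coverage <- function(ds, graph) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  ok <- term_exists(graph, ds$chebi_id)
  list(covered = ds[ok], uncovered = ds[!ok])
}
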