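#' Per-class maximum-similarity feature vectors
#'
#' A drug is encoded as the 14-dimensional vector
#' \eqn{[\alpha_1 \ldots \alpha_{14}]} whose component \eqn{\alpha_m} is the
#' maximum similarity between the drug and the reference drugs of class
#' *m*. Two interchangeable similarity backends are provided: semantic
#' similarity between ontology terms ([do_feature_vector()]) and Tanimoto
#' similarity between hashed substructure fingerprints
#' ([fingerprint_feature_vector()]). A class with no eligible reference
#' drug contributes \eqn{\alpha_m = 0} (no similarity evidence). Excluding
#' the query itself from the reference set — as the jackknife requires — is
#' always the caller's job, via `exclude_ids`.
#'
#' @name features
NULL

# max per class of a similarity row against the reference labels
max_per_class <- function(sim, reference, exclude_ids) {
  keep <- !(reference$drug_id %in% exclude_ids)
  alpha <- numeric(reference$n_classes)
  for (m in seq_len(reference$n_classes)) {
    elig <- keep & vapply(reference$labels, function(l) m %in% l, logical(1L))
    if (any(elig)) alpha[[m]] <- max(sim[elig])
  }
  alpha
}

#' Ontology-similarity feature vector of a drug
#'
#' \eqn{\alpha_m} is the maximum term similarity (see [do_similarity()])
#' between the query's ontology term and the terms of the class-*m*
#' reference drugs not listed in `exclude_ids`.
#'
#' @param query A `drug_record` with a resolvable `chebi_id`.
#' @param reference A `benchmark_dataset` in which every record has a
#'   resolvable `chebi_id` (the ontology-covered subset).
#' @param graph An `ontology_graph`.
#' @param exclude_ids Drug ids to ignore as similarity targets.
#' @param method Term-similarity method, see [do_similarity()].
#' @return Numeric vector of length `reference$n_classes`, each component
#'   in \[0, 1\].
#' @export
do_feature_vector <- function(query, reference, graph,
                              exclude_ids = character(),
                              method = "jaccard_ancestors") {
  stopifnot(inherits(reference, "benchmark_dataset"))
  check_similarity_method(method)
  if (!isTRUE(term_exists(graph, query$chebi_id))) {
    coverage_error(sprintf("drug '%s' is not covered by the ontology (chebi_id '%s')",
                           query$drug_id, query$chebi_id))
  }
  unresolved <- !term_exists(graph, reference$chebi_id)
  if (any(unresolved)) {
    coverage_error(sprintf("reference drug '%s' has no resolvable ontology term",
                           reference$drug_id[unresolved][[1L]]))
  }
  sim <- do_similarity_matrix(graph, query$chebi_id, reference$chebi_id,
                              method = method)[1L, ]
  max_per_class(sim, reference, exclude_ids)
}

#' Fingerprint parameters
#'
#' Settings of the hashed substructure fingerprint used by the fallback
#' similarity backend: OpenBabel's `FP2` path-based fingerprint (all linear
#' and ring substructures up to 7 atoms, hashed into a fixed-length bit
#' vector), 1024 bits. Fixed in one place so the implementation and any
#' cross-check share them.
#'
#' @param type OpenBabel fingerprint name.
#' @param n_bits Bit-vector length.
#' @export
fingerprint_params <- function(type = "FP2", n_bits = 1024L) {
  list(type = type, n_bits = as.integer(n_bits))
}

#' Hashed substructure fingerprints of SMILES strings
#'
#' Parses each SMILES and computes its bit fingerprint. Unparsable SMILES
#' raise an input error naming the offending string.
#'
#' @param smiles Character vector of SMILES strings (names, if present,
#'   become row names).
#' @param params See [fingerprint_params()].
#' @return 0/1 integer matrix, one row per molecule.
#' @export
fingerprints <- function(smiles, params = fingerprint_params()) {
  if (length(smiles) == 0L) {
    return(matrix(0L, 0L, params$n_bits))
  }
  if (any(is.na(smiles) | !nzchar(smiles))) {
    input_error("cannot fingerprint an empty SMILES string")
  }
  ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
    error = function(e) {
      input_error(sprintf("unparsable SMILES among: %s",
                          paste(unique(smiles), collapse = ", ")))
    }
  )
  ok <- ChemmineR::validSDF(sdf)
  if (!all(ok)) {
    input_error(sprintf("unparsable SMILES '%s'", smiles[!ok][[1L]]))
  }
  fp <- ChemmineR::fingerprintOB(sdf, params$type)
  m <- fp@fpma  # FPset bit matrix (as.matrix dispatch needs ChemmineR attached)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (ncol(m) != params$n_bits) {
    m <- m[, seq_len(min(ncol(m), params$n_bits)), drop = FALSE]
  }
  m
}

#' Tanimoto similarity between fingerprint bit vectors
#'
#' \eqn{|a \cap b| / |a \cup b|} on set bits; 0 when the union is empty.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# rows of A vs rows of B; bit matrices
tanimoto_matrix <- function(A, B = A) {
  inter <- A %*% t(B)
  ca <- rowSums(A)
  cb <- rowSums(B)
  un <- outer(ca, cb, "+") - inter
  out <- ifelse(un == 0, 0, inter / un)
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

#' Fingerprint-similarity feature vector of a drug
#'
#' The fallback encoding for drugs not covered by the ontology:
#' \eqn{\alpha_m} is the maximum Tanimoto coefficient between the query's
#' fingerprint and those of the class-*m* reference drugs not listed in
#' `exclude_ids`.
#'
#' @param query A `drug_record` whose `smiles` parses as a valid molecule.
#' @param reference A `benchmark_dataset`.
#' @param exclude_ids Drug ids to ignore as similarity targets.
#' @param params See [fingerprint_params()].
#' @param ref_fps Optional precomputed fingerprint matrix for `reference`
#'   (rows in record order), to avoid recomputation in loops.
#' @return Numeric vector of length `reference$n_classes`.
#' @export
fingerprint_feature_vector <- function(query, reference,
                                       exclude_ids = character(),
                                       params = fingerprint_params(),
                                       ref_fps = NULL) {
  stopifnot(inherits(reference, "benchmark_dataset"))
  if (is.null(ref_fps)) {
    ref_fps <- fingerprints(stats::setNames(reference$smiles, reference$drug_id),
                            params)
  }
  qfp <- fingerprints(stats::setNames(query$smiles, query$drug_id), params)
  sim <- tanimoto_matrix(qfp, ref_fps)[1L, ]
  max_per_class(sim, reference, exclude_ids)
}
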