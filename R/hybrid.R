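#' Hybrid dispatch between ontology and fingerprint sub-predictors
#'
#' The hybrid predictor routes each query on ontology coverage alone: a
#' query whose `chebi_id` resolves in the loaded ontology is formulated
#' with ontology-similarity features and scored by the DO sub-model; any
#' other query is formulated with fingerprint-Tanimoto features and scored
#' by the fallback sub-model. Routing never looks at the scores, and each
#' prediction reports which sub-predictor produced it.
#'
#' @name hybrid
NULL

#' @describeIn hybrid Bundle the two trained sub-predictors with their
#'   reference data and the ontology.
#' @param do_model `mlgkr_model` trained on ontology features of
#'   `do_reference`.
#' @param do_reference The ontology-covered `benchmark_dataset` the DO
#'   model was trained on.
#' @param fb_model `mlgkr_model` trained on fingerprint features of
#'   `fb_reference`.
#' @param fb_reference The `benchmark_dataset` the fallback model was
#'   trained on.
#' @param graph An `ontology_graph`.
#' @param method Term-similarity method for the DO path.
#' @param params Fingerprint parameters for the fallback path.
#' @export
hybrid_predictor <- function(do_model, do_reference, fb_model, fb_reference,
                             graph, method = "jaccard_ancestors",
                             params = fingerprint_params()) {
  stopifnot(inherits(do_model, "mlgkr_model"), inherits(fb_model, "mlgkr_model"),
            inherits(do_reference, "benchmark_dataset"),
            inherits(fb_reference, "benchmark_dataset"),
            inherits(graph, "ontology_graph"))
  structure(list(do_model = do_model, do_reference = do_reference,
                 fb_model = fb_model, fb_reference = fb_reference,
                 graph = graph, method = method, params = params),
            class = "hybrid_predictor")
}

#' @describeIn hybrid Convenience builder: splits `ds` by ontology
#'   coverage, trains the DO sub-model on the covered subset and the
#'   fallback sub-model on the full benchmark, at a common kernel width.
#' @param ds A `benchmark_dataset`.
#' @param theta Kernel width used for both sub-models.
#' @export
build_hybrid <- function(ds, graph, theta, method = "jaccard_ancestors",
                         params = fingerprint_params()) {
  parts <- split_by_coverage(ds, graph)
  if (length(parts$covered) == 0L) {
    model_error("no benchmark drug is covered by the ontology; cannot train the DO sub-model")
  }
  hybrid_predictor(
    do_model = build_do_model(parts$covered, graph, theta, method),
    do_reference = parts$covered,
    fb_model = build_fingerprint_model(ds, theta, params),
    fb_reference = ds,
    graph = graph, method = method, params = params
  )
}

#' Predict the ATC classes of one query drug with the hybrid rule
#'
#' @param query A `drug_record` carrying a SMILES and an optional
#'   `chebi_id`.
#' @param hybrid A `hybrid_predictor`.
#' @param exclude_ids Drug ids to exclude as similarity targets (used by
#'   leave-one-out evaluation; normally empty).
#' @return A `prediction`: list with `drug_id`, `labels` (non-empty,
#'   1-based), `sub_predictor` (`"DO"` or `"FALLBACK"`), `scores` (the
#'   per-class decision scores) and `forced` (`TRUE` when the non-empty
#'   fallback rule of [predict_labels()] fired).
#' @export
predict_hybrid <- function(query, hybrid, exclude_ids = character()) {
  stopifnot(inherits(hybrid, "hybrid_predictor"))
  covered <- isTRUE(term_exists(hybrid$graph, query$chebi_id))
  if (covered) {
    feat <- do_feature_vector(query, hybrid$do_reference, hybrid$graph,
                              exclude_ids = exclude_ids,
                              method = hybrid$method)
    scores <- decision_scores(hybrid$do_model, feat)
    route <- "DO"
  } else {
    feat <- tryCatch(
      fingerprint_feature_vector(query, hybrid$fb_reference,
                                 exclude_ids = exclude_ids,
                                 params = hybrid$params),
      mlatc_input_error = function(e) {
        input_error(sprintf(
          "drug '%s' has neither a resolvable ontology term nor a parsable SMILES ('%s')",
          query$drug_id, query$smiles))
      }
    )
    scores <- decision_scores(hybrid$fb_model, feat)
    route <- "FALLBACK"
  }
  labels <- predict_labels(scores)
  structure(list(drug_id = query$drug_id, labels = as.integer(labels),
                 sub_predictor = route, scores = scores,
                 forced = attr(labels, "forced")),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("<prediction> %s -> {%s} [%s]%s\n", x$drug_id,
              paste(x$labels, collapse = ","), x$sub_predictor,
              if (isTRUE(x$forced)) " (forced arg-max)" else ""))
  invisible(x)
}

#' Write predictions to TSV or JSON
#'
#' TSV columns: `drug_id`, comma-joined 1-based class list,
#' `sub_predictor`. JSON additionally carries the per-class decision
#' scores and the forced-arg-max flag.
#'
#' @param predictions List of `prediction` objects.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    rows <- vapply(predictions, function(p) {
      paste(p$drug_id, paste(p$labels, collapse = ","), p$sub_predictor,
            sep = "\t")
    }, character(1L))
    writeLines(c("drug_id\tclasses\tsub_predictor", rows), path, sep = "\n")
  } else {
    doc <- lapply(predictions, function(p) {
      list(drug_id = p$drug_id, classes = p$labels,
           sub_predictor = p$sub_predictor, scores = p$scores,
           forced = isTRUE(p$forced))
    })
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
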