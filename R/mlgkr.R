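#' Multi-label Gaussian kernel regression (ML-GKR)
#'
#' The classifier keeps every training drug as a pair: its feature vector
#' \eqn{D^i} (per-class maximum similarities) and its label vector
#' \eqn{L^i} with components \eqn{\ell^i_m = +1} when drug *i* occurs in
#' class *m* and \eqn{-1} otherwise. For a query \eqn{D^q}, the per-class
#' decision score is the normalized Gaussian-kernel-weighted average of the
#' training labels,
#' \deqn{\Delta_m = \frac{\sum_i \ell^i_m \exp(-\|D^q - D^i\|^2 / 2\theta^2)}
#'                      {\sum_i \exp(-\|D^q - D^i\|^2 / 2\theta^2)},}
#' and class *m* is predicted whenever \eqn{\Delta_m \ge 0}. The kernel
#' width \eqn{\theta > 0} controls how sharply nearby training drugs
#' dominate: as \eqn{\theta \to 0^+} the classifier approaches the nearest
#' neighbour's label set, as \eqn{\theta \to \infty} it approaches the
#' unweighted label mean.
#'
#' @name mlgkr
NULL

#' @describeIn mlgkr Construct a model from a feature matrix (one row per
#'   training drug), a label matrix in `{-1,+1}` (or `{0,1}`, which is
#'   converted) of the same shape, and a kernel width `theta`.
#' @param features Numeric matrix, n drugs by M classes, entries in \[0, 1\].
#' @param labels Numeric matrix, n by M, entries all `-1`/`+1` (or `0`/`1`).
#' @param theta Positive kernel width.
#' @export
mlgkr_model <- function(features, labels, theta) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) == 0L) model_error("ML-GKR model needs at least one training drug")
  if (!all(dim(features) == dim(labels))) {
    model_error("feature and label matrices must have identical shape")
  }
  if (all(labels %in% c(0, 1))) labels <- 2 * labels - 1
  if (!all(labels %in% c(-1, 1))) {
    model_error("labels must be -1/+1 (or 0/1)")
  }
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0) {
    model_error("theta must be a positive number")
  }
  structure(list(features = unname(features), labels = unname(labels),
                 theta = as.numeric(theta), n_classes = ncol(features)),
            class = "mlgkr_model")
}

#' @export
print.mlgkr_model <- function(x, ...) {
  cat(sprintf("<mlgkr_model> %d training drugs, %d classes, theta = %g\n",
              nrow(x$features), x$n_classes, x$theta))
  invisible(x)
}

#' Squared Euclidean distance between two feature vectors
#'
#' \eqn{\|a - b\|^2 = \sum_u (\alpha^a_u - \alpha^b_u)^2}.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
squared_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum((a - b)^2)
}

#' Per-class decision scores for a query feature vector
#'
#' Evaluates the normalized kernel-weighted label average for every class.
#' The minimum squared distance is subtracted inside every exponent before
#' weighting — an exact, ratio-preserving shift that keeps the weight sum
#' away from zero even for very small `theta`.
#'
#' @param model An `mlgkr_model`.
#' @param query Numeric feature vector of length `model$n_classes`.
#' @return Numeric vector of decision scores, each in \[-1, 1\].
#' @export
decision_scores <- function(model, query) {
  stopifnot(inherits(model, "mlgkr_model"))
  if (length(query) != model$n_classes) {
    model_error(sprintf("query has %d components, model expects %d",
                        length(query), model$n_classes))
  }
  d2 <- rowSums(sweep(model$features, 2L, query)^2)
  decision_scores_from_d2(d2, model$labels, model$theta)
}

# core shared with the jackknife engine: d2 = squared distances to the
# training drugs, L = n x M matrix of +-1 labels
decision_scores_from_d2 <- function(d2, L, theta) {
  w <- exp(-(d2 - min(d2)) / (2 * theta^2))
  s <- drop(crossprod(w, L)) / sum(w)
  pmin(pmax(s, -1), 1)  # guard the one-ulp overshoot of the convex combination
}

#' Threshold decision scores into a predicted label set
#'
#' Class *m* is predicted whenever \eqn{\Delta_m \ge 0} (a score of exactly
#' zero predicts the class). If every score is negative the single class
#' with the largest score is returned instead — ties broken toward the
#' lowest class index — so the predicted set is never empty; when this
#' fallback fires, the result carries attribute `forced = TRUE`.
#'
#' @param scores Numeric vector of decision scores.
#' @return Sorted integer vector of predicted classes (1-based), with
#'   attribute `forced`.
#' @export
predict_labels <- function(scores) {
  pred <- which(scores >= 0)
  forced <- length(pred) == 0L
  if (forced) pred <- which.max(scores)
  structure(as.integer(pred), forced = forced)
}

#' Serialize an ML-GKR model to JSON
#'
#' The document carries a `schema` tag (`"mlatc/mlgkr/1"`), the training
#' feature matrix, the label matrix as -1/+1, and `theta`.
#'
#' @param model An `mlgkr_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mlgkr_model <- function(model, path) {
  stopifnot(inherits(model, "mlgkr_model"))
  doc <- list(schema = "mlatc/mlgkr/1",
              theta = model$theta,
              features = model$features,
              labels = model$labels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn write_mlgkr_model Read a model back from JSON.
#' @export
read_mlgkr_model <- function(path) {
  if (!file.exists(path)) io_error(sprintf("cannot read model file '%s'", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "mlatc/mlgkr/1")) {
    format_error(sprintf("unrecognized model schema '%s'", doc$schema))
  }
  mlgkr_model(doc$features, doc$labels, doc$theta)
}

#' Fit an ML-GKR model on a benchmark with ontology features
#'
#' Training features are the per-class maximum-similarity vectors of every
#' reference drug against the reference set, with each drug's own record
#' excluded as a similarity target (leave-self-out formulation). Including
#' the drug itself would pin \eqn{\alpha_m = 1} at its own classes, turning
#' training vectors into near-indicators of their labels — a representation
#' a query compound outside the reference set can never attain, which
#' degrades the kernel regression. Leave-self-out makes training and query
#' vectors draws from the same mechanism. Labels come from the benchmark's
#' class memberships.
#'
#' @param reference A fully ontology-covered `benchmark_dataset`.
#' @param graph An `ontology_graph`.
#' @param theta Kernel width.
#' @param method Term-similarity method.
#' @return An `mlgkr_model`.
#' @export
build_do_model <- function(reference, graph, theta,
                           method = "jaccard_ancestors") {
  sim <- do_sim_matrix_checked(reference, graph, method)
  features <- loo_features(sim, label_matrix(reference))
  mlgkr_model(features, label_matrix(reference), theta)
}

#' @describeIn build_do_model Same, with fingerprint-Tanimoto similarity
#'   (every record needs a parsable SMILES).
#' @param params See [fingerprint_params()].
#' @export
build_fingerprint_model <- function(reference, theta,
                                    params = fingerprint_params()) {
  fps <- fingerprints(stats::setNames(reference$smiles, reference$drug_id),
                      params)
  sim <- tanimoto_matrix(fps)
  features <- loo_features(sim, label_matrix(reference))
  mlgkr_model(features, label_matrix(reference), theta)
}

# similarity matrix of a covered benchmark against itself
do_sim_matrix_checked <- function(reference, graph, method = "jaccard_ancestors") {
  unresolved <- !term_exists(graph, reference$chebi_id)
  if (any(unresolved)) {
    coverage_error(sprintf("reference drug '%s' has no resolvable ontology term",
                           reference$drug_id[unresolved][[1L]]))
  }
  sim <- do_similarity_matrix(graph, reference$chebi_id, method = method)
  dimnames(sim) <- list(reference$drug_id, reference$drug_id)
  sim
}

# leave-self-out feature matrix from a full similarity matrix: row i,
# class m = max similarity of drug i to the class-m drugs other than i
loo_features <- function(sim, labels01) {
  f <- features_with_exclusions(top3_per_class(sim, labels01))
  dimnames(f) <- list(rownames(sim), NULL)
  f
}
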