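#' Jackknife (leave-one-out) evaluation and kernel-width tuning
#'
#' For every drug k in the benchmark, the jackknife builds a classifier
#' from all remaining drugs and predicts k. The held-out drug is removed
#' both as a training instance and as a similarity target: every feature
#' vector used in fold k — the query's and the training drugs' — is
#' computed with drug k excluded from the reference set, so no component
#' of any vector carries information about the held-out drug's labels.
#' All (actual, predicted) pairs are then scored with [five_metrics()].
#'
#' Because excluding a single drug changes a per-class maximum only when
#' that drug attains it, the engine precomputes the two largest
#' similarities per (drug, class) once and patches fold features in O(1)
#' per entry; distances are likewise computed once per fold and reused
#' across kernel widths, which makes grid tuning cheap.
#'
#' @name evaluate
NULL

# top-3 similarity per (drug, class): values v1 >= v2 >= v3 with the drug
# indices attaining v1 and v2 (0 / NA when the class has too few members).
# Three suffice because a per-class maximum is only ever recomputed with at
# most two drugs excluded: the drug being formulated and the held-out drug.
top3_per_class <- function(sim, labels01) {
  n <- nrow(sim)
  M <- ncol(labels01)
  v1 <- v2 <- v3 <- matrix(0, n, M)
  i1 <- i2 <- matrix(NA_integer_, n, M)
  for (m in seq_len(M)) {
    idx <- which(labels01[, m] == 1L)
    if (length(idx) == 0L) next
    sub <- sim[, idx, drop = FALSE]
    j1 <- max.col(sub, ties.method = "first")
    pick <- cbind(seq_len(n), j1)
    v1[, m] <- sub[pick]
    i1[, m] <- idx[j1]
    if (length(idx) > 1L) {
      sub[pick] <- -Inf
      j2 <- max.col(sub, ties.method = "first")
      pick2 <- cbind(seq_len(n), j2)
      v2[, m] <- sub[pick2]
      i2[, m] <- idx[j2]
      if (length(idx) > 2L) {
        sub[pick2] <- -Inf
        v3[, m] <- apply(sub, 1L, max)
      }
    }
  }
  list(v1 = v1, i1 = i1, v2 = v2, i2 = i2, v3 = v3)
}

# Leave-self-out feature matrix: row i is drug i's per-class maximum
# similarity with drug i itself — and, when `k` is given, the held-out
# drug k — removed as similarity targets. Exact: excluding up to two drugs
# moves a maximum at most to the third-best value.
features_with_exclusions <- function(top3, k = NA_integer_) {
  n <- nrow(top3$v1)
  M <- ncol(top3$v1)
  rowidx <- matrix(seq_len(n), n, M)
  hit_k <- function(i) !is.na(k) & !is.na(i) & i == k
  excl1 <- !is.na(top3$i1) & (top3$i1 == rowidx | hit_k(top3$i1))
  excl2 <- !is.na(top3$i2) & (top3$i2 == rowidx | hit_k(top3$i2))
  f <- top3$v1
  f[excl1 & !excl2] <- top3$v2[excl1 & !excl2]
  f[excl1 & excl2] <- top3$v3[excl1 & excl2]
  f
}

# predictions for held-out rows `which_k` at every theta in `thetas`
fold_predictions <- function(sim, labels01, thetas, which_k = seq_len(nrow(sim))) {
  top3 <- top3_per_class(sim, labels01)
  pm1 <- 2 * labels01 - 1
  out <- lapply(thetas, function(t) {
    list(predicted = vector("list", length(which_k)),
         forced = logical(length(which_k)))
  })
  for (j in seq_along(which_k)) {
    k <- which_k[[j]]
    f <- features_with_exclusions(top3, k)
    q <- f[k, ]
    d2 <- rowSums(sweep(f[-k, , drop = FALSE], 2L, q)^2)
    L <- pm1[-k, , drop = FALSE]
    for (t in seq_along(thetas)) {
      scores <- decision_scores_from_d2(d2, L, thetas[[t]])
      pred <- predict_labels(scores)
      out[[t]]$predicted[[j]] <- as.integer(pred)
      out[[t]]$forced[[j]] <- attr(pred, "forced")
    }
  }
  out
}

# jackknife predictions at several kernel widths; returns, per theta, a
# list(predicted, forced) aligned with ds record order
jackknife_multi <- function(ds, thetas, method, graph = NULL,
                            similarity = "jaccard_ancestors",
                            params = fingerprint_params()) {
  n <- length(ds)
  if (n < 2L) evaluation_error("jackknife needs at least 2 drugs")
  # canonical internal order (by drug id) so results are bitwise invariant
  # under record permutations, even where a score sits on a tie
  ord <- order(ds$drug_id)
  if (is.unsorted(ord)) {
    res <- jackknife_multi(ds[ord], thetas, method, graph, similarity, params)
    return(lapply(res, function(r) {
      out <- r
      out$predicted[ord] <- r$predicted
      out$forced[ord] <- r$forced
      out
    }))
  }
  labels01 <- label_matrix(ds)
  if (method == "do") {
    if (is.null(graph)) config_error("the DO predictor needs an ontology graph")
    sim <- do_sim_matrix_checked(ds, graph, similarity)
    return(fold_predictions(sim, labels01, thetas))
  }
  if (method == "fingerprint") {
    fps <- fingerprints(stats::setNames(ds$smiles, ds$drug_id), params)
    return(fold_predictions(tanimoto_matrix(fps), labels01, thetas))
  }
  # hybrid: covered drugs take the DO route within the covered subset;
  # uncovered drugs take the fingerprint route against the full benchmark
  # (minus the held-out drug), mirroring the hard dispatch rule
  if (is.null(graph)) config_error("the hybrid predictor needs an ontology graph")
  cov <- which(term_exists(graph, ds$chebi_id))
  unc <- setdiff(seq_len(n), cov)
  out <- lapply(thetas, function(t) {
    list(predicted = vector("list", n), forced = logical(n))
  })
  if (length(cov) == 1L) {
    evaluation_error("hybrid jackknife needs either 0 or >= 2 ontology-covered drugs")
  }
  if (length(cov) > 0L) {
    sub <- ds[cov]
    sim <- do_sim_matrix_checked(sub, graph, similarity)
    part <- fold_predictions(sim, label_matrix(sub), thetas)
    for (t in seq_along(thetas)) {
      out[[t]]$predicted[cov] <- part[[t]]$predicted
      out[[t]]$forced[cov] <- part[[t]]$forced
    }
  }
  if (length(unc) > 0L) {
    fps <- fingerprints(stats::setNames(ds$smiles, ds$drug_id), params)
    part <- fold_predictions(tanimoto_matrix(fps), labels01, thetas,
                             which_k = unc)
    for (t in seq_along(thetas)) {
      out[[t]]$predicted[unc] <- part[[t]]$predicted
      out[[t]]$forced[unc] <- part[[t]]$forced
    }
  }
  out
}

#' Jackknife evaluation of a predictor on a benchmark
#'
#' @param ds A `benchmark_dataset` (at least 2 drugs). For `method = "do"`
#'   every record must be ontology-covered; for `"hybrid"` each record is
#'   routed by its own coverage.
#' @param theta Positive kernel width.
#' @param method `"do"`, `"fingerprint"` or `"hybrid"`.
#' @param graph An `ontology_graph` (required for `"do"` and `"hybrid"`).
#' @param similarity Term-similarity method for the DO path.
#' @param params Fingerprint parameters for the fingerprint path.
#' @param return_predictions If `TRUE`, also return per-drug predictions.
#' @return A `metrics_report`; or, with `return_predictions = TRUE`, a list
#'   with `metrics`, `predicted` (list of label sets named by drug id) and
#'   `forced` (logical: arg-max fallback fired).
#' @export
jackknife <- function(ds, theta, method = c("do", "fingerprint", "hybrid"),
                      graph = NULL, similarity = "jaccard_ancestors",
                      params = fingerprint_params(),
                      return_predictions = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    config_error("theta must be a positive number")
  }
  res <- jackknife_multi(ds, theta, method, graph, similarity, params)[[1L]]
  metrics <- five_metrics(ds$labels, res$predicted, n_labels = ds$n_classes)
  if (!return_predictions) return(metrics)
  list(metrics = metrics,
       predicted = stats::setNames(res$predicted, ds$drug_id),
       forced = stats::setNames(res$forced, ds$drug_id))
}

#' Default kernel-width grid
#'
#' \eqn{\{1/n : n = 1..50\} \cup \{1/n^2 : n = 1..10\}}, sorted and
#' deduplicated. The grid spans the near-nearest-neighbour and
#' near-label-mean regimes and contains the operating point 1/36.
#'
#' @return Numeric vector of positive kernel widths.
#' @export
default_theta_grid <- function() {
  sort(unique(c(1 / (1:50), 1 / (1:10)^2)))
}

#' Tune the kernel width by maximizing the jackknife absolute-true rate
#'
#' Runs the jackknife at every grid value and picks the width with the
#' highest absolute-true rate, ties broken toward the smaller width.
#' Distances are shared across grid points, so the sweep costs little more
#' than a single jackknife.
#'
#' @inheritParams jackknife
#' @param grid Non-empty vector of positive kernel widths.
#' @return A `theta_curve`: list with `grid`, `absolute_true_at` (rate per
#'   grid point), `best_theta` and `best_rate`.
#' @export
optimize_theta <- function(ds, grid = default_theta_grid(),
                           method = c("do", "fingerprint", "hybrid"),
                           graph = NULL, similarity = "jaccard_ancestors",
                           params = fingerprint_params()) {
  method <- match.arg(method)
  if (length(grid) == 0L || !is.numeric(grid) || any(!is.finite(grid)) ||
      any(grid <= 0)) {
    config_error("theta grid must be non-empty and strictly positive")
  }
  grid <- as.numeric(grid)
  res <- jackknife_multi(ds, grid, method, graph, similarity, params)
  rates <- vapply(res, function(r) {
    five_metrics(ds$labels, r$predicted, n_labels = ds$n_classes)$absolute_true
  }, numeric(1L))
  best_idx <- which(rates == max(rates))
  best_theta <- min(grid[best_idx])
  structure(list(grid = grid, absolute_true_at = rates,
                 best_theta = best_theta, best_rate = max(rates),
                 method = method),
            class = "theta_curve")
}

#' @export
print.theta_curve <- function(x, ...) {
  cat(sprintf("<theta_curve> %d grid points, best theta = %g (absolute true %.2f%%)\n",
              length(x$grid), x$best_theta, 100 * x$best_rate))
  invisible(x)
}

#' Write a kernel-width tuning curve as TSV
#'
#' Two columns, `theta` and `absolute_true`, one row per grid point.
#'
#' @param curve A `theta_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_theta_curve <- function(curve, path) {
  stopifnot(inherits(curve, "theta_curve"))
  lines <- c("theta\tabsolute_true",
             sprintf("%.17g\t%.17g", curve$grid, curve$absolute_true_at))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
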