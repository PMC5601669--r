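#' Chou's five multi-label metrics
#'
#' For N samples with actual label sets \eqn{L_k} and predicted sets
#' \eqn{L^*_k} over a universe of M labels:
#' \itemize{
#'   \item aiming: mean of \eqn{|L_k \cap L^*_k| / |L^*_k|} (precision-like);
#'   \item coverage: mean of \eqn{|L_k \cap L^*_k| / |L_k|} (recall-like);
#'   \item accuracy: mean of \eqn{|L_k \cap L^*_k| / |L_k \cup L^*_k|}
#'     (Jaccard-like);
#'   \item absolute true: fraction of samples with \eqn{L_k = L^*_k} exactly;
#'   \item absolute false: mean of
#'     \eqn{(|L_k \cup L^*_k| - |L_k \cap L^*_k|) / M} (normalized
#'     symmetric difference).
#' }
#' Empty actual or predicted sets make the formulas undefined (division by
#' a set size of zero) and are rejected rather than scored.
#'
#' @param actual List of integer vectors: the observed label sets.
#' @param predicted List of integer vectors, same length: the predicted sets.
#' @param n_labels Size M of the label universe (default 14).
#' @return A `metrics_report`: list with `aiming`, `coverage`, `accuracy`,
#'   `absolute_true`, `absolute_false`, `n_samples`, `n_labels`.
#' @export
five_metrics <- function(actual, predicted, n_labels = 14L) {
  if (length(actual) != length(predicted)) {
    evaluation_error("actual and predicted lists must have the same length")
  }
  n <- length(actual)
  if (n == 0L) evaluation_error("cannot score an empty list of pairs")
  n_labels <- as.integer(n_labels)
  aim <- cov <- acc <- atrue <- afalse <- numeric(n)
  for (k in seq_len(n)) {
    L <- unique(as.integer(actual[[k]]))
    P <- unique(as.integer(predicted[[k]]))
    if (length(L) == 0L) evaluation_error(sprintf("actual label set %d is empty", k))
    if (length(P) == 0L) evaluation_error(sprintf("predicted label set %d is empty", k))
    if (any(c(L, P) < 1L) || any(c(L, P) > n_labels)) {
      evaluation_error(sprintf("label outside 1..%d in pair %d", n_labels, k))
    }
    i <- length(intersect(L, P))
    u <- length(union(L, P))
    aim[[k]] <- i / length(P)
    cov[[k]] <- i / length(L)
    acc[[k]] <- i / u
    atrue[[k]] <- as.numeric(u == i && length(L) == length(P))
    afalse[[k]] <- (u - i) / n_labels
  }
  structure(
    list(aiming = mean(aim), coverage = mean(cov), accuracy = mean(acc),
         absolute_true = mean(atrue), absolute_false = mean(afalse),
         n_samples = n, n_labels = n_labels),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics(x), sep = "\n")
  invisible(x)
}

#' Format a metrics report as a five-column table
#'
#' Values are printed as percentages to two decimals.
#'
#' @param x A `metrics_report`.
#' @return Character vector of table lines.
#' @export
format_metrics <- function(x) {
  stopifnot(inherits(x, "metrics_report"))
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  header <- sprintf("%-10s %-10s %-10s %-14s %-14s",
                    "Aiming", "Coverage", "Accuracy", "Absolute true",
                    "Absolute false")
  row <- sprintf("%-10s %-10s %-10s %-14s %-14s",
                 pct(x$aiming), pct(x$coverage), pct(x$accuracy),
                 pct(x$absolute_true), pct(x$absolute_false))
  c(header, row, sprintf("(N = %d samples, M = %d labels)", x$n_samples, x$n_labels))
}
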