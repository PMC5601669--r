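# Shared fixtures and independent oracles. Oracles are deliberately written
# in a different style from the implementation (set arithmetic vs matrix
# algebra, fixpoint iteration vs topological order) so the two routes stay
# independent.

obo_file <- function(..., header = "format-version: 1.2") {
  stanzas <- c(...)
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c(header, "", stanzas), path)
  path
}

term_stanza <- function(id, is_a = character(), obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("is_a: ", is_a),
    if (obsolete) "is_obsolete: true", "")
}

# chain A <- B <- C (C is_a B is_a A)
chain_graph <- function() {
  parse_obo(obo_file(term_stanza("A"), term_stanza("B", "A"),
                     term_stanza("C", "B")))
}

# random DAG over n terms: edges always point from higher to lower index,
# so acyclicity holds by construction
random_dag_edges <- function(n, p = 0.3) {
  terms <- sprintf("T%02d", seq_len(n))
  edges <- list()
  for (i in seq_len(n)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1L) < p) {
        edges[[length(edges) + 1L]] <- c(terms[[i]], terms[[j]])
      }
    }
  }
  list(terms = terms, edges = edges)
}

dag_to_obo <- function(dag, envir = parent.frame()) {
  stanzas <- lapply(dag$terms, function(t) {
    parents <- vapply(Filter(function(e) e[[1L]] == t, dag$edges),
                      function(e) e[[2L]], character(1L))
    term_stanza(t, parents)
  })
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = envir)
  writeLines(c("format-version: 1.2", "", unlist(stanzas)), path)
  path
}

# brute-force reflexive transitive closure by fixpoint iteration
brute_ancestors <- function(dag, term) {
  closed <- term
  repeat {
    new <- closed
    for (e in dag$edges) if (e[[1L]] %in% closed) new <- union(new, e[[2L]])
    if (setequal(new, closed)) return(sort(closed))
    closed <- new
  }
}

# brute-force five metrics on 0/1 indicator vectors
brute_five_metrics <- function(actual, predicted, M) {
  n <- length(actual)
  acc <- matrix(0, n, 5L)
  for (k in seq_len(n)) {
    a <- p <- rep(0L, M)
    a[actual[[k]]] <- 1L
    p[predicted[[k]]] <- 1L
    inter <- sum(a * p)
    uni <- sum(pmax(a, p))
    acc[k, ] <- c(inter / sum(p), inter / sum(a), inter / uni,
                  as.numeric(all(a == p)), (uni - inter) / M)
  }
  means <- colMeans(acc)
  list(aiming = means[[1L]], coverage = means[[2L]], accuracy = means[[3L]],
       absolute_true = means[[4L]], absolute_false = means[[5L]])
}

random_label_pairs <- function(n, M) {
  actual <- predicted <- vector("list", n)
  for (k in seq_len(n)) {
    actual[[k]] <- sample.int(M, sample.int(min(M, 4L), 1L))
    predicted[[k]] <- sample.int(M, sample.int(min(M, 4L), 1L))
  }
  list(actual = actual, predicted = predicted)
}

# naive two-pass decision scores: no stability shift, long-double sums
naive_decision_scores <- function(features, labels_pm1, theta, query) {
  n <- nrow(features)
  num <- rep(0, ncol(features))
  den <- 0
  for (i in seq_len(n)) {
    w <- exp(-sum((query - features[i, ])^2) / (2 * theta^2))
    num <- num + labels_pm1[i, ] * w
    den <- den + w
  }
  num / den
}

random_mlgkr <- function(n = 20L, M = 14L, theta = 1) {
  f <- matrix(stats::runif(n * M), n, M)
  l01 <- matrix(0L, n, M)
  for (i in seq_len(n)) l01[i, sample.int(M, sample.int(3L, 1L))] <- 1L
  mlgkr_model(f, l01, theta)
}

# tiny fully-covered benchmark + ontology: class subtrees P1..Pm under a
# root, each drug's term a child of its class parents
toy_covered <- function(n_classes = 3L, per_class = 3L) {
  root <- term_stanza("R")
  classes <- lapply(seq_len(n_classes), function(m) {
    term_stanza(sprintf("P%d", m), "R")
  })
  n <- n_classes * per_class
  labels <- lapply(seq_len(n), function(i) (i - 1L) %% n_classes + 1L)
  drugs <- lapply(seq_len(n), function(i) {
    term_stanza(sprintf("T%03d", i), sprintf("P%d", labels[[i]]))
  })
  path <- obo_file(root, unlist(classes), unlist(drugs),
                   header = "format-version: 1.2")
  graph <- parse_obo(path)
  ds <- benchmark_dataset(sprintf("d%03d", seq_len(n)),
                          rep("CCO", n),
                          sprintf("T%03d", seq_len(n)),
                          labels, n_classes = n_classes)
  list(graph = graph, ds = ds)
}
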