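#' Ontology graphs: OBO parsing, ancestor closures, term similarity
#'
#' An `ontology_graph` is a directed acyclic graph of ontology terms linked
#' by is-a edges (child to parent), as found in chemical ontologies such as
#' ChEBI. Ancestor closures are reflexive: every term is an ancestor of
#' itself. Obsolete terms are dropped at parse time, together with any edge
#' touching them, so an identifier pointing at an obsolete term does not
#' resolve.
#'
#' @name ontology
NULL

new_ontology_graph <- function(terms, parents) {
  terms <- sort(unique(terms))
  parents <- parents[intersect(names(parents), terms)]
  parents <- lapply(parents, function(p) sort(unique(p)))
  missing <- setdiff(terms, names(parents))
  parents[missing] <- list(character())
  parents <- parents[terms]
  g <- list(terms = terms, parents = parents, cache = new.env(parent = emptyenv()))
  class(g) <- "ontology_graph"
  assert_acyclic(g)
  g
}

# Cycle check via igraph; names one offending term in the error.
assert_acyclic <- function(graph) {
  edges <- ontology_edges(graph)
  if (nrow(edges) == 0L) return(invisible(graph))
  ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = graph$terms)
  if (!igraph::is_dag(ig)) {
    loops <- edges$child[edges$child == edges$parent]
    if (length(loops) > 0L) {
      format_error(sprintf("ontology is-a relation is cyclic (term '%s' on a cycle)", loops[[1L]]))
    }
    comp <- igraph::components(ig, mode = "strong")
    bad <- names(comp$membership)[comp$membership == which(comp$csize > 1L)[1L]]
    format_error(sprintf("ontology is-a relation is cyclic (term '%s' on a cycle)", sort(bad)[[1L]]))
  }
  invisible(graph)
}

#' @describeIn ontology Edge list of a graph as a data frame with columns
#'   `child` and `parent`.
#' @export
ontology_edges <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  n <- lengths(graph$parents)
  data.frame(
    child = rep(names(graph$parents), n),
    parent = unlist(graph$parents, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Parse an OBO flat file into an ontology graph
#'
#' Reads the `[Term]` stanzas of an OBO file, keeping the `id:`, `is_a:` and
#' `is_obsolete:` keys; all other keys and stanza types (e.g. `[Typedef]`)
#' are ignored, as are non-is-a relationships. `is_a` values are truncated at
#' the first `!` comment. Obsolete terms are excluded from the graph along
#' with every edge touching them. A parent referenced by an `is_a` line but
#' lacking its own stanza is added as a bare term. Cyclic input is rejected.
#'
#' @param path Path to an OBO flat file.
#' @return An `ontology_graph`.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) io_error(sprintf("cannot read OBO file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  terms <- character()
  obsolete <- character()
  parents <- list()

  bounds <- c(stanza_starts, length(lines) + 1L)
  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[seq(s + 1L, length.out = max(0L, end - s))]
    id <- sub("^id:\\s*", "", grep("^id:", body, value = TRUE))
    if (length(id) == 0L) format_error("OBO [Term] stanza without an id: line")
    id <- trimws(id[[1L]])
    obs <- grepl("^is_obsolete:\\s*true", body)
    isa <- grep("^is_a:", body, value = TRUE)
    isa <- trimws(sub("!.*$", "", sub("^is_a:\\s*", "", isa)))
    isa <- isa[nzchar(isa)]
    if (any(obs)) {
      obsolete <- c(obsolete, id)
    } else {
      terms <- c(terms, id)
      parents[[id]] <- unique(c(parents[[id]], isa))
    }
  }

  terms <- setdiff(unique(terms), obsolete)
  # add dangling parents as bare terms; drop edges into obsolete terms
  parents <- lapply(parents[intersect(names(parents), terms)],
                    function(p) setdiff(p, obsolete))
  terms <- unique(c(terms, unlist(parents, use.names = FALSE)))
  new_ontology_graph(terms, parents)
}

#' Write an ontology graph as an OBO flat file
#'
#' Emits one `[Term]` stanza per term with its `is_a` lines, in sorted term
#' order, so identical graphs serialize byte-identically.
#'
#' @param graph An `ontology_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  out <- c("format-version: 1.2", "")
  for (t in graph$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("is_a: ", graph$parents[[t]]), "")
  }
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' @describeIn ontology Does `term` resolve to a (non-obsolete) term of the
#'   graph? Vectorised over `term`; `NA` identifiers do not resolve.
#' @export
term_exists <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"))
  !is.na(term) & term %in% graph$terms
}

#' Reflexive transitive ancestor closure of a term
#'
#' All terms reachable from `term` by following is-a edges, including `term`
#' itself. Closures for the whole graph are computed once (in topological
#' order) and cached on the graph object.
#'
#' @param graph An `ontology_graph`.
#' @param term A term identifier present in the graph.
#' @return Sorted character vector of term identifiers.
#' @export
ancestors <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (length(term) != 1L || !isTRUE(term %in% graph$terms)) {
    lookup_error(sprintf("unknown ontology term '%s'", paste(term, collapse = ",")))
  }
  ancestor_index(graph)[[term]]
}

# Named list term -> sorted reflexive ancestor set, memoised per graph.
ancestor_index <- function(graph) {
  cached <- graph$cache$ancestors
  if (!is.null(cached)) return(cached)
  edges <- ontology_edges(graph)
  order <- graph$terms
  if (nrow(edges) > 0L) {
    ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                        vertices = graph$terms)
    # topological order with parents first, so closures compose by union
    order <- names(igraph::topo_sort(ig, mode = "in"))
  }
  anc <- vector("list", length(order))
  names(anc) <- order
  for (t in order) {
    anc[[t]] <- sort(unique(c(t, unlist(anc[graph$parents[[t]]], use.names = FALSE))))
  }
  anc <- anc[graph$terms]
  graph$cache$ancestors <- anc
  anc
}

#' Similarity between two ontology terms
#'
#' Semantic similarity derived from ontology placement. The
#' `"jaccard_ancestors"` method scores a pair of terms by the Jaccard
#' overlap of their reflexive is-a ancestor closures,
#' \eqn{|A(a) \cap A(b)| / |A(a) \cup A(b)|}: 1 for identical terms, 0 for
#' terms whose closures are disjoint, symmetric, and always in \[0, 1\].
#'
#' @param graph An `ontology_graph`.
#' @param term_a,term_b Term identifiers present in the graph.
#' @param method Similarity method; only `"jaccard_ancestors"` is available.
#' @return A similarity score in \[0, 1\].
#' @export
do_similarity <- function(graph, term_a, term_b, method = "jaccard_ancestors") {
  check_similarity_method(method)
  a <- ancestors(graph, term_a)
  b <- ancestors(graph, term_b)
  length(intersect(a, b)) / length(union(a, b))
}

check_similarity_method <- function(method) {
  if (!identical(method, "jaccard_ancestors")) {
    config_error(sprintf("unknown similarity method '%s' (available: jaccard_ancestors)",
                         paste(method, collapse = ",")))
  }
  invisible(method)
}

#' Pairwise term-similarity matrix
#'
#' @param graph An `ontology_graph`.
#' @param terms_a,terms_b Character vectors of term identifiers;
#'   `terms_b` defaults to `terms_a`.
#' @inheritParams do_similarity
#' @return Numeric matrix of dimension `length(terms_a)` by `length(terms_b)`.
#' @export
do_similarity_matrix <- function(graph, terms_a, terms_b = terms_a,
                                 method = "jaccard_ancestors") {
  check_similarity_method(method)
  idx <- ancestor_index(graph)
  bad <- setdiff(unique(c(terms_a, terms_b)), graph$terms)
  if (length(bad) > 0L) {
    lookup_error(sprintf("unknown ontology term '%s'", bad[[1L]]))
  }
  A <- idx[terms_a]
  B <- idx[terms_b]
  na <- lengths(A)
  nb <- lengths(B)
  out <- matrix(0, length(A), length(B),
                dimnames = list(names(A), names(B)))
  for (i in seq_along(A)) {
    ai <- A[[i]]
    inter <- vapply(B, function(b) length(intersect(ai, b)), integer(1L))
    out[i, ] <- inter / (na[[i]] + nb - inter)
  }
  out
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms, %d is-a edges\n",
              length(x$terms), sum(lengths(x$parents))))
  invisible(x)
}
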