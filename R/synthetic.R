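#' Seeded synthetic ontologies and multi-label benchmarks
#'
#' The generator emulates the statistical structure the ontology features
#' exploit: drugs of one class share ontology ancestry. It builds a single
#' root, one is-a chain ("class subtree") of `subtree_depth` terms per
#' class, and one term per drug attached at the deepest term of its class's
#' chain — drugs are leaf-level specific compounds, while the chain terms
#' above them stand for successively broader chemical families. A drug
#' occurring in several classes gets a parent at the bottom of each of its
#' class chains. `cross_link_noise` is the probability that a chain term
#' acquires an extra is-a parent inside another class's chain, which blurs
#' the between-class separation (extra parents always point toward
#' lower-numbered classes, so the graph stays acyclic). Multi-label drugs
#' pair each class with a fixed partner class (the next index, wrapping),
#' mimicking the strong label co-occurrence of real ATC data, and their
#' count per class is `round(multi_label_fraction * drugs_per_class)` —
#' deterministic, so the multiplicity distribution is known exactly.
#' SMILES are drawn from a fixed embedded alphabet of real small molecules
#' so the fingerprint backend is exercised deterministically.
#'
#' @name synthetic
NULL

# real small-molecule SMILES used for synthetic drugs
synthetic_smiles_alphabet <- function() {
  c("CCO",                                    # ethanol
    "CCCO",                                   # 1-propanol
    "CC(=O)OC1=CC=CC=C1C(=O)O",               # aspirin
    "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",           # caffeine
    "CC(=O)NC1=CC=C(O)C=C1",                  # paracetamol
    "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",          # ibuprofen
    "C1=CC=C(C=C1)C(=O)O",                    # benzoic acid
    "OCC1OC(O)C(O)C(O)C1O",                   # glucose (flat)
    "CN1CCCC1C1=CC=CN=C1",                    # nicotine (flat)
    "C1=CC=C2C(=C1)C=CC=C2",                  # naphthalene
    "CC(N)C(=O)O",                            # alanine
    "NC(=O)C1=CC=CN=C1",                      # nicotinamide
    "CC1=CC=C(C=C1)S(=O)(=O)N",               # tosylamide
    "OC1=CC=CC=C1",                           # phenol
    "CCN(CC)CC",                              # triethylamine
    "CC(C)NCC(O)COC1=CC=CC2=C1C=CC=C2")       # propranolol
}

#' @describeIn synthetic Validated generator configuration.
#' @param n_classes Number of classes (default 14, the ATC main classes).
#' @param drugs_per_class Drugs whose primary class is each class.
#' @param multi_label_fraction Fraction of each class's drugs that also
#'   carry the partner class.
#' @param subtree_depth Length of each class's is-a chain.
#' @param cross_link_noise Probability of an extra cross-chain is-a parent
#'   per chain term.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @export
synthetic_config <- function(n_classes = 14L, drugs_per_class = 10L,
                             multi_label_fraction = 0.15,
                             subtree_depth = 3L, cross_link_noise = 0,
                             seed = 1L) {
  cfg <- list(n_classes = as.integer(n_classes),
              drugs_per_class = as.integer(drugs_per_class),
              multi_label_fraction = as.numeric(multi_label_fraction),
              subtree_depth = as.integer(subtree_depth),
              cross_link_noise = as.numeric(cross_link_noise),
              seed = as.integer(seed))
  with(cfg, {
    if (n_classes < 1L || drugs_per_class < 1L || subtree_depth < 1L) {
      config_error("n_classes, drugs_per_class and subtree_depth must be positive")
    }
    if (multi_label_fraction < 0 || multi_label_fraction > 1 ||
        cross_link_noise < 0 || cross_link_noise > 1) {
      config_error("multi_label_fraction and cross_link_noise must lie in [0,1]")
    }
    if (is.na(seed)) config_error("seed must be an integer")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic ontology and benchmark
#'
#' @param config A [synthetic_config()].
#' @return List with `ontology` (an `ontology_graph`), `benchmark` (a
#'   `benchmark_dataset`, fully ontology-covered), and `truth` —
#'   generator bookkeeping: per-drug label sets, primary classes, the ids
#'   of multi-label drugs, the exact multiplicity distribution, per-class
#'   chain terms, and the configuration used.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  withr::local_seed(config$seed)
  M <- config$n_classes
  depth <- config$subtree_depth
  root <- "SYN:1000000"
  chain <- function(m, d) sprintf("SYN:2%02d%04d", m, d)
  drug_term <- function(i) sprintf("SYN:3%06d", i)

  terms <- root
  parents <- list()
  class_terms <- vector("list", M)
  for (m in seq_len(M)) {
    nodes <- chain(m, seq_len(depth))
    class_terms[[m]] <- nodes
    terms <- c(terms, nodes)
    parents[[nodes[[1L]]]] <- root
    for (d in seq_len(depth)[-1L]) {
      parents[[nodes[[d]]]] <- nodes[[d - 1L]]
    }
  }
  # noise: extra is-a parents across chains, always toward a lower class
  # (keeps the graph acyclic). One candidate link and one uniform are drawn
  # per chain term whatever the noise level, and the link is active iff
  # u < cross_link_noise: common random numbers, so at a fixed seed the
  # active link set grows monotonically with the noise level and datasets
  # at different noise levels differ only in those links.
  if (M > 1L) {
    for (m in 2:M) {
      for (d in seq_len(depth)) {
        u <- stats::runif(1L)
        m2 <- sample.int(m - 1L, 1L)
        d2 <- sample.int(depth, 1L)
        if (u < config$cross_link_noise) {
          node <- chain(m, d)
          parents[[node]] <- unique(c(parents[[node]], chain(m2, d2)))
        }
      }
    }
  }

  n <- M * config$drugs_per_class
  primary <- rep(seq_len(M), each = config$drugs_per_class)
  labels <- as.list(primary)
  k_multi <- round(config$multi_label_fraction * config$drugs_per_class)
  multi <- logical(n)
  for (m in seq_len(M)) {
    members <- which(primary == m)
    if (k_multi > 0L && M > 1L) {
      chosen <- members[sample.int(length(members), min(k_multi, length(members)))]
      partner <- m %% M + 1L
      for (i in chosen) labels[[i]] <- sort(c(m, partner))
      multi[chosen] <- TRUE
    }
  }

  alphabet <- synthetic_smiles_alphabet()
  smiles <- alphabet[sample.int(length(alphabet), n, replace = TRUE)]
  drug_ids <- sprintf("D%04d", seq_len(n))
  dterms <- drug_term(seq_len(n))
  for (i in seq_len(n)) {
    par <- vapply(labels[[i]], function(c) chain(c, depth), character(1L))
    parents[[dterms[[i]]]] <- sort(unique(par))
    terms <- c(terms, dterms[[i]])
  }

  graph <- new_ontology_graph(terms, parents)
  ds <- benchmark_dataset(drug_ids, smiles, dterms, labels, n_classes = M)
  mult <- table(factor(lengths(labels), levels = sort(unique(lengths(labels)))))
  truth <- list(labels = stats::setNames(labels, drug_ids),
                primary_class = stats::setNames(primary, drug_ids),
                multi_label_ids = drug_ids[multi],
                n_singletons = sum(!multi),
                multiplicity = stats::setNames(as.integer(mult), names(mult)),
                class_terms = class_terms,
                drug_terms = stats::setNames(dterms, drug_ids),
                config = config)
  list(ontology = graph, benchmark = ds, truth = truth)
}
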