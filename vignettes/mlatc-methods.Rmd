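---
title: "Methods: multi-label ATC class prediction with ontology similarity and Gaussian kernel regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label ATC class prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlatc)
```

## The problem

The WHO's ATC (Anatomical Therapeutic Chemical) system assigns drug
compounds to 14 main classes by their therapeutic and chemical character.
The task is multi-label: a compound may hold several ATC codes at once,
and the interesting prediction target is the *exact* label set, not one
class. `mlatc` implements a hybrid multi-label predictor for this task:
an ontology-similarity predictor for compounds present in a chemical
ontology such as ChEBI, a fingerprint-similarity fallback for compounds
that are not, a hard dispatch rule between the two, the five multi-label
evaluation metrics standard in this literature, and a leakage-safe
jackknife harness with kernel-width tuning. A seeded synthetic generator
makes the whole pipeline testable offline.

## Sample formulation

Let the benchmark \(S = S_1 \cup \dots \cup S_{14}\) be partitioned by
class membership (a multi-label drug lies in several \(S_m\)). A drug is
encoded as the 14-vector

\[ D = [\alpha_1\ \alpha_2\ \cdots\ \alpha_{14}]^T, \qquad
   \alpha_m = \max_{r \in S_m} \operatorname{sim}(d, r), \]

its per-class maximum similarity to the reference drugs. Two similarity
backends implement \(\operatorname{sim}\):

* **Ontology similarity** (`do_feature_vector()`): the Jaccard overlap of
  reflexive is-a ancestor closures of the two compounds' ontology terms,
  \(|A(a) \cap A(b)| / |A(a) \cup A(b)|\). The literature behind this
  family of predictors does not pin down a single formula for
  ontology-derived compound similarity; we chose ancestor-set Jaccard
  because it is bounded in \([0,1]\), symmetric, exactly 1 on identical
  terms, exactly 0 on disjoint closures, and depends only on the is-a
  backbone that every OBO ontology provides. The `method` argument is an
  extension point (`"jaccard_ancestors"` is the only built-in) so an
  information-content measure could be added without touching callers.
* **Fingerprint similarity** (`fingerprint_feature_vector()`): Tanimoto
  coefficient between OpenBabel FP2 hashed path fingerprints (1024 bits,
  substructures up to 7 atoms), computed through ChemmineR. This backend
  stands in for interaction-profile formulations that require external
  chemical-interaction databases; it is deliberately simple and is
  labelled `FALLBACK` in every output.

A class with no eligible reference drug contributes \(\alpha_m = 0\):
absence of similarity evidence, not an error, which keeps tiny jackknife
folds well-defined. Excluding a drug from the reference (for held-out
evaluation) is always the caller's decision via `exclude_ids`; the
featureizer itself never drops the query silently.

### Leave-self-out training formulation

For a drug that is itself part of the reference set, the naive encoding
puts \(\alpha_m = 1\) at each of its own classes (self-similarity), so
training vectors become near-indicators of their own labels. A query
compound from outside the reference can never attain that representation,
and the mismatch measurably distorts the kernel regression: a two-class
query's nearest training vectors become single-class drugs rather than
drugs sharing its class pair. `mlatc` therefore formulates every
*training* drug with its own record excluded as a similarity target
(`build_do_model()`, `build_fingerprint_model()`), so training and query
vectors are draws from the same mechanism. The public featureizer keeps
the self-eligible contract; the exclusion is applied by the model
builders and the jackknife engine.

## The classifier

Each training drug carries a label vector \(L^i\) with
\(\ell^i_m = +1\) if the drug occurs in class \(m\) and \(-1\) otherwise.
For a query \(D^q\) the per-class decision score is Gaussian kernel
regression on the labels:

\[ \Delta_m = \frac{\sum_i \ell^i_m\, e^{-\|D^q - D^i\|^2 / 2\theta^2}}
                   {\sum_i e^{-\|D^q - D^i\|^2 / 2\theta^2}}, \]

and class \(m\) is predicted iff \(\Delta_m \ge 0\) (a tie at exactly
zero predicts the class). \(\theta\) interpolates between two regimes:
\(\theta \to 0^+\) approaches the nearest neighbour's label set,
\(\theta \to \infty\) the unweighted label mean. Both limits are verified
numerically in the test suite (\(\theta = 10^{-6}\), \(10^{6}\)).

Numerical choices:

* **Stability shift.** For small \(\theta\) every raw weight underflows.
  The minimum squared distance is subtracted inside all exponents — an
  exact, ratio-preserving shift, not an approximation — so the weight sum
  is at least 1.
* **Clamping.** \(\Delta_m\) is a convex combination of \(\pm 1\) and is
  clamped to \([-1, 1]\) to absorb one-ulp floating-point overshoot.
* **Non-empty predictions.** If every \(\Delta_m < 0\), the arg-max class
  is returned (ties toward the lowest class index) and the result is
  flagged `forced`. An empty prediction would make the aiming metric
  undefined; the flag keeps the fallback observable rather than silent.
* **Canonical summation order.** The jackknife engine accumulates kernel
  sums in drug-id order regardless of record order, so evaluation is
  bitwise invariant under permutations of the benchmark file — including
  at exact decision-boundary ties, where summation order could otherwise
  flip a sign.

## Hybrid dispatch

A query with an ontology term that resolves to a non-obsolete term of the
loaded ontology is encoded with ontology features and scored by the DO
sub-model; any other query takes the fingerprint route. Routing depends
on coverage only, never on the scores, and every prediction reports which
sub-predictor produced it. "Covered" is operationalized as "carries a
term identifier resolving in the loaded OBO graph" — the only
offline-checkable reading; structure-based resolution of SMILES to
ontology entries is out of scope.

## Evaluation

`five_metrics()` implements the five standard multi-label rates: aiming
(precision-like), coverage (recall-like), accuracy (Jaccard-like),
absolute true (exact-match rate) and absolute false (normalized symmetric
difference). Empty actual or predicted sets are rejected — the formulas
divide by set sizes — instead of being scored as zero, so contract
violations surface. The label universe size \(M\) is a parameter
(default 14) so small toy universes are scored honestly.

`jackknife()` is leave-one-out: for each drug \(k\), the model is built
from all remaining drugs and \(k\) is predicted. The held-out drug is
excluded both as a training instance and as a similarity target: any
\(\alpha\)-component computed against the held-out drug itself would leak
its labels into the fold. Excluding one drug moves a per-class maximum
only when that drug attained it, so the engine precomputes the three
largest similarities per (drug, class) and patches fold features in
constant time per entry; distances are computed once per fold and shared
across all kernel widths, which makes the grid search in
`optimize_theta()` barely more expensive than a single jackknife.

`optimize_theta()` maximizes the jackknife absolute-true rate over a grid
of widths, ties broken toward the smaller width. The default grid
\(\{1/n\}_{n=1}^{50} \cup \{1/n^2\}_{n=1}^{10}\) spans both kernel
regimes and contains \(1/36\), the operating point this family of
predictors uses in production; the exact tuning grid used historically is
not recoverable, so the default is a reconstruction and is overridable.

## The synthetic generator

`generate_benchmark()` emulates the one statistical property the
ontology encoding exploits: *drugs of one class share ontology
ancestry*. It builds one root, a chain of `subtree_depth` terms per class
(successively narrower chemical families), and one term per drug attached
at the bottom of its class chain — drugs are leaf-level specific
compounds. A multi-label drug gets a parent at the bottom of each of its
class chains. Defaults are 14 classes, 10 drugs per class, and a
multi-label fraction of 0.15 per class, matching the roughly 15%
multi-label share of the real 3,883-drug ATC benchmark. Multi-label
drugs pair each class with a fixed partner (the next class index,
wrapping): real ATC label pairs are strongly correlated, and deterministic
pairing keeps the exact multiplicity distribution in the generator's
bookkeeping. `cross_link_noise` is the probability that a chain term
gains an extra is-a parent in another class's chain; candidate links and
their uniforms are drawn once per term whatever the noise level (common
random numbers), so at a fixed seed the active link set grows nestedly
with the noise level and benchmarks at different noise levels differ
*only* in those links — a clean dose-response design.

What the generator does **not** emulate, and what passing tests therefore
do not show: real chemistry (SMILES are drawn from a fixed 16-molecule
alphabet uncorrelated with class, so the fingerprint fallback is
exercised but uninformative on synthetic data); ChEBI's scale and its
tangled multiple inheritance; label multiplicities above two; and any
relationship between structural similarity and ontology placement.
Perfect recovery on the noise-free synthetic benchmark demonstrates that
the pipeline is correct and leakage-free, not that the method attains any
particular accuracy on real drugs.

## Problem sizes and reproducibility

The shipped evaluations use the generator defaults (140 drugs, a
183-term ontology, the 53-point default width grid) — sizes at which a
full jackknife-with-tuning runs in about a second, chosen so the whole
pipeline is exercised end to end routinely. Every random choice flows
from one explicit seed per `generate_benchmark()` call through an
isolated RNG scope (`withr`); no global seed state is touched, and the
same seed reproduces ontology and benchmark files byte for byte.
`scripts/acceptance.R` regenerates the study conditions from a
command-line seed and recomputes every reported quantity from scratch.

## Known limitations

* The ontology similarity uses is-a edges only; other OBO relationship
  types (`has_role`, `has_part`) are ignored.
* The fingerprint fallback is a structural stand-in, not a reimplementation
  of interaction-profile predictors; its accuracy on real data is not
  claimed.
* Obsolete ontology terms are dropped at parse time, so a drug mapped to
  an obsolete term routes to the fallback rather than to a resurrected
  term.
* ATC sub-level codes (2nd–5th levels) are out of scope; the label
  universe is the 14 main classes (configurable for toy data).
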