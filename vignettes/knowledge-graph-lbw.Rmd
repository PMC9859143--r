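---
title: "Knowledge-graph features for low-birth-weight prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph features for low-birth-weight prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbwgraph)
```

## The problem

Low birth weight (LBW, birth weight below 2500 g) affects roughly one in
nine pregnancies in the cohorts this package emulates and is strongly
associated with neonatal morbidity. Predicting it from maternal risk factors
is a heavily imbalanced binary classification problem: the tabular
representation treats patients as independent rows, although mothers who
share complications (gestational diabetes, previous LBW, consanguinity, ...)
tend to have correlated outcomes.

The pipeline implemented here makes that relational structure explicit. A
cohort table is transformed into an undirected bipartite *knowledge graph*
G = (V, E): every patient is a node, every binary complication is a node,
every level of a categorical factor (blood group A, B, ...) is a node, and
an edge joins a patient to each complication or category value they carry.
Continuous measures (age, BMI, height) remain properties of the patient node
rather than becoming nodes. Patients with similar complication profiles are
then close in the graph, and that proximity is harvested in two ways:
node2vec embeddings and classical topological statistics. Classifiers are
compared across four feature sets — original tabular factors, embeddings,
embeddings plus topological features, and everything combined — under
repeated stratified cross-validation with imbalance-aware metrics.

## Random-walk embeddings

node2vec performs second-order biased random walks. Standing at node *n*
having arrived from *t*, the unnormalized probability of stepping to a
neighbour *x* is the edge weight times a bias that depends on the distance
d(t, x):

* d = 0 (step back to *t*): bias 1/p — the *return* parameter p controls
  immediate backtracking;
* d = 1 (x is also a neighbour of *t*): bias 1;
* d = 2 (x moves away from *t*): bias 1/q — the *in-out* parameter q
  interpolates between breadth-first (large q, walks stay local) and
  depth-first (small q, walks escape) behaviour.

In a walk context d(t, x) can only be 0, 1 or 2, so the package computes it
locally (x equals t; x adjacent to t; otherwise 2) instead of running a
shortest-path search. The first step of each walk has no predecessor, so it
is uniform over neighbours, matching the reference implementation of the
method. Isolated start nodes yield length-1 walks.

Walk sequences are treated as sentences and embedded with skip-gram and
negative sampling (dynamic context window, unigram^0.75 negative table,
linearly decaying learning rate), written in C++ and fully deterministic
given a seed on a single thread. A second, closed-form backend factorizes
the positive pointwise-mutual-information matrix of windowed walk
co-occurrences by a seeded randomized truncated SVD; it exists because a
gradient-free, deterministic factorization is occasionally preferable for
debugging and because the two backends cross-check each other in the test
suite (both must separate the cliques of a two-clique toy graph).

Defaults: p = 1, q = 1, walk length 80, 10 walks per node, 64 dimensions,
window 5, 5 epochs, 5 negative samples, learning rate 0.025. The underlying
study reports none of these settings, so the package adopts the method's
customary defaults; all are exposed through `walk_params()` and
`embedding_params()` and none is treated as a claim about the original
analysis.

## Topological features

Per patient node the package computes: degree (with in-degree, out-degree
and weighted degree reported under the undirected convention in-degree =
out-degree = degree, weighted degree = their sum); closeness (reciprocal
of summed shortest-path distances within the node's component, 0 for
isolated nodes); unnormalized betweenness; eigenvector centrality (leading
adjacency eigenvector, unit Euclidean norm); HITS hub and authority scores
(computed by shifted power iteration on A + I with L1 normalization — the
shift guarantees convergence on bipartite graphs — and coincident on an
undirected graph, where both reduce to the Perron eigenvector of A);
PageRank with damping 0.85; the local clustering coefficient (triangles
over neighbour pairs d(d−1)/2, 0 when d < 2); the Louvain community label;
the k = 3 nearest neighbours in embedding space by Euclidean distance; and
the mean Jaccard neighbour-set similarity to those k neighbours.

Two printed formulas in the source material required interpretation. Its
PageRank recurrence divides a neighbour's score by the *target's* out-degree,
which does not define a stochastic process; the package uses the standard
semantics (each contributor j is divided by j's own degree), consistent with
the classical reference the formula cites. Its clustering denominator is
rendered ambiguously and is read as d(d−1)/2, the number of neighbour pairs.
The nearest-neighbour feature is computed in embedding space (the source
describes a Euclidean distance), with graph-space Jaccard similarity used to
summarize how structurally similar those embedding neighbours are.

The centralities are delegated to igraph; the test suite verifies each one
against independent brute-force oracles (distance and path counting via
adjacency-matrix powers, dense eigendecomposition, a dense linear solve of
the PageRank fixed point, triangle counting via A³) on every connected graph
with up to six nodes. HITS is implemented directly in the package because
the installed igraph returns asymmetric hub/authority scores on undirected
graphs, violating the symmetry the undirected formulation requires.

The community label enters the classifiers one-hot encoded — a community id
is nominal, not ordinal. Node similarity is summarized per node (mean
Jaccard to the top-k embedding neighbours) because a full pairwise matrix is
not a per-patient feature.

## The synthetic cohort

The real cohort (3453 pregnancies, 391 LBW = 11.32%, about 40 mixed-type
risk factors) is available only on request, so the package generates a
synthetic stand-in with the structure the method assumes:

* each patient draws a latent *complication profile* (3 profiles by
  default, uniform); binary complication prevalences are multiplied by a
  per-profile affinity (3 inside the enriched profile, 0.4 outside), so
  patients within a profile share complications — the premise that gives a
  patient–complication graph its signal, and what makes Louvain communities
  and embedding-space neighbourhoods meaningful in the synthetic data;
* factors are roughly 60% binary complications (prevalences 0.08–0.30),
  20% categorical (blood-group-like distributions) and 20% continuous
  (age 31.6 ± 6.07, BMI, height, weight — the age moments follow the
  cohort's published descriptives);
* the label is Bernoulli with a logistic model in the factors: binary
  factors enter as 0/1 with modest log-odds effects (0.25–0.9), continuous
  factors as z-scores (±0.2), categorical factors as an indicator of their
  last, highest-risk category (0.35). The intercept is calibrated by
  bisection so the expected prevalence matches the 11.32% target. The
  logistic form is the package's choice — the source describes no
  generative model — and is the minimal model under which both tabular and
  graph features can carry signal. At these defaults the generating model's
  own (Bayes-optimal) AUC is about 0.79, comparable to the discrimination
  the original study reports, and `effect_scale = 0` yields an exact null
  cohort for calibration tests.

The generator reproduces none of the real cohort's marginal tables (they
are not public), so passing tests demonstrate that the *pipeline* behaves
correctly under the assumed dependence structure — not that the synthetic
data match the clinical population. Missing values can be masked completely
at random (default rate 0); the original study does not describe its
missing-data handling, so imputation (training-fold mode/median) is
deliberately simple.

## Evaluation protocol

Cross-validation is 5-fold, repeated 5 times, stratified so every fold
preserves the class ratio within one sample. Graph construction, walks,
embeddings and topological features are computed once on the full cohort
before cross-validation — the *transductive* protocol the original analysis
used (its stated limitation is exactly that new nodes unseen at graph
construction are hard to classify). The outcome label is structurally barred
from the graph, so no label leakage is possible; the residual structural
leakage (test patients shape the graph) is inherent to the protocol and
documented rather than hidden. A strict inductive mode
(`inductive = TRUE`) rebuilds the graph per fold with held-out patients
contributing no edges; they then carry isolated-node features, which is the
honest consequence of the transductive design.

Continuous features are z-scored and missing values imputed using
training-fold statistics only. Classifiers are consumed through a
fit/predict-probability contract with the study's hyperparameters as
defaults: random forest (100 trees, sqrt(p) features), Gaussian naive
Bayes, ridge logistic regression (penalty 1e-8, effectively unregularized),
3-nearest-neighbour vote with Euclidean distance, a single-hidden-layer
perceptron (16 units, weight decay 0.001, 200 iterations — the R stack's
standard feed-forward network), XGBoost (100 rounds, learning rate 0.01)
and a second gradient-boosted configuration with leaf-wise (lossguide)
histogram growth at the same learning rate. Seven classifiers mirror the
seven result tables being replicated; no class rebalancing and no
hyperparameter tuning are performed, matching the original design.

Metrics per fold: support-weighted precision, recall and F-score (per-class
formulas TP/(TP+FP), TP/(TP+FN), 2PR/(P+R) with the 0/0 → 0 convention);
AUC-ROC as the tie-corrected Mann–Whitney rank statistic; and the
precision–recall area for the LBW class. The PR curve is built from a
threshold sweep, and between consecutive achievable operating points
A = (TP_A, FP_A) and B = (TP_B, FP_B) precision is interpolated at every
unit true-positive increment x by

y = (TP_A + x) / (TP_A + x + FP_A + x·(FP_B − FP_A)/(TP_B − TP_A)),

i.e. false positives accrue linearly with true positives between operating
points; the area is the trapezoid integral of precision over recall, with
the curve anchored at recall 0 at the precision of the first true positive.
"PR overall" is the support-weighted mean of the per-class areas (each class
scored by its own predicted probability) — the source reports an overall PR
value without defining it, and this weighting parallels its weighted
precision/recall/F convention. Reported numbers are mean and SD over the 25
folds.

## Numerical choices and degenerate inputs

* Power iterations (HITS) stop at an L1 change below 1e-10 with a
  1000-iteration cap; PageRank and eigenvector centrality inherit igraph's
  solvers and are tested to 1e-8 against dense solves.
* Transition distributions are renormalized exactly; ties in embedding-space
  nearest neighbours break by embedding row order, making results
  reproducible.
* Isolated patients yield length-1 walks, zero embedding vectors, zero
  closeness/betweenness/clustering and keep their row in every feature set.
* Bisection for the label-model intercept runs on [−40, 40] to 1e-10 and
  fails loudly if the effects are non-finite.
* All randomness (cohort, walks, embedding initialization and sampling,
  folds, classifier seeds) derives from user-supplied integer seeds; the
  walk and embedding code uses its own xorshift generator so results do not
  depend on R's global RNG state.

## Problem sizes

The test-suite experiments use the cohort sizes the analyses are designed
around: exhaustive centrality verification on all connected graphs with up
to 6 nodes; calibration and determinism checks at n = 1000; the
feature-set comparison at n = 1500 over 5 generator seeds; and one
full-scale run at n = 3453 with 40 factors and 64-dimensional embeddings.
The acceptance script evaluates the four feature sets with XGBoost at
n = 1500 and reports the null calibration at n = 1000.

## Known limitations

* The synthetic cohort is a structural emulation, not a statistical twin of
  the restricted clinical data; absolute metric values are not comparable
  with the original study's tables, only orderings and calibration
  properties are.
* The transductive protocol cannot score a truly new patient without
  rebuilding the graph and embeddings.
* The skip-gram trainer is single-threaded by design (determinism over
  speed); full-scale embedding takes a couple of minutes.
* The perceptron uses a logistic hidden layer (the R stack's `nnet`), not
  ReLU; with one hidden layer and early stopping by iteration cap this is
  the closest faithful stand-in for the study's MLP configuration.
* Only binary outcomes are supported; the metrics generalize to more
  classes but the cohort generator and graph builder assume LBW vs normal.
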