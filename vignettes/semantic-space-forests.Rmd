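---
title: "Semantic-space ensembles and randomized-tree forests for ADE detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic-space ensembles and randomized-tree forests for ADE detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Care episodes documented in electronic health records mix four kinds of
clinical events: words from free-text notes, diagnosis codes, drug codes and
measurement types. Detecting whether an episode involves a particular adverse
drug event (ADE) — operationalized as an ADE-specific diagnosis code having
been assigned — is a binary classification problem over this heterogeneous,
high-dimensional, sparse event data. `adeforest` implements a pipeline that
(i) learns dense *distributed representations* of clinical events from their
co-occurrence structure, (ii) builds many such representations by varying the
context window of the representation learner, and (iii) trains forests of
randomized trees that exploit this *ensemble of semantic spaces* under three
utilization strategies.

## Semantic spaces

For each data type, all event sequences are extracted from the care episodes
(structured events ordered by recording day; notes sentence by sentence). A
skip-gram model with negative sampling is trained on each set of sequences:
given item–context pairs \((i, c)\) with contexts drawn from a symmetric
window of \(w\) items on each side, it finds parameters maximizing
\(\prod_{(i,c)} p(c \mid i)\). The input-layer parameters are the semantic
vectors. One space is trained per (data type, window size): with four data
types and the default ten window sizes \(2, 4, \dots, 20\) ("2+2" … "20+20"),
the grid holds 40 spaces of a shared dimensionality \(V\) (200 at full scale,
25 at desk scale).

Training choices worth making explicit:

* **Fixed symmetric window.** Every item within \(w\) positions is a context.
  The common trick of sampling a reduced window per position is deliberately
  not used: with a fixed window, a pair of events co-occurring only at
  distance \(d\) receives training signal exactly when \(w \ge d\), which
  makes window-size effects sharp and testable.
* **Determinism.** Training is single-threaded with an internal xorshift
  generator seeded from the configuration, so identical inputs give
  bit-identical vectors. Desk-scale corpora train in seconds, so the usual
  asynchronous-update speedups buy nothing here.
* **Defaults** (all configurable): 5 epochs, 5 negative samples, initial
  learning rate 0.025 with linear decay, `min_count = 1` (synthetic corpora
  have no noise tokens worth pruning).
* **Target-code exclusion.** The diagnosis code that defines the positive
  class is deleted from diagnosis sequences *before* training — neighbouring
  events become adjacent — so no diagnosis space ever contains the label
  token. The same code is also removed at featurization time, so the
  exclusion holds for both routes into the features.

## From episodes to features

An episode's representation at window size \(w\) concatenates, in the fixed
order word–diagnosis–drug–measurement, one block per data type: the sum of
each distinct event's vector multiplied by its count in the episode
(a count-weighted bag of embeddings). Events missing from a space's
vocabulary contribute zero. No normalization is applied — the count-weighted
sum is the representation. Blocks are \(V\) wide, so one window yields
\(V \times T\) features and the concatenation over all \(P\) windows
\(V \times T \times P\).

## The three utilization strategies

All strategies train `n_trees` (default 500) fully grown Gini decision trees
(`rpart` with `cp = 0`, minimum bucket 1, no surrogates), each on a bootstrap
replicate of the training episodes, and predict by unweighted majority vote
(the score is the fraction of trees voting positive; a score exactly at the
threshold yields the negative label). They differ in what each tree sees:

| strategy | representation per tree | feature subset per tree |
|---|---|---|
| FDR | all windows concatenated (\(VTP\) wide) | \(\lfloor\sqrt{VTP}\rfloor\) |
| RDR-FS | one window drawn uniformly per tree (\(VT\) wide) | \(\lfloor\sqrt{VT}\rfloor\) |
| RDR-ALL | one window drawn uniformly per tree | all \(VT\) |

At \(V = 200\), \(T = 4\), \(P = 10\) the ensemble exploits 8000 features in
every strategy while a single tree inspects 89 (FDR), 28 (RDR-FS) or 800
(RDR-ALL). Square roots are floored. Random subspacing is applied once per
tree, not per node: the method is bagging plus the random subspace method,
applicable to any base learner, rather than the classical random forest.
Window sampling for the RDR strategies is uniform *with replacement* across
trees — with 500 trees and 10 windows any without-replacement scheme would be
ill-posed. Per-tree seeds are derived from the master seed by a counter
scheme, so any single tree is reproducible in isolation.

The count-based baseline applies the same bagging-plus-subspacing forest to
raw per-token event counts (one sparse column per observed token, namespaced
by data type, target code removed).

## Evaluation

* **Accuracy** is the percentage of correctly classified episodes; **AUC** is
  the probability that a random positive is scored above a random negative
  (ties count one half), computed through the midrank identity and verified
  in the tests against brute-force pair enumeration.
* **Ensemble inspection**: average tree accuracy is the mean of each tree's
  own test accuracy (each tree classifying through its own representation);
  *diversity* is crudely estimated as ensemble accuracy minus average tree
  accuracy, on the fraction scale. For averaging ensembles in the regression
  sense the exact ambiguity decomposition \(E = A - D\) links squared
  ensemble error, mean squared base error and the mean squared deviation of
  base predictions from the ensemble prediction;
  `ambiguity_decomposition()` computes all three and the tests verify the
  identity to \(10^{-10}\).
* **Cross-validation** is stratified; semantic spaces are pretrained once on
  the whole background corpus (representation learning is unsupervised and
  label-independent) and shared across folds, mirroring pretraining on the
  full clinical corpus. Folds are shuffled under a fixed seed so all
  strategies see identical folds, which tightens the paired comparison.
* **Friedman test**: per-dataset ranks (rank 1 = highest score, average ranks
  on ties), \(\chi^2_F = \frac{12n}{k(k+1)} \sum_j (\bar R_j -
  \frac{k+1}{2})^2\) with \(k - 1\) degrees of freedom. The classic
  chi-square form is canonical here; the test suite checks agreement with an
  independent reference implementation.
* **Post-hoc pairwise comparison**: \(z = (\bar R_i - \bar R_j) /
  \sqrt{k(k+1)/(6n)}\), two-sided normal p-values, adjusted by the
  Bergmann–Hommel procedure. Exhaustive hypothesis sets are enumerated from
  all partitions of the methods (feasible for \(k \le 4\); `holm` is the
  fallback beyond), and the adjusted p-value of a hypothesis is the largest
  \(|E| \cdot \min_{j \in E} p_j\) over exhaustive sets \(E\) containing it,
  capped at 1.
* **Pool-size experiment**: for each pool size \(s\), every one of the
  \(\binom{P}{s}\) window subsets is evaluated with a stratified 70/30 split
  and the scores averaged. Split seeds are keyed by the window subset itself,
  so a single-window run reproduces the corresponding member of a larger
  sweep exactly.

## The synthetic EHR generator

Real clinical corpora cannot ship with the package, so `generate_corpus()`
draws desk-scale corpora with the structural properties the method relies
on. Each episode belongs to one of a few latent clinical states; each state
holds a sparse categorical distribution over latent *meanings* for every data
type (Dirichlet-like draws with concentration 0.25, so states prefer a few
meanings). Each surface vocabulary is partitioned into synonym clusters
(defaults: cluster sizes 20/10/8/6 for word/diagnosis/drug/measurement over
vocabularies of 400/60/40/30); an emission picks a meaning from the state's
distribution, then a surface token from the meaning's cluster.

Two design points matter:

* **Per-episode lexical locking.** Each episode first draws 2 admissible
  variants per meaning and emits only those, emulating clinician- and
  coder-specific lexical habits. Locking is what separates the two
  representations: a given surface token can appear in at most
  2/cluster-size of the episodes that express its meaning — however many
  events an episode contains — so per-token count features are starved, while
  embeddings, which place cluster members close together (they share context
  distributions across the corpus), retain the full meaning-level signal.
  Two variants rather than one are locked because averaging over two vectors
  halves the idiosyncratic noise an episode inherits from any single token's
  imperfectly trained vector.
* **Hidden ADE state.** A positive episode (probability `ade_prevalence`,
  default 0.3) receives its target code in the diagnosis stream and mixes its
  state's emission distributions with a code-specific ADE profile at weight
  `signal_strength` (default 0.9) across *all four* streams. The target codes
  are reserved tokens outside every synonym cluster, so leakage removal
  cannot be circumvented by a synonym; with `signal_strength = 0` positives
  are distributionally identical to negatives apart from the removed code,
  and held-out AUC stays at chance — the null calibration the tests check.

What the generator does *not* emulate: ICD-10/ATC code hierarchies,
visit-level temporal dynamics, missing-data mechanisms, realistic token
frequency spectra (vocabularies are three to four orders of magnitude smaller
than a hospital corpus). Passing benchmarks on this generator demonstrate
that the implementation realizes the method's mechanics and produces the
expected qualitative orderings — not that those orderings transfer to any
particular clinical corpus.

## Problem sizes used in the tests

The package's own benchmark runs at desk scale, chosen so the full pipeline
executes in minutes on one core: 300 patients with 1–3 episodes each
(≈ 600 episodes), 25-dimensional vectors, window pool {2, 5, 8}, 50 trees,
5 datasets of 25–40 positives per class, 70/30 splits replicated over 10
seeds. Cross-validation properties use 10 folds with 50 positives per class —
below that, per-fold AUC estimates (3 positives vs 3 negatives is nine pairs)
are too unstable to say anything about calibration. The pool-size trend is
checked with a five-window pool, comparing sizes 1 and 5 over 10 seeds.

## Known limitations

* The Bergmann–Hommel adjustment is restricted to four methods or fewer;
  beyond that the implementation refuses and suggests Holm.
* Per-node feature sampling (random forest proper) is not available; the
  implemented method is per-tree subspacing by construction.
* `rpart` caps tree depth at 30, which is unreachable at desk scale but
  would truncate fully grown trees on much larger datasets.
* Word sequences carry no temporal structure beyond sentence grouping, and
  same-day structured events keep their input order (the data model has no
  sub-day timestamps).
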