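---
title: "Predicting drug–disease associations over a molecular association network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-disease associations over a molecular association network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`grlmn` predicts drug–disease associations (DDAs) by combining two views
of every molecule in a heterogeneous **molecular association network
(MAN)** over five node kinds — drugs, diseases, proteins, miRNAs and
lncRNAs — linked by nine association types (drug–disease, drug–protein,
protein–protein, protein–disease, lncRNA–protein, lncRNA–disease,
miRNA–protein, miRNA–disease, miRNA–lncRNA), all with unit edge weight:

1. **Node attributes** — what the molecule *is*: a 64-dimensional vector
   per node computed from the molecule's own data.
2. **Node behavior** — where the molecule *sits* in the network: a
   64-dimensional LINE embedding of the MAN.

A candidate pair (drug *r*, disease *e*) is represented by the
concatenation *attr(r) ‖ emb(r) ‖ attr(e) ‖ emb(e)* (width 256) and
scored by a random forest trained on known associations against an equal
number of sampled non-associations. The two ablations keep only the
attribute half (width 128, reported as `GRLMN_A`) or only the embedding
half (`GRLMN_M`).

### Disease attributes: semantic similarity over MeSH DAGs

Every disease descriptor owns one or more MeSH tree numbers; stripping
trailing segments enumerates its ancestors, giving a per-disease DAG.
A member $d$ of disease $e$'s DAG contributes

$$C_e(d) = \begin{cases} 1 & d = e\\
\max\{\varepsilon \cdot C_e(d')\,:\, d' \text{ child of } d\} & d \ne e
\end{cases}$$

with decay $\varepsilon \in (0,1)$, and $DV(e) = \sum_{d} C_e(d)$. Two
diseases are compared through their shared ancestors:

$$SV_1(i,j) = \frac{\sum_{d \in N_i \cap N_j} \bigl(C_i(d) + C_j(d)\bigr)}{DV(i) + DV(j)},$$

which is symmetric, lies in $[0,1]$, and equals 1 exactly when the two
DAGs coincide (the same descriptor). The package defaults to
$\varepsilon = 0.5$, the standard choice in this family of DAG-based
similarity measures; it is exposed as `epsilon` everywhere.

The pairwise similarity matrix is turned into fixed-width node vectors:
each disease's row is compressed to 64 dimensions with the stacked
autoencoder when there are more than 64 diseases, and zero-padded to 64
otherwise (a strictly-decreasing encoder cannot widen its input). This
keeps every node kind at the same attribute width.

### Sequence attributes: grouped 3-mers

Protein and ncRNA sequences are reduced to a 4-letter alphabet — the
amino-acid groups {A,V,L,I,M,F,W,P}, {G,S,T,C,N,Q,Y}, {R,K,H}, {D,E}
(hydrophobic / polar / basic / acidic), or the four ribonucleotides with
DNA `T` read as `U` — and every overlapping window of length 3 is
counted, giving a $4^3 = 64$-bin frequency vector that sums to 1.
Characters outside the alphabet are dropped (and counted in a message);
a sequence with fewer than three usable residues yields no attribute and
the node is flagged.

### Drug attributes: compressed circular fingerprints

SMILES are converted to circular (Morgan-type, radius-2 / ECFP4)
fingerprints through OpenBabel, folded to 1024 bits, and compressed to
64 dimensions by a stacked autoencoder (1024 → 256 → 64). The
autoencoder is a symmetric sigmoid network pretrained greedily layer by
layer: each stage learns to reconstruct its own input under
mean-squared error by minibatch SGD (learning rate 0.01, batch 16,
50 epochs per layer by default), and its code feeds the next stage.

### Behavior vectors: LINE over the MAN

LINE models two proximities. First order: the probability that two
vertices are neighbors, $p_1(a,b) = \sigma(u_b^\top u_a)$, matched
against the empirical edge distribution $\omega_{ab}/W$. Second order:
the probability that $b$ appears as a *context* of $a$,
$p_2(b \mid a) = \exp(\acute u_b^\top u_a) / \sum_k \exp(\acute u_k^\top u_a)$,
matched against $\omega_{ab}/d_a$. Minimizing the weighted negative
log-likelihoods $L_1$ and $L_2$ fits each half.

Training uses edge sampling: each draw picks an edge by weight (alias
method) and pairs it with $K = 5$ negatives drawn proportional to
degree$^{0.75}$, replacing the full softmax of the second-order model.
Undirected edges are expanded to both directions for the second order
and randomly oriented per draw for the first. The two halves are trained
independently at 32 dimensions each and concatenated (first order, then
second). Defaults: initialization uniform in $(-0.5/\text{dim},
0.5/\text{dim})$, initial learning rate 0.025 decaying linearly to 1%,
and a sample budget of $500\,|E|$ per order — at $100\,|E|$ the
second-order loss on graphs of a few hundred nodes is still visibly
falling and the context vectors have not yet spread, so the package uses
the larger budget; both are configurable (`line_config()`).

The exact objectives survive in `exact_line_losses()` (guarded to
$|V| \le 2000$) and in `line_descent_reference()`, a full-gradient
reference optimizer for small graphs. They exist to validate the
sampled trainer — the test suite checks that both objectives decrease
strictly under exact gradient descent and that trained embeddings beat
random initializations — not for production use.

### Classifier

The production classifier is a random forest with `num.trees = 100` and
`max.depth = 110` (the grid-searched values), all other settings at the
`ranger` defaults, probability splits, fixed seed, one thread for
reproducibility. AdaBoost (discrete SAMME over depth-3 `rpart` trees,
written in-package since no boosting-with-trees package is a hard
dependency), logistic regression and Gaussian naive Bayes sit behind
the same interface for comparison runs.

## Evaluation protocol

`grlmn_cv()` performs stratified five-fold cross-validation on the known
associations plus an equal number of negatives sampled uniformly from
unobserved (drug, disease) pairs. Metrics are sensitivity, specificity,
precision, accuracy, Matthews correlation (undefined denominators are
reported as `NA`, never coerced to 0), and trapezoid AUC (equal to the
normalized Mann–Whitney statistic; verified against an independent
implementation). Fold summaries report mean ± sample standard deviation.

**Leakage-safe re-embedding is the default.** Each fold's held-out
positive edges are removed from the MAN before LINE runs, and their
absence is asserted, so the features of a test pair can never encode the
edge being predicted. `leakage_safe = FALSE` restores the optimistic
protocol that embeds the full graph once; the difference between the two
is exactly the optimism introduced by letting test edges shape the
embedding, and the package keeps both so that the effect is measurable.
Note an asymmetry the safe protocol cannot remove: training positives
remain present as edges while held-out positives do not, so a classifier
leaning on direct-edge signatures generalizes worse than its training
fit suggests. This shows up as the embedding ablation trailing the
attribute ablation on synthetic data.

**Case-study ranking.** `grlmn_rank()` deletes every drug association
of the query disease, re-embeds, retrains, and ranks all drugs. The
query's candidate pairs are excluded from the negative pool: if they are
allowed in, the query — present in training only as negatives — can be
isolated by disease-identifying attribute coordinates and every
candidate inherits a near-zero score, inverting the ranking. Ties are
broken lexicographically by drug id for reproducibility.

## The synthetic data generator

`simulate_man()` produces a complete, self-consistent input bundle: a
MAN with planted community structure, sequences, SMILES and a MeSH-style
descriptor table. It exists because a planted-block world is the
smallest world in which the method's premise — association patterns
among the five molecule kinds carry drug–disease signal — is true and
quantifiable, giving the test suite a known ground truth to recover.

Design, with defaults:

* Node counts 40 / 60 / 120 / 60 / 30 (drugs / diseases / proteins /
  miRNAs / lncRNAs): the composition of a real association compendium at
  roughly 1/50 scale, ~310 nodes, keeping the full pipeline under a
  minute per cross-validation on one CPU.
* Four communities; each of the nine edge kinds is a block model.
  The drug–disease layer realizes within/between probabilities
  `dd_base*(1+3*signal)` and `dd_base*(1-signal)`; auxiliary layers
  interpolate their within-community probability from `between` up to
  `within` as `signal` rises. `signal = 0` collapses every contrast to
  a null model.
* `dd_base = 0.25`. Scaling the node counts down by 50 shrinks the
  number of labeled pairs by ~2500×, so keeping a real compendium's
  ~11% association density would leave a few hundred training pairs —
  demonstrably below what the forest needs to learn the pair-matching
  function (in a controlled experiment its held-out AUC rose from ~0.76
  at 450 clean-label pairs to ~0.99 at 1000). The denser layer keeps
  the scaled-down recovery experiment powered; it is a property of the
  simulation scale, not a claim about real density.
* `attr_noise = 0.10`: each node's *attribute* profile (sequence
  composition, MeSH branch, SMILES scaffold family) is drawn from a
  random community with this probability, while its edges keep the true
  community. Real attributes correlate imperfectly with interaction
  communities; this also means attribute-driven recovery legitimately
  fails for the minority of mislabeled nodes.
* Sequences: per-community Dirichlet profiles over the reduced
  alphabet; miRNAs get 20–26 nt, others 80–200 (lncRNAs doubled).
  Drugs: per-community scaffold families with randomized linkers and
  terminal groups, all valid SMILES. MeSH: one hierarchy branch per
  community, diseases attached beneath their community's branch so
  semantic similarity is graded within communities and zero across.
* 10% of true drug–disease edges are reserved (never placed in the
  graph) as held-out positives for ranking-recovery experiments.
* A connectivity pass attaches any isolated node to a protein of its
  community, since an isolated node cannot be embedded.

What passing tests on this generator do **not** show: robustness to
degree heterogeneity, to incomplete or biased edge sampling, to
realistic chemistry, or to the scale of real compendia. The generator
makes no attempt to match real degree distributions.

## Numerical choices and degenerate inputs

* Sigmoid dot products are clamped to ±35 before exponentiation.
* Second-order probabilities use log-sum-exp stabilization.
* Duplicate edges collapse to one unit-weight edge; self-loops are
  skipped with a warning; malformed rows abort with their line number.
* Diseases without a MeSH DAG, sequences under 3 usable residues and
  unparseable SMILES leave the node flagged with a zero attribute
  vector; flagged drugs and diseases are excluded from classifier
  training pairs (zero vectors would train silently) but stay in the
  graph.
* All randomness flows from one master seed per entry point, from which
  per-stage seeds are derived; reruns with the same seed are
  bit-identical (the LINE trainer uses its own integer RNG, so results
  do not depend on platform distribution implementations).

## Problem sizes used by the test suite

Unit tests run on graphs of 3–40 nodes; pipeline tests on a ~105-node
simulation; the end-to-end recovery experiment on the ~310-node default
with five-fold leakage-safe cross-validation of all three feature
variants plus a null run. These sizes were chosen so the behavior under
test (oracle equality, monotone descent, planted-signal recovery,
chance-level nulls) is already unambiguous at small scale.

## Known limitations

* The leakage-safe protocol still trains on positives whose edges are
  embedded (see above); fully transductive-safe variants (embedding
  with *all* labeled edges removed) are expressible via
  `drop_dd_edges()` but are not the default.
* Ranking quality for a disease rests on its attributes and auxiliary
  edges once its drug edges are deleted; a disease with misleading
  attributes and few auxiliary edges is not recoverable.
* The AdaBoost comparator is a compact reference implementation, not a
  tuned production boosting stack.
* No information-content similarity variants, no Node2vec-style walk
  embeddings, no automated database retrieval: inputs are user-supplied
  flat files.
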