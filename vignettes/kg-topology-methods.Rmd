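---
title: "Edge topology and embedding accuracy in knowledge graphs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge topology and embedding accuracy in knowledge graphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgtopo)
```

## Motivation

Biomedical knowledge graphs encode facts as directed labelled triples
(head, relation, tail) over typed entities — genes, drugs, diseases,
pathways. Shallow knowledge-graph-embedding (KGE) models are the standard
tool for predicting missing edges, yet their accuracy varies enormously
across graphs, relations and even individual triples. Much of that variance
traces back to *local* edge topology: how many neighbours the endpoints
have, and whether a triple participates in a symmetric pair, an inverse or
inference pair, or a composition triangle. kgtopo computes these per-triple
quantities, trains the four classic shallow scorers, and provides the
stratified analyses that connect the two.

A deliberate design choice, and the reason the package works at the triple
level, is that pattern membership is *not* aggregated to whole relation
types by default. A relation can be symmetric for a fraction of its triples
and not the rest; relation-level labels average away exactly the signal the
stratified analyses need. `aggregate_by_relation()` exists for comparison
with the relation-level convention, with an explicit majority threshold.

## Per-triple quantities

For a triple $(h, r, t)$ in a graph $G$:

* **head out-degree** $\deg(h) = |\{t' \mid \exists r' : (h,r',t') \in G\}|$
  and **tail in-degree** $\deg(t) = |\{h' \mid \exists r' : (h',r',t) \in
  G\}|$ — distinct-neighbour counts, not edge counts;
* **same-relation degrees** $\deg_r(h), \deg_r(t)$ restrict to relation $r$;
* **edge cardinality**: 1:1, 1:M, M:1 or M:M according to whether
  $\deg_r(h)$ and $\deg_r(t)$ equal or exceed 1 (the label is read
  tail-side:head-side, so $\deg_r(h) > 1$, $\deg_r(t) = 1$ is 1:M);
* **is symmetric**: $h \neq t$ and $(t,r,h) \in G$;
* **has inference**: $\exists r' \neq r : (h,r',t) \in G$;
* **has inverse**: $\exists r' \neq r : (t,r',h) \in G$;
* **has composition**: $\exists r_1, r_2, n \notin \{h,t\} : (h,r_1,n),
  (n,r_2,t) \in G$.

A triple can satisfy several patterns at once or none; the census therefore
reports the four pattern fractions (which may sum above 1) plus a
none-of-the-four fraction.

Two details are enforced explicitly. First, the intermediate of a
composition must differ from both endpoints, so self-loops never create
compositions. Second, $r_1$ and $r_2$ are unconstrained: they may equal $r$
and each other — only the intermediate entity is restricted.

### Implementation and verification

Symmetry, inference and inverse are resolved with keyed lookups on the
deduplicated triple set (exact integer keys; graph size is guarded so keys
stay below $2^{53}$ and remain exact doubles). Composition counts come from
the sparse boolean adjacency product $A^2$ (any-relation adjacency), with
explicit corrections for paths through $h$ or $t$. Distinct relation-pair
counts, which the matrix product cannot see, are enumerated by joining the
out-edges of $h$ with the in-edges of $t$ — the same join drives the
metapath census stratified by the intermediate's entity type.

Every detector is verified, property-style, against a brute-force
triple-loop oracle that applies the definitions literally, over hundreds of
random graphs including self-loops; further invariants (mutuality of
symmetry, inverse/inference duality under edge reversal, degree
monotonicity, invariance under id permutation) are tested separately.

### Scope of the reference graph

Censuses default to the full graph (all splits merged). When analysing test
triples, both the degrees and the counterpart flags should be computed
against the *training* graph — the information the model actually saw — and
every relevant function takes the reference graph as an explicit
`pattern_graph`/`train` argument, so both conventions are available. For
test triples classified against train, an endpoint unseen in training has
degree 0, which is kept (rather than clamped) and binned separately.

## The synthetic generator

Real biomedical KGs cannot be redistributed with a package, and their
pattern structure is uncontrolled. The generator builds graphs where the
ground truth is known by construction:

* base edges are drawn without replacement, endpoints sampled with weights
  $\propto \mathrm{rank}^{-\alpha}$ (`degree_skew`), giving the heavy-tailed
  degree profile typical of curated biomedical graphs (hub genes,
  well-studied drugs);
* per base edge, with configured rates, a symmetric counterpart, an inverse
  counterpart, an inference counterpart (both under fresh relations from a
  reserved pool — an inverse under the *same* relation would be symmetry),
  and/or a composition triangle through an intermediate are planted and
  recorded in a ledger;
* entity types are assigned in contiguous blocks with configurable
  proportions (default 50% gene, 30% drug, 20% disease).

Planting adds counterpart edges rather than rewiring, so base-edge
statistics stay interpretable. In **clean mode** the emitted graph provably
contains *only* ledgered instances: at most one pattern is planted per base
edge, base edges occupy globally distinct unordered entity pairs,
composition intermediates are fresh entities, and every insertion is
checked against accidental two-path completions, with rejection sampling
(100 retries per edge, then an error). Clean mode is what makes
"detector output equals the ledger exactly" a testable equality rather than
a high-probability event.

Defaults (500 entities, 4 base relations, 1000 base edges, skew 0.8,
planting rates 0.1) describe a mid-density multi-relational graph; tests
and the acceptance script state their own sizes explicitly.

What the generator does *not* emulate: correlated pattern placement,
schema-constrained relation endpoints beyond type blocks, and the joint
degree–pattern distribution of any real KG. Passing tests on synthetic
graphs therefore validate the machinery and the directional model laws, not
quantitative transfer to a particular biomedical graph.

### Controlled splits

`controlled_split()` assigns train/valid/test tags while forcing, for every
planted symmetric/inverse/inference pair with a member in test, the other
member either into train (`in_train`) or into test (`held_out`). Pairs are
assigned as units sampled toward the remaining per-split deficits, so the
requested fractions are respected to within two triples even when most
triples are constrained; planted composition path edges always stay in
train so triangles remain visible during training.

## Embedding models

Four shallow scorers are implemented with hand-derived gradients (scores,
higher = more plausible):

| model | score | relation parameters |
|---|---|---|
| TransE | $-\lVert e_h + e_r - e_t \rVert_p$ | one vector |
| DistMult | $\sum_i e_{h,i} e_{r,i} e_{t,i}$ | one vector |
| RotatE | $-\sum_i \lvert h_i r_i - t_i \rvert$, $h, t \in \mathbb{C}^d$, $|r_i| = 1$ | phase vector |
| TripleRE | $-\lVert e_h \circ r^{head} - e_t \circ r^{tail} + r^{mid} \rVert_p$ | three vectors |

RotatE relations are stored as phases, so the unit-modulus constraint holds
by construction after every update. DistMult's elementwise product is
grouped as $(e_h \circ e_t) \circ e_r$, which makes its score symmetry
$s(h,r,t) = s(t,r,h)$ exact in floating point, not just up to association.
These two architectural facts — DistMult scoring all relations
symmetrically, TransE being unable to (a symmetric pair forces
$e_r \approx 0$) — are the model laws the acceptance experiments probe.

Training uses uniform corruption of head and/or tail, with the
self-adversarial negative-sampling loss
$$-\log \sigma(\gamma + s^+) - \sum_j p_j \log \sigma(-s_j^- - \gamma),
\qquad p_j \propto e^{\alpha s_j^-} \text{ (not backpropagated)},$$
or a margin-ranking loss. Defaults: margin $\gamma = 6$, 64 negatives per
positive, both-side corruption, temperature 1, batch 256. Initialization is
uniform in $[-\gamma/d, \gamma/d]$ for the distance models (TripleRE's
scalers around 1), small-variance normal for DistMult, phases uniform in
$[0, 2\pi)$.

The default optimizer is Adagrad (per-parameter accumulated-gradient
scaling) rather than constant-step SGD: at the small problem sizes this
package targets, embedding rows are touched at very different frequencies
and a single global step size either stalls rare entities or destabilises
hubs. Plain SGD remains available (`optimizer = "sgd"`). The only hard
contract is reproducibility — a fixed seed yields bit-identical loss
trajectories — and an abort with a diagnostic if the loss turns
non-finite.

## Evaluation protocol

Only tail prediction is implemented; a head-prediction analysis is the same
computation on the edge-reversed graph. For each query $(h, r, ?)$ the
model scores the candidate set (all entities, or an explicit candidate
vector), scores of *other* known-true tails $(h,r,t') $ in the filter graph
are masked, and the rank of the true tail is recorded. The filter graph is
the union of all splits, the standard filtered protocol. Ties take the mean
rank among tied scores. Reported metrics are MRR and Hits@K, plus the
closed-form random baseline $\mathbb{E}[\mathrm{RR}] = \frac{1}{n}
\sum_{k=1}^{n} 1/k$ for $n$ candidates, which any trained model must beat.

**Demixing** — whether a model ranks entities of the query's correct target
type above other types — is operationalized as the fraction of queries
whose top-1 filtered prediction has the target type. This is one natural
reading of the task; finer-grained versions (e.g. type precision at deeper
cutoffs) would be easy to add but are not implemented, and reports should
flag the operationalization.

## Stratified analyses

`stratify()` computes MRR/Hits within groups defined by joint
(head-degree-bin × tail-degree-bin), cardinality class, a pattern flag, or
a counterpart flag. Degree bins default to powers of two
$\{1\}, \{2,3\}, \{4\text{–}7\}, \ldots$ — a readable geometric scale for
heavy-tailed degrees; bin edges are configurable. Because group metrics are
plain restrictions of the global metric, size-weighted group MRRs
reconstruct the global MRR to numerical precision, a property the suite
asserts at $10^{-12}$.

`pattern_effect()` reports the per-bin MRR difference between triples with
and without a flag (cells with an empty side are NA), and
`counterpart_contrast()` compares test triples whose
symmetric/inverse/inference partner was visible in training against those
whose partner was not — the leakage-like contrast that typically dominates
apparent "pattern effects".

`case_study()` implements the paired two-graph protocol: align two graphs
by exact label match, take the triples of one relation present in both,
hold out a seeded 10% as a common test set, remove it from both graphs'
edges, and evaluate both trained models against the common candidate set
(distinct tails of the shared triples). Exact label alignment is a
deliberate restriction — it fits the situation where one graph is
constructed as a superset of the other; fuzzy entity matching is out of
scope.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use: 100 random graphs of up to
200 triples for oracle equivalence; 20 clean-mode graphs (300 entities, 150
base edges, rates 0.15) for exact planted recovery; 1000 random-embedding
queries over 50 candidates for the harmonic baseline; and, for the model
laws, clean all-symmetric graphs of 2000 triples (600 entities, 1000 base
pairs) trained at dimension 64 for 30 epochs with 32 negatives, five seeds
per contrast with a one-sided sign test. All randomness flows from explicit
seeds; the acceptance script derives every sub-seed from its `--seed`
argument.

## Known limitations

* Composition detection enumerates directed 2-paths only; longer or
  undirected metapaths are out of scope.
* The KGE trainer is plain R; it is sized for graphs of $10^3$–$10^5$
  triples and modest dimensions, not for full-scale biomedical benchmarks.
* Convolutional and message-passing scorers are intentionally absent.
* No statistical machinery beyond counts, deltas and sign tests is
  provided; the stratified outputs are flat tables meant for downstream
  plotting or modelling.
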