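---
title: "Common-neighbour association discovery: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common-neighbour association discovery: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codac)
```

## The model

`codac` works on a tripartite graph: vocabularies X and Y to be associated
(in the motivating instantiation, Gene Ontology terms and protein domain
families), indirectly connected through a third vocabulary Z (protein
sequences or structure chains). Each evidence dataset contributes two
bipartite layers, X–Z and Y–Z, as unweighted edge lists. The modelling
assumption is that a genuine X–Y association manifests as *correlated
neighbourhoods*: the x and the y annotate largely the same z items. The
score of a candidate pair is the cosine of its two 0/1 neighbourhood
vectors,

$$C(x,y) \;=\; \frac{|N(x)\cap N(y)|}{\sqrt{|N(x)|\,|N(y)|}},$$

computed for all pairs at once as $U_1 U_2^\top$ from the row-normalised
biadjacency matrices. Cosine discounts promiscuous items: a z linked to
everything contributes to many numerators but inflates both degrees.
Matrices are sparse end to end (`Matrix::dgCMatrix`); only pairs with at
least one common neighbour are ever materialised, so the |X|·|Y| product
space is never allocated.

Items with zero degree score zero against everything (the normalised zero
row is kept as zeros rather than producing NaN); this is the only sensible
reading for vocabulary members that simply have no data.

## Calibration against a degree-preserving null

The decision threshold cannot be chosen on the raw score scale, which
depends on degree structure. Calibration therefore builds a gold standard:

* **Positives** — all known X–Y associations supplied by the user.
* **Negatives** — pairs that look associated *under a null that keeps every
  node exactly as busy as in the real data*. Each evidence layer is
  shuffled by random double-edge swaps, which preserve all left and right
  degrees by construction; residual overlap with the original edges is then
  removed by targeted swaps, so the shuffled graph shares no edge with the
  original. The shuffled layers are scored exactly like the real ones and
  |N| = |P| negatives are drawn uniformly from the nonzero shuffled scores
  (zero-score pairs would make the task trivial).

The overlap-clearing walk accepts any swap that does not increase the
overlap count and, with probability 0.25, overlap-increasing swaps as well;
without this escape hatch the walk can freeze in configurations where every
single swap either creates a duplicate edge or re-creates an original one.
A whole attempt restarts (up to `max_tries`) if overlap cannot be cleared.
Not every graph *has* a disjoint degree-preserving rearrangement — a
complete bipartite graph is the extreme case, and sufficiently dense or
skewed graphs fail too. Provable cases are rejected up front
(`codac_shuffle_infeasible`); exhausting the restarts is reported as its own
condition (`codac_shuffle_exhausted`). In testing against an exact max-flow
feasibility oracle, every exhaustion on random sparse graphs corresponded
to a genuinely infeasible instance.

The gold standard is split in half (training/test, ceiling convention for
odd counts, both halves preserving the P:N ratio). The threshold grid is
0.000–1.000 in steps of 0.001; a pair is predicted positive iff its score
is *strictly* greater than the threshold, and the smallest grid value
maximising training F1 wins — at equal F1 a lower threshold keeps more
recall. The same strict inequality is used in the final filter, with one
exception: pairs that are already known associations are kept at their
computed score regardless of the threshold, flagged `known`.

## Combining datasets

Per-dataset scores are combined as a true weighted average over *all*
datasets, missing scores counting as zero — a pair scored by one dataset
out of three with weight 1 each gets a third of its single score. Weights
live on the grid 1.0, 1.1, …, 10.0 and are selected to maximise the AUC of
retrieving the known positives from the complete ranked list of computed
pairs (positives that no dataset scored enter the ranking at score zero).
AUC is the Mann–Whitney statistic with ties credited 0.5.

For up to three datasets the full grid (91 per dataset) can be enumerated.
Beyond that the default is coordinate ascent: sweep one weight at a time
over the grid in dataset input order, move only on strict AUC improvement
(first grid value achieving the sweep maximum), cycle until a full sweep
changes nothing, cap 20 cycles. A single-start ascent from equal weights
measurably stalls in local maxima of the jagged, piecewise-constant AUC
landscape (observed gaps up to ~1e-3 on a few percent of simulated
two-dataset problems), so the ascent is restarted from a deterministic set
of starting points — all-equal weights plus one dataset-dominant start
(that weight 10, the rest 1) per dataset — and the best final AUC wins. On
two-dataset problems this multi-start ascent reproduced the exhaustive-grid
optimum in 60/60 simulated instances while costing only (d+1) sweeps.
Because the all-equal start is included, the result can never fall below
the equal-weights AUC. Note the AUC objective is invariant to rescaling all
weights, so reported weight vectors are unique only up to scale on their
grid.

## Significance and quality classes

Each kept edge receives, per dataset, the upper tail of the hypergeometric
distribution of its common-neighbour count K given the dataset's Z universe
size and the two degrees — computed through `stats::phyper`'s survival
form, which is stable up to Z universes of 10^7. The Z universe of a
dataset is the set of distinct Z items observed in its (clustered) edges:
edge lists cannot carry isolated vertices, so this definition makes
file-based and in-memory runs identical. A dataset is considered to *have
data* for a pair when both endpoints have at least one neighbour in it;
otherwise its p-value is recorded as absent and excluded from the class
denominator (an absent dataset says nothing, which is different from a
dataset that looked and found K = 0, where p = 1).

Significance is strict: p < 0.05/|kept edges|, the Bonferroni family-wise
level over the edges actually tested (counted after score filtering,
before any most-specific reduction; the count and level are logged in the
run manifest). Classes: **Gold** — all present p-values significant;
**Silver** — more than half (exactly half is not more than half);
**Bronze** — the rest.

## Ontology handling

When X is an ontology, only `is_a` links are honoured; `part_of` and other
OBO relationship types are ignored — the conservative reading for GO-style
annotation inheritance. Loading verifies acyclicity (Kahn's algorithm)
before any query runs, and obsolete terms are dropped with a count. An
optional pre-scoring propagation step adds, for every edge (x, z), edges
from z to every ancestor of x *already present in the graph's vocabulary*
(no new terms are invented); the operation is monotone and idempotent.
Post-prediction, `most_specific_filter` reduces an association set to the
per-y antichain of terms none of whose descendants is also associated with
that y — the unit in which association totals are conventionally counted.
Both orders (propagate-then-predict and predict-then-filter) are exposed,
since either may be wanted depending on whether the evidence or the
conclusions should inherit.

## The synthetic generator

`synthetic_spec()` / `generate_tripartite()` emulate the statistical
structure the method assumes: each planted (x, y) pair owns a block of Z
items that link to both endpoints independently with probability `signal`
(per dataset, scaled by `dataset_quality`), every possible edge additionally
appears with probability `noise`, a fraction of Z items have duplicate
copies whose edges are re-drawn from the same probabilities (grouped by the
emitted cluster map, so clustering genuinely merges complementary
observations), and an artificial rooted DAG places every x as a leaf under
a small internal hierarchy, with occasional double parents to create
diamonds. Planted pairs form a matching where vocabulary sizes allow, so in
the noiseless limit each planted pair scores exactly 1; endpoints are
reused only when more pairs are requested than a side has items.

The defaults — 50 x 50 vocabularies, 500 Z items, 60 planted pairs, signal
0.8, noise 0.01, three equal-quality datasets, 10% Z redundancy, half of
the planted pairs declared known — are the package's reference study
conditions, used by the test suite and the acceptance script. They were
chosen once as a desk-scale regime that reproduces the qualitative features
of real annotation data (sparse layers, ~10 neighbours per item, consensus
AUC in the mid-0.9s, small calibrated thresholds) while keeping every run
in seconds on one CPU.

What the generator does *not* emulate: realistic GO term-frequency
distributions, domain-architecture correlations, multi-function domains
sharing blocks (available via `block_overlap`, off by default), or
evidence-code heterogeneity. Passing tests on synthetic data therefore
demonstrate correctness of the machinery and recoverability under the
stated noise model, not performance on any particular biological corpus.

## What counts as a recovered association

At the reference conditions the gold standard is small (|P| = |N| = 30),
so the calibrated threshold — placed just above the highest-scoring
shuffled negative — admits a tail of weak score-only pairs from the noise
process (scores ~0.08–0.15, versus ~0.24–0.54 for planted pairs). This is
exactly the situation the quality classes exist for: those noise survivors
obtain no per-dataset statistical support and land in Bronze, while planted
pairs are Gold or Silver. `evaluate_recovery()` therefore counts Gold and
Silver novel predictions as recovered by default (Bronze can be included
explicitly). With that definition the reference run at seed 7 recovers the
held-out planted pairs with precision 1.0, recall 0.9, F1 0.947.

## Numerical and degenerate-input conventions

* Cosine entries are clamped to 1 from above (floating products of
  normalised rows can exceed 1 by ~1e-16 for identical neighbourhoods).
* Identifier comparison is exact, case-sensitive string equality;
  whitespace is trimmed at file I/O only.
* Vocabularies sort lexicographically unless an explicit order is given, so
  matrix layouts (and therefore output files) are reproducible across runs.
* All randomised steps (shuffles, negative sampling, splitting, the
  generator) take explicit seeds; the pipeline derives stage seeds from one
  master seed by fixed offsets, and identical configurations with the same
  seed produce byte-identical outputs.
* Degenerate calibrations are surfaced, not patched: an empty positive set,
  a training half without positives, or fewer eligible shuffled pairs than
  required negatives are errors (`codac_degenerate_calibration`); positives
  all scoring zero yields a warning and a zero F-measure.

## Known limitations

* The weight search optimises a step function on a lattice; ties are
  resolved by documented first-maximum rules rather than any preference for
  interior solutions, and the multi-start ascent, while empirically exact
  on two-dataset problems, carries no global-optimality guarantee for many
  datasets.
* Edge-shuffling feasibility is only pre-checked for provable patterns;
  for dense inputs the distinction between "infeasible" and "not found in
  `max_tries` restarts" is reported but not decided exactly.
* Clustering consumes a precomputed identity map; computing sequence
  clusters is out of scope.
* The single train/test split follows the calibration design it
  implements; no cross-validation is provided.
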