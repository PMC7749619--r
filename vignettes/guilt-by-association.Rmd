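---
title: "Guilt-by-association gene prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association gene prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbanet)
```

`gbanet` turns a common but usually web-service-bound analysis — picking
follow-up candidates from a differential-expression screen by their
association with known phenotype biology — into a local, deterministic,
testable pipeline. This vignette is the package's own account of the models
it implements, the parameters that matter, what the synthetic benchmark
does and does not show, and the places where the design was genuinely open.

## The statistical model, stage by stage

### Trained list: propagation scoring

The reference ("trained") gene set is not taken from a fixed database but
built from the network itself. Keywords are matched case-insensitively as
literal substrings against annotation-term ids and labels; every gene
annotated to a matching term and present in the interaction network is a
seed. Substring matching (no stemming, no tokenization) was chosen because
it is reproducible and auditable, and because phenotype keyword lists in
practice contain multiword phrases ("long-term potentiation") that literal
matching handles naturally.

Propagation then scores every node. Seeds start at score 1, everything else
at 0. One *repetition* consists of `iterations` synchronous rounds in which
each node receives the mean of its neighbors' previous-round values; at the
end of the repetition each node's stored score becomes

```
score <- max(score, decay * max over rounds of received value)
```

with `decay = 0.5`, and after `repetitions` repetitions scores are divided
by their maximum. The scheme is deliberately simple: it is topology-global
(hubs integrate many paths), seed-dominated (a non-seed can never exceed
`decay`), bounded in [0, 1], and completely deterministic. One detail is
worth flagging: the repetition merges the *running maximum* over the
propagation rounds rather than the final round's value only. With
synchronous mean-of-neighbors updates, a node at odd distance from all mass
receives zero on even rounds (and vice versa); merging only the last round
would make scores depend on path-length parity and would let a node
directly attached to a seed keep a zero score with an even iteration count.
The running maximum removes the parity artifact and makes the score
strictly monotone in connectivity to scored nodes, which the test suite
asserts as an invariant.

Defaults `repetitions = 3, iterations = 2` keep influence local (roughly a
six-edge horizon with geometric damping) while letting later repetitions
re-propagate the scores accumulated by earlier ones. The trained list keeps
genes with score strictly `> 0.1`, the conventional cutoff for this kind of
propagation score; ordering is by descending score with a lexicographic
tie-break so output files are reproducible byte for byte.

### Prioritization: annotation similarity with sampling nulls

Candidates are DEG records with `|FC| > 1.3` (strict; the sign is kept, and
1.3 corresponds to a 30 % expression difference — a conventional
biological-relevance floor for two-group screens). Each candidate is scored
against the trained list once per annotation category:

* **Set-valued categories** (GO domains, pathways, phenotypes, diseases,
  literature): pairwise similarity is the Jaccard index of the two genes'
  term sets; the gene-level score is the mean of the `k` largest pairwise
  similarities over the trained genes, with `k = |trained list|` by default
  — i.e. a plain mean, with unannotated trained genes contributing 0. The
  top-`k` form is exposed because the proprietary fuzzy aggregation used by
  popular web tools is not published; the mean is the transparent,
  auditable special case.
* **Vector-valued category** (coexpression): Pearson correlation of the two
  genes' profiles mapped to [0, 1] via `(r + 1) / 2`.

A candidate with no annotation in a category scores 0 there and the
category is *uninformative* for it — it is excluded from the meta-analysis
rather than counted as evidence of dissimilarity.

Null distributions are built by sampling `n_samples = 5000` genes uniformly
**with replacement** from the genome and scoring them identically; the
p-value is the add-one estimator `(1 + #{null ≥ obs})/(n_samples + 1)`.
With replacement keeps draws i.i.d.; the add-one estimator is slightly
conservative but can never return 0, which matters because Fisher's method
(`−2 Σ ln p` against χ² with `2m` degrees of freedom, `m` = informative
categories) would degenerate at `p = 0`. The null depends only on the
category, trained list and universe — not on the candidate — so one shared
null per category serves all candidates, which is also what makes the
result invariant to candidate input order.

Selection applies Benjamini–Hochberg across candidates at FDR 5 % *and* a
combined-p cutoff of `10⁻³`. The cutoff is configurable; `10⁻³` is the
literal value of the conventional "10e-4" notation used in this
literature, and is consistent with published prioritized tables whose
largest printed p-value is ≈ 2.3 × 10⁻⁴. Candidates that are themselves
members of the trained list are auto-included regardless of their p-values:
they are known phenotype genes observed as differentially expressed, which
is the strongest association the framework recognizes.

### Enrichment and the up/down z-score

Over-representation uses the upper-tail hypergeometric probability of an
overlap at least as large as observed; terms with zero overlap are not
tested. BH adjustment is applied **within each category** (GO domains,
pathways, …), matching how per-category results are conventionally
reported; a term is enriched at `p < 0.05` and `q ≤ 0.05`. The background
defaults to all genes annotated in the category and is configurable — in
pipeline runs it is the full gene universe, which is the more conservative
choice when gene lists contain sparsely annotated members.

The regulation profile of a term (or of a whole tissue list) is
`z = (up − down)/√count`. The √count denominator follows the circle-plot
convention this statistic comes from; because the formula is printed
ambiguously in parts of the literature, `(up − down)/count` is available
behind `z_denominator = "count"`. The sign pattern, not the magnitude, is
the scientifically interpretable part.

### Functional clustering

Prioritized genes are embedded from a binary gene × term incidence matrix
over the enriched terms. Hamming distance counts differing terms;
all-zero *columns* are dropped (a term annotating none of the listed genes
carries no information) but all-zero *rows* are kept (an unannotated gene
has a well-defined distance to everything). Two Euclidean readings of
"distances derived from the Hamming matrix" are implemented:

* `hamming-rows` (default): Euclidean distance between rows of the Hamming
  matrix — the literal derivation of a second distance from the first;
* `incidence-sqrt`: `√Hamming`, which is exactly the Euclidean distance
  between the binary incidence rows and a true metric (it satisfies the
  triangle inequality; the suite checks this exhaustively on small random
  matrices).

Both are exposed because the literature describing this construction is
ambiguous; results in practice differ only in scale, not in cluster
structure. Embedding uses classical (Torgerson) MDS — not stress-minimizing
SMACOF — because the per-component *variance explained* is wanted, and that
quantity is defined by the eigen-spectrum: component *i* explains
`λᵢ / Σ(positive λ)`. Negative eigenvalues (possible for non-Euclidean
input) are excluded from coordinates and denominator. Axes are sign-
canonicalized (first nonzero loading positive) so repeated runs produce
identical files.

### TF-target centrality

ChIP-derived TF→target edges are filtered at peak intensity `< 500` and
regulatory potential `< 1` (both strict, as these thresholds are
conventionally quoted); duplicate (TF, target) pairs keep the lowest
regulatory potential. The network is the undirected simple graph of
filtered edges onto prioritized targets, with isolated prioritized genes
retained. Degree counts all incident edges (TF–TF edges included, since
published tables report a single degree per node) and betweenness is
unnormalized Brandes betweenness — published magnitudes indicate raw
pair counts rather than normalized fractions. TF ranking is by degree,
then betweenness, then name; the tie-break hierarchy is stated explicitly
because none is conventional.

## The synthetic world

`generate_world()` emulates the full input bundle with a planted truth:

* **Network**: preferential-attachment backbone (`igraph::sample_pa`,
  3 edges/node) with vertex labels randomly permuted, plus extra
  module-internal edges with probability `0.08 · signal` per pair. PPI
  degree distributions are heavy-tailed and propagation behavior depends on
  hubs, hence the scale-free backbone; at `signal = 0` module genes are
  indistinguishable from background (asserted by a two-sample degree test).
* **Corpus**: per category, "signal" terms drawing each member from the
  module with probability `signal` (uniform genome draws otherwise) plus
  uniform background terms; a phenotype category carries the free-text
  labels that `keyword_annotations()` makes keyword-matchable.
* **DEG tables**: gene sampling weights `1 + 9·signal` for module genes;
  fold-change magnitudes `1.3 · exp(Exp(3))` for the configured passing
  fraction (default 0.92, the pass rate of the motivating two-tissue
  screen, whose DEG-table sizes — 12 % and 6.5 % of the genome — also set
  the default table sizes) and `U(1.01, 1.3)` otherwise; Rademacher signs
  with `P(+) = up_bias` in one tissue and `1 − up_bias` in the other, so
  the tissue z-scores have opposite constructed signs whenever
  `up_bias > 0.5`.
* **TF edges**: one planted hub TF with many filter-passing edges to DEG
  genes among background TFs with mixed filter status.

A single integer seed drives everything (bit-identical worlds per seed),
and `write_world()` records it in a header comment of every file. What the
generator does **not** emulate: probe-level microarray effects, annotation
redundancy along the GO graph, correlated evidence across categories
(categories are generated independently, making Fisher's independence
assumption exactly true — real annotation sources are correlated and the
combined p-values there are anti-conservative), and literature bias. A
passing benchmark therefore demonstrates correctness of the machinery and
calibration under the stated model, not performance on any particular real
annotation corpus.

## Numerical choices and degenerate inputs

* p-values never reach 0 (add-one estimator; combined p floored at the
  smallest positive double); Fisher combination refuses `p ≤ 0`.
* Thresholds quoted from conventions (`> 1.3`, `> 0.1`, `< 500`, `< 1`)
  are strict inequalities throughout, and boundary cases are unit-tested.
* Isolated nodes propagate nothing and score exactly 0 (mean over an empty
  neighborhood is defined as 0).
* Duplicate gene symbols are resolved on a case-folded key (mouse
  title-case and human upper-case symbols unify); output preserves the
  first-seen original casing.
* Numeric parsing accepts decimal commas and typographic minus signs
  (U+2212, U+2010, U+2013), as found in published supplementary tables;
  unparseable rows are rejected with their row indices reported.
* MDS of degenerate configurations (collinear points, duplicated rows)
  pads missing components with zeros rather than failing.
* Tie-breaks are lexicographic everywhere a ranking is emitted.

## Problem sizes used by the test suite

The suite validates statistical behavior at sizes chosen to make sampling
error negligible relative to the tested margins while keeping a full run in
tens of seconds: planted-truth recovery on a 2,000-gene world with a
50-gene module at signal 0.9 (trained-list enrichment ≥ 5× base rate,
prioritization AUROC ≥ 0.9); calibration on null worlds of 400 genes
(200 test genes × 500 null draws, Kolmogorov–Smirnov) and 20 independent
150-gene null worlds for the FDR bound; oracle equivalences on exhaustive
small instances (hypergeometric backgrounds ≤ 30 genes, 8-node betweenness
graphs, ≤ 8 × 8 incidence matrices).

## Known limitations

* The propagation score is a package-defined contract chosen to preserve
  the qualitative behavior of topology-global seed scoring; absolute scores
  are not comparable across networks of very different density, only the
  thresholded membership is intended for downstream use.
* Fisher's method assumes independent evidence across categories; real
  annotation sources overlap heavily. Treat combined p-values as a ranking
  device (as the selection rule does, jointly with FDR control), not as
  literal tail probabilities.
* Keyword seeding is a deliberately biased step — it encodes prior biology.
  Different keyword lists give different trained lists; the package makes
  the mapping auditable (`select_seeds()` records per-gene keyword
  provenance) rather than pretending neutrality.
* The GO graph is not used: terms are independent gene sets, so no
  redundancy reduction across ancestor/descendant terms is performed.
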