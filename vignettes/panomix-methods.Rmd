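---
title: "Methods: multi-omics mapping, topological ranking and cross-pathway scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics mapping, topological ranking and cross-pathway scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panomix)
```

## The model

`panomix` treats the cell as a multi-layer meta-interactome: one
protein/gene node per gene symbol (users must pre-map accessions),
miRNA nodes, and metabolite nodes, joined by four edge kinds —
undirected protein–protein interactions, directed miRNA→target and
TF→target regulation, and enzyme–metabolite incidence. PPI edges come
from STRING-style links files filtered on the `experimental` evidence
channel at a minimum score of 700, the conventional medium-confidence
cut for experimentally supported interactions; `combined_score` is
available behind an explicit flag. Merging layers is a typed set union:
edges are deduplicated per (source, target, kind), PPI edges stored
with canonical endpoint order, self-edges always dropped. Simple-graph
semantics are assumed throughout because the clustering coefficient and
the local entropy below are defined on simple graphs.

## Omics harmonization

Quantitative layers (mRNA, miRNA, proteomics — the *primary* layers)
carry (id, logFC, adjusted p). Within each uploaded layer the logFC
vector is rescaled by its own maximum absolute value to [−1, +1]; the
normalizing maximum is taken over the uploaded file only, not over the
network, so each dataset is comparable on its own scale. A record is
called up (down) when `logFC ≥ logfc_up` (`≤ logfc_down`) **and**
`p ≤ p_max`; both comparisons are inclusive, which is the natural
reading of "threshold" and is what the boundary tests pin down.
Defaults are ±1 and 0.05, the field's customary cutoffs.

Per node, the combined score sums the normalized logFC of the
threshold-passing records across primary layers. The sign of a non-zero
sum gives the up/down status; exact cancellation (tolerance 1e-12)
yields *expressed*. Two open choices were resolved as follows and are
deliberate package semantics:

* only threshold-passing records contribute to the sum (the
  alternative — summing all records — would let two sub-threshold
  layers manufacture a deregulation call);
* nodes absent from every primary layer are excluded from all
  downstream analysis even if mutated/methylated/phosphorylated,
  *except* in alteration-only runs (no primary layer supplied), where
  altered identifiers enter the table with status `altered` and seed
  the extraction. This keeps genomics-only analyses possible while
  preserving the rule that primary data decides deregulation.

Alteration layers never override a primary call; they only add
per-layer flags.

## Filtered network and candidate set

Extraction seeds the parent graph with every up/down/altered node and
keeps nodes within `level` (1 or 2) hops, traversing regulatory edges
in both directions so a deregulated target pulls in its regulators.
The retained subgraph is the *induced* one: edges between two retained
non-seed nodes are kept. Topological ranking is then restricted to the
candidate set — omics-covered, non-metabolite nodes (altered nodes in
alteration-only runs; seeded enzymes in metabolite-driven runs) — so
that z-scores are standardized over nodes the data actually speaks
about.

## Topology indices and TIN selection

Degree, betweenness, closeness and local clustering are computed on the
undirected simple projection of the filtered network. Betweenness is
normalized by (N−1)(N−2)/2; closeness uses the component-scaled form
(r/Σd)·(r/(N−1)) so that values remain comparable in disconnected
networks; isolated and degree-one nodes get closeness/clustering 0.
Every index is max-normalized (x/x_max) and converted to z-scores with
the sample SD (ddof = 1; the estimator is a package choice). Because
z-scores are affine-invariant, thresholding z of the normalized index
is identical to thresholding z of the raw index — the suite checks both
paths agree to 1e-9.

Hubs exceed the z-degree threshold (strict >, per "greater than the
threshold"), bottlenecks the z-betweenness threshold, and central nodes
the z-threshold on the cumulative centrality score. The CCS sums the
combined score c = norm(betweenness) + norm(closeness) +
norm(clustering) over a node's first-layer interactors *including the
node's own term*; including the self term keeps isolated candidates
rankable and is flagged here as a deliberate resolution of an ambiguous
definition. Components whose index is identically zero across the
network (e.g. betweenness on a clique) contribute zeros to c rather
than failing normalization. Nodes in at least two TIN categories are
IINs. The interactive choose-threshold-from-the-PDF step of a server
workflow becomes a two-pass flow here: `pdf_plot_data()` /
`autoplot()` expose the z-score density table, and all selection
functions default to z = 1 for non-interactive use.

## Enrichment

The contingency counts are a (overlap drawn from the query list),
b (query size, counting genes outside the pathway universe too),
c (pathway size) and d (universe = exact union of all member sets). Two
statistics are implemented and never conflated: the single-table point
probability C(b,a)·C(d,c)/C(b+d,a+c), evaluated in log space, and the
standard upper-tail over-representation p under the hypergeometric law
(population d, successes c, draws b). The tail form is the default
because the procedure is described as a Fisher-exact test; the point
form is what the printed formula states, so it stays selectable.
Selection uses raw p ≤ 0.05 (inclusive) to stay faithful to the
published workflow; Benjamini–Hochberg adjustment is available behind
`adjust = TRUE`, off by default. Prognostic-marker annotation reports,
per gene, the cancer type with the minimum Kaplan–Meier p-value.

## Cross-pathway path scoring

Candidate paths X→M run from signaling proteins (mode 1) or from
targets of deregulated TFs/miRNAs (modes 2–3, regulator recorded as a
prefix and required to stay off its own path) to metabolic enzymes,
through at most three PPI intermediates — the XM/XPM/XPPM/XPPPM
grammar. Enumeration is exhaustive up to that bound and ordered
lexicographically, so runs are deterministic. The filter keeps a path
when both terminals are deregulated and every interior node is at least
expressed; "terminal" in the regulatory modes means the regulator
(judged by its own omics layer) and M, with X interior.

Scoring pins a concrete log-likelihood contract on the HMM-style
ingredients (the cited prior model is not re-derived here; this
contract is the package's documented gap-fill):

* expression score s(v) = 1 + |combined_score(v)| ∈ [1, 1+k];
* transition probability of step u→v: s(u)s(v) normalized over all
  eligible network neighbours of u *of the step's edge kind*
  (regulatory targets for the regulator hop, PPI partners otherwise),
  eligible meaning covered by primary omics — so per-source
  probabilities form a true distribution;
* emission e(v) = (1 + w(v) + H(v)/H_max) / (2 + k), where w(v) counts
  the satisfied weight options (at most four of six: deregulated,
  crosstalk, rate-limiting, hub, CN, bottleneck), k = number of
  selected options, and the local-entropy term H(v) (Shannon entropy of
  the normalized neighbourhood weight distribution, H ≤ log degree) is
  included only when the entropy flag is on — entropy is a separate
  weight family, not one of the six predicates. The +1/(2+k) smoothing
  keeps emissions in (0, 1) and scores finite;
* path score = Σ log(transition) + Σ log(emission), z-scored over all
  filtered paths of the run; importance is inclusive z ≥ 1.

Raising an interior node's weight can only raise its paths' scores
(emission is monotone in w), which the property tests assert. The
two-stage X–M *pair* scoring mentioned alongside the path scoring in
the source workflow is not defined there; this package scores paths
globally and leaves pair-level aggregation out of scope.

## Synthetic study generator

The generator is first-class, tested code and defines the study
conditions used everywhere: 200 proteins in an Erdős–Rényi PPI layer
with mean degree 4 (a Barabási–Albert option exists for scale-free
degree structure), 20 miRNAs and 10 TFs each wired to random target
sets, 30 metabolites attached to metabolic enzymes, 15% signaling and
15% metabolic proteins (independent draws, overlap allowed), 20%
planted-deregulated nodes with logFC ~ Normal(±2, 0.3) and significant
p-values against an expressed background, sub-threshold decoy PPI edges
to exercise the score filter, and one planted cancer pathway drawing
15 of its members from the planted-deregulated genes. These sizes keep
a full pipeline run in seconds while leaving path enumeration
non-trivial. All draws derive from one integer seed, and generated
files are read back through the package's own parsers, so every fixture
validates every reader.

What the generator does **not** emulate: real human interactome degree
distributions beyond the scale-free option, correlated noise between
omics layers, batch structure, identifier mapping problems, or
database-version effects. Passing tests therefore demonstrate the
correctness of the algorithms under controlled conditions, not recovery
performance on real cohort data.

## Numerical choices and degenerate inputs

Hypergeometric terms are computed via `lchoose` sums in log space and
match exact integer-coefficient arithmetic to 1e-12 on exhaustive small
sweeps. Zero-sum combined scores use a 1e-12 tolerance. Degenerate
situations fail loudly rather than silently: all-zero logFC vectors,
all-zero index vectors, zero-SD z-score inputs, empty seed or candidate
sets, and identical path scores all raise classed errors. Ties in path
ordering break lexicographically; merging is order-independent; no
module except the generator uses randomness, and generator runs restore
the caller's RNG state.

## Problem sizes used by the checks

The test suite verifies centralities against an exhaustive
simple-path-enumeration oracle on every connected labeled graph with up
to 5 nodes plus seeded random 6–7-node graphs; path enumeration against
brute-force DFS on 200 seeded random graphs of up to 8 protein nodes;
hypergeometric values exhaustively for b + d ≤ 14 (point) and d ≤ 12
(tail); planted-pathway recovery across 100 seeded replicates of the
default study; and byte-identical reruns of the full pipeline. These
sizes were chosen so each property is checked exhaustively where
exhaustiveness is affordable and by seeded sampling where the space is
astronomically large.

## Known limitations

Identifier namespaces are the caller's responsibility (one node per
gene symbol). Eigenvector-style centralities are deliberately absent.
Enrichment treats pathways as flat sets (no ontology traversal).
Metabolomics input is an identifier list; metabolite abundances are not
modeled. The path-score contract, while fully specified and tested
here, is one concrete realization of an HMM-style scoring scheme whose
published description leaves the details to prior work.
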