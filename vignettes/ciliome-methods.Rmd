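---
title: "Seed-centric PPI interactomes: models, statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-centric PPI interactomes: models, statistics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliome)
```

## The model

`ciliome` works with *seed-centric interactomes*: undirected protein–protein
interaction (PPI) graphs anchored on a curated seed gene set (here, cilia
genes — intraflagellar transport, BBSome, transition zone, ciliary membrane
and motile cilia proteins), where every edge touches at least one seed. Edges
carry a binary provenance: **known** (reported in curated databases such as
HPRD or BioGRID) or **novel** (computationally predicted and consumed as
input — the package does not predict interactions itself). Non-seed nodes
inherit a role from their incident edges: a *known interactor* has at least
one curated edge, a *novel interactor* is connected exclusively through
predictions. This role partition drives every downstream stratification:
which disease-network overlaps are attributable to predictions, and which
drugs reach the network only through predicted interactors.

Three modelling conventions are worth making explicit:

* **Known precedence.** A gene pair present in both the known and the novel
  input is stored once, as known: a prediction of an already-curated pair is
  a confirmation, not a new edge. This keeps edge counts honest and makes
  assembly order-independent.
* **Symbols are identity.** Gene identity is the normalized (uppercased,
  whitespace-free) symbol string. No alias resolution or identifier mapping
  is attempted; harmonizing inputs to one symbol space is the caller's
  responsibility, and is deliberately out of scope.
* **Seed–seed edges** are allowed and contribute to the per-seed counts of
  *both* endpoints, while distinct-edge totals are reported separately. This
  is why a per-seed count table can sum to slightly more than the number of
  distinct edges in the graph.

Self-loops are rejected by default (the usual PPI convention); an explicit
flag admits homodimers.

## Over-representation statistics

All overlap significance in the package reduces to one kernel: the
hypergeometric upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$,
with $N$ the background size, $K$ and $n$ the two set sizes and $k$ the
observed overlap. It is computed with `stats::phyper`, and the test suite
pins it against an independent combinatorial-counting oracle (and, at tiny
sizes, literal subset enumeration). Multiple testing across an annotation
collection uses the Benjamini–Hochberg step-up (`stats::p.adjust`), adjusted
over *all* tested terms, with results sorted by adjusted p, then raw p, then
term id so that output order is deterministic under ties.

Choices a user should know about:

* The test is one-sided (over-representation only), the default of the
  neighborhood-enrichment tools this module emulates.
* The default significance level is adjusted p < 0.05, configurable.
* The background defaults to the annotation universe (union of annotated
  genes); for interactome-versus-interactome overlaps it is an explicit
  universe *size*, defaulting to 20,000 — approximately the number of human
  protein-coding genes. The choice of background materially changes the
  p-values and is surfaced as a parameter everywhere.
* Query or category genes missing from the background are dropped with a
  warning, not an error: real annotation tables are incomplete.
* Annotations are used exactly as given; there is no ontology-graph
  propagation of terms to ancestors. Enrichment results on sparse, leaf-level
  annotations are therefore conservative relative to tools that propagate.

Neighborhood enrichment queries a seed's interacting partners — known and
novel together, the seed itself excluded — so that significant terms can be
read as network-supported functional assignments for seeds with little
direct annotation.

## Expression filters and direction concordance

Differential expression uses the conventional thresholds: linear fold change
above 2 (or below 1/2) at p < 0.05, with *strict* inequalities on both
(a gene at exactly 2.0 or exactly p = 0.05 is excluded); abundance filtering
declares a gene expressed at TPM ≥ 2 (*inclusive*) in at least one provided
tissue context, i.e. per-context thresholding followed by a union. Fold
changes are linear ratios; a flag converts log2 input.

The disease-versus-development concordance analysis classifies each gene by
the direction of two fold changes — disease case/control and old/young
developmental — into four categories: opposite in either orientation, same
direction, or unclassified when a direction is flat. The flat band defaults
to zero width (every non-unit fold change has a direction), because the
upstream filter already restricts attention to strongly differential genes;
a configurable log2 band is available for noisy data. The developmental
ratio is taken between exactly two labelled time points rather than fitted
as a trend, matching how such comparisons are reported; genes with zero
young-timepoint abundance are excluded with a warning rather than given an
infinite ratio.

## Graph distances and the random-set null

Average shortest path is the mean breadth-first distance over distinct
unordered pairs spanning two gene sets, excluding same-gene pairs.
Unreachable pairs are *excluded from the mean and counted* — the
least-assumption treatment — with an optional imputation constant for
sensitivity analysis. Distances come from `igraph::distances`; the suite
checks them against an independent Floyd–Warshall oracle.

The empirical null samples uniform gene sets (without replacement within a
draw) from a caller-supplied background list. Two modes are provided because
they answer different questions: within-set (is this set more tightly
interconnected than random?) and between-set (is this set closer to a fixed
reference set than random?). In both, the observed statistic and the null
statistics are exchangeable when the observed set is itself a uniform draw,
which is what makes the empirical p-value calibrated — the suite verifies
uniformity over 500 seeded replicates. The p-value uses the add-one
pseudocount $(r+1)/(m+1)$, so it is never exactly zero; draws that miss the
network entirely are dropped from both numerator and denominator. All
randomness is governed by an explicit seed and the caller's RNG stream is
saved and restored.

## Drug stratification

Drugs map into a network through their target genes; a drug counts when at
least one target is a node. The stratum of a drug considers *all* its
in-network targets: `known_only` when every target is a seed or known
interactor (seeds are established genes, so they count toward the known
stratum), `novel_only` when every target is a novel interactor, `both`
otherwise. ATC tabulation takes the first letter of each code (the level-1
anatomical category); a drug with several codes counts once per *distinct*
category, and drugs with no code land in an `unclassified` bin. Within a
category the three strata sum to the category's distinct-drug count by
construction. Indication filtering is case-insensitive exact label matching;
mapping indication vocabularies onto an ontology is out of scope.

## What the synthetic generators emulate — and what they do not

The generators produce every input shape the pipeline consumes, with planted
ground truth recorded alongside, so each analysis stage has a
recoverable-signal test. They are pure functions of a `synthetic_spec`:
identical specs give identical outputs, byte for byte.

The defaults are chosen to match the study conditions the package was built
around: a 20,000-gene universe; 165 seed genes; mean per-seed degrees of 6.1
known and 4.6 novel interactions (the ratios of roughly a thousand known and
three-quarters of a thousand novel edges over 165 seeds); 34% of seeds with
no known interaction at all (zero-truncating the Poisson draw for the
remaining seeds); an overlap geometry of 400- and 1,600-node networks
sharing 90 genes over the 20,000-gene background; 5% planted over- and
under-expressed genes with fold changes in [2.5, 8] (and mirrored below 1)
at p < 0.01, against null genes held inside (0.7, 1.4) so that threshold
boundaries are tested deterministically rather than stochastically; 37% of
differential genes moving developmentally in the same direction as in
disease; and an ATC mixture dominated by nervous-system drugs.

Degree structure is Poisson around a mean. Real PPI networks are
heavy-tailed, modular and ascertainment-biased (well-studied genes have more
curated edges); planted annotation terms are internally exchangeable rather
than hierarchically correlated like real ontology terms; synthetic gene
names (`G00001`, …) are systematic to avoid colliding with real symbols.
Passing the recovery tests therefore demonstrates *correctness of the
bookkeeping and statistics* — exact per-seed counts, exact planted-set
recovery, calibrated nulls — not robustness to the topology or annotation
correlation of real human data.

## The packaged cilia table

`cilia_table1()` loads a transcription of a published table listing, for
each of 165 cilia genes, its number of curated PPIs, its number of predicted
novel PPIs, and the novel partner symbols. Transcription notes:

* The partner-list length is authoritative: `n_novel` is recomputed from the
  list on load, and disagreements are warned about.
* One partner symbol, `42435` under ROPN1L, is a spreadsheet-corrupted token
  in the source table; it is retained verbatim and flagged by the reader.
* The source text runs the table together without delimiters; it was
  re-segmented against the ordered seed list. One segmentation was genuinely
  ambiguous (`DNAJB1…` versus `DNAJB12…`); it was resolved to DNAJB1 with 28
  known PPIs because the alternative makes the per-seed known counts sum to
  fewer than the total number of distinct known PPIs the same publication
  reports, which is impossible, while the chosen reading reconciles exactly
  (one seed–seed known edge counted twice).
* The transcription's aggregate counts differ slightly from the summary
  sentences printed alongside the source table (for example, one novel
  interactor named in the source's prose appears nowhere in its table as
  extracted). The fixture ships the table as transcribed rather than
  adjusted toward the prose; the test suite records the divergence
  explicitly.

## Numerical and interface choices

* Tie-breaks: enrichment output is ordered by adjusted p, raw p, term id;
  edges are stored with endpoints sorted lexicographically and tables sorted
  by endpoint, making every result reproducible and diff-able.
* Degenerate inputs fail loudly: empty seed sets, empty backgrounds,
  distance queries with no usable pair, and out-of-range p-values are
  errors; recoverable irregularities (genes missing from a background or a
  network, records with non-positive fold change) are warnings with counts.
* Strict assembly is the default; lenient assembly drops seedless edges and
  reports how many.
* File formats are plain text: an edge TSV and a SIF dialect, both carrying
  a `# seeds:` header comment so that isolated seeds survive round trips,
  and GraphML (via igraph) with `role` node attributes and `provenance`
  edge attributes. Round-trip identity is property-tested.
* The package's interface is its functions, this vignette and
  `scripts/acceptance.R`; no shell entry point is shipped, since every
  pipeline step is a short, composable R call.
* Problem sizes in the shipped tests and acceptance script (a full 20,000
  gene universe for the end-to-end run; a few-hundred-node graph with 200
  replicates of 99 draws for null calibration) were chosen so the whole
  suite completes in about a minute while still exercising study-scale
  inputs.

## Known limitations

* No identifier mapping: symbol mismatches between inputs silently shrink
  overlaps (by design, with warnings where a background is declared).
* No GO-graph propagation, no gene-permutation (GSEA-style) statistics, no
  pathway-tool emulation beyond generic collection enrichment.
* Overlap p-values depend on an assumed background size; reports carry the
  size and test family used so that this assumption is visible.
* The PPI prediction step itself is out of scope; predicted edges are
  inputs with a provenance tag, nothing more.
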