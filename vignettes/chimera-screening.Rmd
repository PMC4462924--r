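---
title: "Reference-based chimera screening of fungal ITS sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based chimera screening of fungal ITS sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refchimera)
library(dplyr)
```

## The problem

PCR amplification of mixed DNA templates routinely produces *chimeras*:
artifact sequences whose two halves descend from different parent
molecules. In the fungal barcoding marker — the nuclear ribosomal
internal transcribed spacer region, ITS1–5.8S–ITS2, about 550 bp on
average — the highly conserved 5.8S gene acts as a natural bridge point
for template switching, so chimera control is a prerequisite for species
identification, richness estimation and phylogenetic work with ITS data.

Reference-mode chimera detectors compare each query against a trusted,
chimera-free reference collection and ask whether its left and right
parts are best explained by *different* references. refchimera
implements the three ingredients such a workflow needs:

1. **Reference-set construction** — clustering a sequence corpus into
   species hypotheses (SHs) at stepped similarity thresholds and
   drawing one representative per SH (`build_reference_set()`).
2. **Detection** — a segmented, vote-based bimera score with an explicit
   crossover search (`screen_corpus()`, `detect_one()`).
3. **Benchmarking** — the classic simulation design in which the whole
   reference set is bisected at the 5.8S midpoint and reshuffled by a
   random derangement, plus the accompanying statistics
   (`simulate_benchmark()`, `detection_stats()`,
   `compare_score_groups()`).

A synthetic corpus generator with known taxonomy and exact region
boundaries (`generate_corpus()`) provides ground truth for every step.

## The synthetic corpus

`generate_corpus()` emulates the hierarchical structure of a curated
fungal ITS collection with a fixed divergence ladder:

| tier | default divergence | role |
|------|-------------------|------|
| corpus root → genus ancestor | 0.25 per spacer | separates genera well below the 80% coarse-clustering threshold |
| genus ancestor → species template | 0.05 | sibling species sit at roughly 90% identity: inside one genus cluster, but split by the 97–100% SH thresholds |
| species template → record | 0.005 | conspecific records stay above the 98.5% representative threshold |
| 5.8S ancestor → species 5.8S | 0.002, substitutions only | a near-invariant anchor, as the real gene is |

Spacer lengths are drawn uniformly (ITS1 170–220 bp, ITS2 172–222 bp
around a 158 bp 5.8S), giving a mean total length near the 550 bp
typical of the fungal kingdom. A fraction (default 0.1) of spacer
mutation events are single-base indels; indels never touch the 5.8S, so
the anchor and its midpoint stay well defined — which is precisely the
property the simulator exploits. Base composition is uniform and no
ambiguity codes are emitted by default.

What the generator does *not* model: rate heterogeneity along the
spacers, secondary structure, length differences between lineages,
sequencing error, and taxonomically biased sampling. Passing benchmarks
on this corpus therefore demonstrate the correctness and calibration of
the machinery under idealized conditions, not field performance on real
environmental data — the same caveat that applies to any
reshuffled-halves simulation.

```{r corpus}
corpus <- generate_corpus(n_genera = 4, species_per_genus = 3,
                          seqs_per_species = 3, seed = 1)
count(corpus, genus)
```

## Species hypotheses and the reference set

The corpus is clustered twice, mirroring curated-database practice:
first at 80% identity into genus-level groups, then within each group at
97%–100% in 0.5% steps into species hypotheses. Both rounds use
deterministic greedy centroid clustering: records are processed in
decreasing length order (ties by id) and join the first centroid at or
above the threshold. Thresholds are applied in ascending order, each
level subdividing the previous level's clusters, so SHs refine
monotonically — every SH at one threshold lies inside exactly one SH at
any lower threshold. This hierarchical pass is a deliberate design
choice: independent clustering runs per threshold would not guarantee
that nesting.

Identity is defined operationally as matching columns over alignment
columns after trimming terminal gap columns, from a global alignment
with match +1, mismatch −1, and affine gaps costing 2 + L for a gap of
length L. Ambiguity codes match only themselves; this is the only
parameter-free reading and is easy to test.

One sequence represents each SH at the 98.5% threshold: the most
frequent exact sequence type wins, with ties resolved by pooled
membership, longest sequence, then smallest id. Singleton SHs are
excluded unless explicitly sanctioned, reflecting the observation that
large-corpus singletons are enriched for technical artifacts; manual
overrides supersede the automatic choice and are recorded with
provenance `"manual"`.

```{r refset}
refs <- build_reference_set(corpus)
select(refs, id, sh_id, n_members, provenance)
```

## The chimera score

Each query is cleaved into four (default) contiguous segments, and the
references sharing the most 8-mers with each segment are pooled into a
candidate set (a deterministic stand-in for a heuristic similarity
search). For a candidate parent pair (A, B), both parents are globally
aligned to the query and the alignment columns are projected onto query
coordinates. Columns where query, A and B agree are ignored; every other
column casts a vote:

* **Y** — the query matches this side's parent and differs from the other,
* **N** — the query matches the *wrong* parent for this side,
* **A** — the query differs from both (abstention).

For a crossover placed in any gap between informative columns, each side
is scored as

$$h_{side} = \frac{Y}{\beta\,(N + r) + \alpha\,A}$$

and the pair score is the product $h_L \cdot h_R$, maximized over all
crossovers and both parent orientations. Defaults: no-vote weight
$\beta = 8$, abstention weight $\alpha = 0.5$, pseudo-count $r = 1.4$,
and at least `min_diffs = 3` yes-votes required per side. A query is
flagged when its best score over up to 24 candidate pairs exceeds 0.28.

The design rationale, in order of importance:

* **Multiplicative sides.** A genuine chimera has strong support on
  *both* flanks; a clean sequence whose mismatches scatter across two
  relatives accumulates yes-votes for either on both sides, so one side
  always carries heavy N-penalties and the product collapses. A pooled
  (additive) denominator does not have this property and fails to
  separate clean queries from chimeras at any single threshold.
* **Pseudo-count inside the no-vote weight.** With a bare additive
  regularizer, a side with a handful of terminal columns that happen to
  favor one parent scores Y/r and can simulate a crossover. With
  $\beta(N + r)$ a side needs roughly six clean diagnostic columns
  before it contributes materially, which places borderline cases —
  decisions hanging on a few base pairs — near the threshold, where
  they belong.
* **min_diffs.** A hard floor of three yes-votes per side removes the
  residual tail of one- and two-column "crossovers".
* **Unbounded scores.** The score grows with diagnostic-column counts,
  so obvious chimeras between divergent parents reach scores in the
  tens to hundreds while borderline ones sit just above the threshold —
  the dynamic range practitioners use to triage manual review.

The crossover search is exact: prefix sums over the informative columns
evaluate every cut position, and the package's tests verify equality
with a brute-force scan over all positions and all ordered parent
pairs.

```{r detect}
ann <- locate_58s(refs, consensus_58s(corpus))
bench <- simulate_benchmark(ann, n_replicates = 2, seed = 9)
calls <- screen_corpus(bench[, c("id", "seq")], refs)
glance(calls)
```

## Subregion extraction

Amplicon studies often sequence only ITS1 or only ITS2, so the
reference set is also provided as ITS1-only and ITS2-only views. The
5.8S is located by aligning a 5.8S consensus end-to-end inside each
record (pattern-global, subject-local alignment with the same scoring as
above); the best placement defines the gene, ITS1 is everything before
it and ITS2 everything after. A placement must reach half the maximum
attainable score or the record is excluded from the subregion files
with a warning rather than aborting the run. This consensus-anchored
approach deliberately replaces profile-HMM machinery: in the
conserved-5.8S regime the toolkit targets, a single anchor suffices,
and on synthetic corpora boundary recovery is exact. Sequences carrying
long (200+ bp) fragments of the flanking SSU/LSU genes are outside this
design's remit. The 5.8S interval is inclusive of its alignment span;
all coordinates are 0-based and half-open, a convention chosen once to
eliminate off-by-one ambiguity and recorded in every exported
annotation table.

## The simulation benchmark

`simulate_benchmark()` reproduces the standard evaluation design:
every annotated reference is bisected at
`r58s_start + floor(r58s_length / 2)` (the floor rule for odd lengths
is a documented convention), and right halves are reassigned to left
halves by a uniformly sampled derangement — a permutation with no fixed
points — so each fragment is used exactly once and never regrafts onto
its own parent. Uniformity comes from rejection-sampling random
permutations (about e attempts on average); with ten replicates the
procedure yields ten full-size chimera sets, mirroring the published
protocol. Reshuffling is global rather than constrained within genera:
the source protocol gives no constraint, and the unconstrained reading
matches its chimera counts. Derangement, conservation and uniformity
(all nine derangements of n = 4 within ±0.01 of 1/9 over 10,000 draws)
are asserted in the test suite.

```{r stats}
calls$replicate <- bench$replicate
stats <- detection_stats(calls)
glance(stats)
```

Detection rates are summarized as per-replicate percentages with their
mean and sample standard deviation (n − 1; the estimator is not
specified upstream, so the conventional one is used and documented).
Flagged scores are reported in the conventional bins (0.28, 1], (1, 10]
and (10, ∞) — bin edges are right-closed, a documented resolution of
the ambiguity in prose like "between 1 and 10". Chimeric and
non-chimeric score groups are compared with the Wilcoxon-Mann-Whitney
rank-sum test (midranks, tie-corrected normal approximation with
continuity correction, via `stats::wilcox.test`), with medians reported
alongside.

## Numerical and degenerate-input choices

* All randomness flows through explicit `seed` arguments
  (`withr::with_seed`); corpora, reference sets, benchmarks and reports
  are pure functions of their inputs, and reports embed no timestamps
  so reruns are byte-identical.
* Clustering ties (equal lengths, equal identities, equal modal counts)
  are all broken lexicographically by id, making every pipeline stage
  deterministic under input reordering.
* SH identifiers are content-derived hashes of the sorted member ids
  plus the threshold, so they are stable across runs and machines
  without minting database-style accessions.
* An empty candidate set, a query identical to one parent, or a pair
  with no informative columns all yield score 0 (never an error); a
  one-sequence reference set cannot be screened against itself with
  self-exclusion and simply produces no candidates.
* `segment_query()` refuses sequences shorter than the segment count;
  the same segmentation rule applies to full-length and ITS1-/ITS2-only
  queries of any length at or above it.

## Problem sizes

The packaged benchmark uses a corpus of 120 species in 40 genera with
two sequences per species (about 240 records, ~117 of which survive as
SH representatives), ten chimera replicates (~1,170 queries), and a
clean-reference self-screen. These sizes keep the full pipeline — from
corpus generation through screening and statistics — to a few minutes
on a single core while leaving every behavior of interest measurable;
all invariant checks additionally run on smaller corpora across many
seeds.

## Known limitations

* The detector handles two-parent (bimera) models only; three-way
  chimeras, breakpoints outside the 5.8S and abundance-informed *de
  novo* detection are out of scope.
* Queries are assumed to be forward-strand and orientation-normalized.
* Ambiguity codes are treated as literal symbols; a run of Ns therefore
  counts as abstentions rather than partial matches.
* Reference-mode detection is only as good as its reference set: a
  chimera whose parents are absent from the references, or whose
  parents share a near-identical spacer (for example conserved-ITS2
  species complexes), can evade detection or produce a false positive —
  flagged sequences merit manual review near the threshold.
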