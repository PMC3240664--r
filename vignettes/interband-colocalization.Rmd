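---
title: "Anchored interval analysis of interband-like open chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored interval analysis of interband-like open chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interbandscope)
```

## The problem

Polytene chromosomes of *Drosophila* alternate compacted bands with
decompacted interbands. A small set of interbands has been mapped to the
base pair through P-transposon insertions, giving 13 reference anchor
coordinates (distributed 1:3:4:5 over chr2R, chr3L, chr3R and chrX). The
question this package operationalizes: which chromatin proteins bind these
regions in cell-line chromosomes, do those proteins co-localize genome-wide,
and which chromatin states cover the anchors?

The package implements the full analytic chain as reusable, tested
components: anchored window profiling, a weighted-resampling binomial
enrichment test, genome-wide fragment length-class statistics, a pairwise
co-localization similarity rate with ordinal MDS and hierarchical
clustering, a block-contingency chi-square test, and chromatin-state
composition profiles — plus a synthetic-data generator so everything runs
and is verified without any external download.

## Data model and conventions

Binding tracks are `GRanges` with a numeric `score` column; the protein name
travels in `metadata()`. We use the Bioconductor convention (1-based closed
coordinates) internally; GFF input (1-based) is taken as-is, BED (0-based
half-open) is shifted on IO. "Overlap" always means at least one shared base
pair, so intervals that merely touch do not overlap — identical semantics to
the half-open formulation. Strand is ignored throughout: binding fragments
and chromatin states are strandless annotations.

Two inclusion rules recur. Fragments count only when their score is present
and strictly positive (a missing score is non-positive). The co-localization
statistic additionally drops fragments of 10 kb or longer; this length
filter applies *only* there — the resampling enrichment test deliberately
imposes no size limit, and the length-class table tabulates everything, with
lengths rounded to the nearest kb (half-up) into the 1–3 / 4–6 / 7–9 / 10–11
classes and explicit excluded-short/long tallies. The published class labels
never define bin edges; nearest-kb rounding is our reading (a floor-based
binning sits behind a flag).

## The enrichment test

For a window size `w` (4 or 10 kb), 13000 random chunks of size `w` are
drawn, arms chosen with weights equal to the anchors' per-arm counts
(1:3:4:5 at the reference), start uniform within the arm. The empirical
frequency `p` is the fraction of chunks overlapped by at least one positive
fragment (single-hit counting). With `m` of the 13 anchor windows bound, the
lower binomial tail is

P(p, m, 13) = sum_{i=0..m} C(13, i) p^i (1-p)^(13-i),

and the reported tail follows the observed side: if `m > 13 p` then
P' = 1 − P, otherwise P. Stars bin P' at 1e-2, 1e-3, 1e-6. Restricted
backgrounds (the three molecularly mapped band controls) sample inside the
given intervals, length-weighted. The two window sizes use independent
seeded draws; one chunk set per (window, background) is shared by all
tracks.

**A calibration caveat the tests make explicit.** The tail rule chooses the
tail after seeing `m` and, on the enriched side, uses P(X > m) — excluding
the observed count's own probability mass. Both features inflate the test's
size: under structureless null worlds we measure a type-I rate of ~0.10 at
nominal 0.05. The acceptance suite states the calibration criterion
faithfully and it fails by design of the published rule, not by
implementation error; the companion enumeration tests prove the tail
arithmetic exact to 1e-12. Users wanting calibrated p-values should treat P'
as a ranking score or apply the emitted Benjamini–Hochberg column.

## The similarity rate and its reduction

For tracks i and j (positive, < 10 kb), several fragments of one track may
bind the same fragment of the other; such redundant binders are removed from
both sides, leaving reduced sizes m', n'. The similarity rate is
r = k / min(m', n'), with k the remaining one-to-one overlap count. We
formalize the reduction as a maximum matching on the bipartite
interval-overlap graph: k is the matching size; each reduced track keeps its
matched fragments plus fragments overlapping nothing. Because the maximum
matching size is unique, k, m', n' and r are independent of tie-breaking;
matching is computed with augmenting paths over fragments in genomic order,
so retained fragment identities are reproducible. A literal "remove until
the graph is a matching" procedure cannot always reach the maximum k (a
fragment containing two matched counterparts keeps an extra edge), so the
guaranteed post-state is: exactly k fragments on each side overlap the other
side. The test suite pins k to an independent igraph matching oracle on a
thousand random instances.

The genome-wide significance of pairwise co-localization uses a 2x2
contingency over non-overlapping 3-kb blocks (the median fragment class;
40000 blocks at the 120 Mb reference scale — the shipped reference build
rounds arm lengths to 3-kb multiples so the partition is exact). A block is
positive for a protein when any positive fragment overlaps it; the expected
co-occupied count under independence is en = l·m/n, and the statistic is the
1-df Pearson chi-square (no continuity correction by default; a flag adds
Yates). Degenerate margins are flagged rather than crashed.

## Embedding and clustering

Dissimilarity is d = 1 − r. The embedding is two-dimensional *ordinal* MDS
(only the rank order of dissimilarities counts): classical-scaling
initialization, then Kruskal stress minimization with isotonic regression
(`MASS::isoMDS`); stress is reported as a fraction. Rank-basedness makes the
result invariant to monotone transforms of d, which is why the simple 1 − r
choice is safe. Off-diagonal zeros (identical tracks) are lifted by a tiny
epsilon because zero dissimilarities are not representable in the stress
machinery; coincident classical starts get an epsilon jitter under the
caller's seed. Clustering is standard agglomeration on the same d; average
linkage by default (the original tool's linkage is unstated; complete and
single sit behind a flag), cut at k groups.

## What the synthetic worlds emulate

`sim_config()` states the world once; `generate_world()` realizes it
deterministically from the seed, with per-track substreams keyed by protein
name so adding a track never reshuffles the others.

* **Scale.** Four arms totalling 12 Mb (one tenth of the 120 Mb euchromatic
  reference), 350 planted interband-like loci (one tenth of the ~3500
  estimated genome-wide), spaced at least 12 kb apart so loci stay separable
  from any single fragment.
* **Loci and anchors.** Loci are points expanded to 3-kb windows (the
  median fragment class and the "3–4 kb" interband size estimate). Thirteen
  loci are sampled with the reference 1:3:4:5 arm distribution; anchors sit
  at locus centers with ±500 bp jitter. The jitter default is a free
  parameter, not an inference — no noise model for anchor placement exists
  in the source.
* **Tracks.** Six "active" proteins place a fragment over each locus with
  detection probability 0.95 (the reference bound-fractions are 80–100%,
  most near 100%; 0.95 gives an expected 96%), centered with jitter, plus
  uniform background at 20 fragments/Mb, for a total density matching the
  real genome-wide one (~42 fragments/Mb). Six "silent" proteins (Polycomb
  group and insulators) place 40 fragments/Mb uniformly, avoiding loci by
  construction. Ten percent of background fragments carry non-positive
  scores to exercise the positive filter. Fragment lengths are log-normal
  (meanlog log 1800, sdlog 0.45) truncated to [0.2, 11] kb, putting ~90% of
  fragments in the 1–3 kb class — inside the published 70–95% range; the
  published table gives class frequencies, not a family, so the family is a
  package choice.
* **States.** A RED-analog segment paints each locus; the remainder is
  partitioned into segments (exponential lengths, mean 8 kb) labeled
  YELLOW/BLUE/GREEN/BLACK with weights 0.20/0.15/0.15/0.50 (BLACK dominates
  real genomes). The nine-state scheme plants state "1".
* **Null worlds.** `null_world()` keeps every marginal rate but removes all
  structure: uniform tracks, uniform anchors (at the configured per-arm
  counts, matching the default sampling weights), unplanted states.

What a green test does *not* establish: the generator has no nucleosome- or
read-level signal, no correlated placement between active tracks beyond
shared loci, no chromatin-domain autocorrelation, and anchors are never
systematically offset from loci. Results on real ChIP-chip data (absolute
counts, published percentages, published cluster coordinates) are expressly
out of desk scope.

## Numerical choices and degenerate inputs

* Percentages are half-up rounded to one decimal, matching the published
  tables (base R's round-half-even would disagree on exact halves).
* `binomial_tail` uses `pbinom` for both tails (never `1 - pbinom` in
  floating point); p = 0 and 1 are exact.
* Windows clipped at arm edges warn and compute shares over covered bp;
  state shares include an explicit "unassigned" filler so they always sum
  to 100.
* Ratio of state shares with an empty denominator returns a flagged
  undefined result, not an error.
* `similarity` on an empty reduced side returns r = 0 with a `degenerate`
  flag.
* The interband-border helper (maximal segment run with a quorum of bound
  active tracks) is explicitly heuristic — the published borders were drawn
  by eye.
* The 10A1-2 band control start coordinate is printed in the source with an
  extra digit; the fixture resolves it to 10.8 Mb (the only value inside
  the arm and consistent with its end) and says so in its header.

## Known limitations

The enrichment tail rule is anti-conservative (see above) — kept because it
is the published procedure. Whether redundancy-removal's k should count
matched pairs or raw overlap events is resolved in favor of matched pairs
(the oracle invariant pins this down). Real-data acceptance (published
absolute numbers) requires the original downloads and is not attempted.
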