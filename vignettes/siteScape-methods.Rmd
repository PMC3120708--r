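---
title: "Landscape-based prediction of protein interaction sites: methods and design"
author: "siteScape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape-based prediction of protein interaction sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteScape)
```

## The model

Short polypeptide sequences that re-occur across a proteome mediate a large
fraction of protein–protein interactions. siteScape turns that observation
into a site predictor. For query proteins A and B and an interaction
database (unordered id pairs with sequences), every pair of sliding windows
(window length `w`, one window per start position) is scored by
co-occurrence:

$$H[i,j] = \#\{\text{oriented pairs } (X,Y) :
  \text{window}_i(A) \sqsubseteq X \wedge \text{window}_j(B) \sqsubseteq Y\}$$

Each unordered database pair contributes both orientations (X, Y) and
(Y, X) — a self-pair contributes once — so the landscape cannot depend on
the arbitrary column order of the pair file, and
`computeLandscape(A, B)[i, j] == computeLandscape(B, A)[j, i]` holds
exactly. The increment is one per oriented pair, however many positions of
X match: co-occurrence is counted over *pairs*, not occurrences, which
bounds every cell by twice the number of database pairs and keeps counts
interpretable as "supporting interactions". Window matching defaults to
exact substring occurrence; a similarity mode (substitution matrix plus a
summed-score threshold) is available through `matchParams()` for users who
want tolerant matching, with the conservative rule that `'X'` (unknown
residue) matches only itself exactly and never matches under similarity.
Match profiles per (query, database protein) are cached internally; results
are identical with and without the cache.

A query pair is scanned with the unordered query pair removed from the
database by default (`excludeQueryPair = TRUE`): when a validation pair also
appears in the training data, keeping it would let the pair explain its own
site.

## Site calling

Peaks indicate sites; the hill around a peak indicates extent. Site calling
iterates:

1. **Gate.** If the tallest cell is below `minPeakHeight` (default 10
   counts) the landscape yields no predictions. Diffuse landscapes can
   support an interaction call while containing no discrete site feature;
   the default follows the conventional compromise value of 10 after
   comparing 5/10/15. The retained condition is `height >= minPeakHeight`
   (the threshold is configurable, and documented as inclusive).
2. **Peak.** The tallest unmasked cell, ties broken by smallest row then
   smallest column index. The tie rule is a package choice made purely for
   determinism.
3. **Spurious-spike rejection.** A minimum of one walk step in each
   direction is enforced: if any in-bounds axial neighbour is below
   `percentPeak × height`, the peak is a sharp spike without a supporting
   hill — typically a random match — and is masked (that single cell) and
   skipped. Directions outside the matrix count as satisfied so boundary
   peaks are not auto-rejected.
4. **Walk.** From the peak, four independent axial runs (up, down, left,
   right) continue while the landscape stays at or above
   `percentPeak × height`; the run extents define the site rectangle
   (a cross-probe bounding box, not a flood fill). Residue ranges are the
   union of the residues covered by the rectangle's windows:
   `[i0, i1 + w − 1]` and `[j0, j1 + w − 1]`, 1-based inclusive, the
   coordinate convention of every file the package reads or writes.
5. **Mask and repeat** until `maxPeaks` predictions (default 3) or no peak
   reaches the gate. Ranks follow decreasing peak height.

Two masks with different roles are kept deliberately separate. Cells masked
as *spurious* are excluded from the peak search only: a genuine peak's walk
may cross them, since the spike rejection says nothing about the hill they
sit on. Cells *claimed* by an earlier rank stop both the search and the
walk, and the recorded rectangle is additionally clipped against claimed
cells, so rectangles of distinct ranks are cell-disjoint — without the
clip, a later walk whose axial probes avoid an earlier rectangle could
still overlap it at a corner.

`percentPeak` has no canonical published value; the package default is
0.30. Lower values extend the walk further down the hill and give larger,
less specific sites; raising the value gives compact cores. It is exposed
on every relevant function and as a required-visible CLI flag.

## The Distance Measure

Validation data (DOMINO-style lab-confirmed site pairs) frequently
over-estimate sites — whole domains reported where a few residues bind — so
a useful error metric must not punish a prediction for being smaller than
the lab range. Per protein the distance is the clamped overshoot

$$\Delta = \max(0,\ start_{lab} - start_{pred},\ end_{pred} - end_{lab}),$$

zero exactly when the prediction is contained in the lab range. The two
distances are scaled by protein length and combined by vector addition:

$$DM = \frac{1}{\sqrt 2}\sqrt{\left(\frac{\Delta_A}{L_A-1}\right)^2 +
  \left(\frac{\Delta_B}{L_B-1}\right)^2} \in [0,1].$$

Two boundary facts pin the algebra down: containment on both sides gives
exactly 0, and single-residue sites at opposite ends of both proteins give
exactly 1. The second fact forces the normalisation denominator to be
$L-1$ rather than $L$ (the maximal possible overshoot of a length-1
prediction is $L-1$); a length-1 protein contributes ratio 0 by convention.
It also fixes the sign of the end-position difference as
$end_{pred} - end_{lab}$: both differences must be negative under
containment for the clamp to read "perfect match". The measure is nearly
scale-free — doubling all coordinates and lengths changes DM by under 2%
for proteins of length ≥ 50 — so values are comparable across proteins of
arbitrary length. No attempt is made to trim coarse lab ranges; the clamp
is the accommodation.

`bestOfK()` models validating the top-k ranked sites (minimum DM over the
first k ranks) and is non-increasing in k by construction.

## Evaluation against a random baseline

`evaluatePredictions()` scores each lab pair's rank-1..k predictions,
draws `nRandom` matched random sites per pair (start uniform on
$\{1..L\}$, end uniform on the remaining length $\{start..L\}$,
independent per protein; the "remaining length" reading of the baseline is
uniform — the one natural choice), and reports:

* per-pair DM and best-of-k values, with gated pairs counted and excluded
  from averages;
* mean predicted vs mean random DM per k;
* enrichment tables over DM bins (10-point bins to 50%, one open bin
  above — the two conventional example bins are "0% ≤ DM < 10%" and
  "50% ≤ DM"; edges configurable);
* a two-sample Kolmogorov–Smirnov comparison of the rank-1 predicted and
  slot-1 random DM distributions (exact-vs-asymptotic p-value method is
  left to `stats::ks.test` and recorded in the report).

The random stream is seeded (mandatory `seed`) and the baseline is drawn
for every pair whether or not it was gated, so gating cannot shift the
stream of later pairs.

`perProteinContributions()` audits imbalance in validation sets where some
proteins recur across many pairs. No published formula exists for a
single-protein score, so the package defines it as the protein's
length-scaled overshoot pushed through the DM combiner with the partner
term zeroed, $ratio_X/\sqrt 2$: the score lives on the DM scale and the
vector sum of the two per-protein scores recovers the pair DM exactly.

## Domain context

`bestOverlapDomain()` picks the annotation maximising residue overlap with
a predicted range (ties: longer annotation, then lexicographic accession —
determinism again). `domainPairCounts()` counts unordered co-occurring
domain-name pairs over qualifying site pairs, optionally keeping only
predictions with DM below a high-confidence threshold (0.20 by
convention). `unannotatedSites()` reports site pairs overlapping no
annotation on *either* protein, with peak height and literal subsequence —
candidate novel re-occurring motifs. Pairs annotated on exactly one side
belong to neither table; they are excluded conservatively and surfaced via
a message. Annotations are consumed as precomputed tables (e.g. an
InterProScan export); the package never calls annotation services.

## The synthetic generator

`generateDataset()` emulates the one property the method depends on:
re-occurring sequence pairs among interacting proteins. It draws uniform
random sequences over the 20 standard residues, overwrites a motif pair
into disjoint carrier groups at recorded positions (overwriting rather than
inserting keeps lengths and coordinates fixed), wires carrierA × carrierB
interactions at a given density plus Bernoulli background pairs, and holds
out one query pair per motif whose true rectangle goes into the lab-site
table. Defaults: 24 proteins (12 carriers + 12 background, a realistic mix
of signal and noise at background rate 0.02), lengths uniform on 80–200,
6 + 6 carriers at density 1.0, motif length 12 scanned at `w = 10`.

The motif must be strictly longer than the scanning window. With motif
length equal to `w` the planted signal occupies exactly one landscape cell,
and the spurious-spike filter rejects one-cell spikes *by construction* —
recovery would be impossible for any `percentPeak`. Motif length
`w + 2` gives a 3 × 3 support block whose centre survives the filter and
whose walked rectangle converts to exactly the planted residue ranges.

What the generator does **not** emulate: realistic amino-acid composition,
homology and shared evolutionary history between database proteins,
low-complexity regions, and lab-site over-estimation (truth ranges are
exact). Passing recovery tests therefore demonstrates correctness of the
counting, walking and scoring machinery — not expected accuracy on real
interactomes, which depends on database coverage and matching parameters.

## Problem sizes and numerical choices

The shipped test-suite sizes are the package's own verification choices:
landscape correctness is proven against a brute-force triple-loop oracle on
50 random toy instances (≤ 8 proteins, length ≤ 30, `w` ≤ 4); DM laws are
scanned exhaustively over the full two-sided interval product on length-6
proteins and per-protein on length-12 proteins; planted-site recovery runs
100 seeded replicates of the default study; evaluation-null calibration
runs 100 replicates of 200 pairs. All randomness is seeded; identical
seeds give byte-identical generator output.

Degenerate inputs are defined, not accidental: a query shorter than `w`
yields a zero-extent landscape (no predictions); an all-zero or fully
masked landscape has no peak; an empty DM list makes `bestOfK()` return
`NA`, excluding the pair from averages; a length-1 protein contributes DM
ratio 0; single-residue lab sites are valid records, while records with
`start > end` or non-positive coordinates are rejected at parse time.

## Known limitations

* Exact matching with the default `w` is stricter than similarity-based
  matching tuned on real interactomes; on sparse databases landscapes will
  often gate. The similarity mode is provided but no published constants
  are claimed for it.
* Peak ranking uses height only; no shape statistics beyond the spurious
  rule.
* The walk's cross-probe rectangle can overstate a curved hill's extent in
  the corners; it was chosen as the literal, deterministic reading of the
  axial-walk description.
* Whether re-detection should happen on a threshold-masked rather than
  rectangle-masked landscape is unknowable from the published description;
  rectangle masking (with the disjointness clip above) was chosen and is
  the behaviour the tests pin down.
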