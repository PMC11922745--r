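---
title: "Methods: strand-specific DSB end-map analysis and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-specific DSB end-map analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakmapr)
```

## The data model

A strand-specific DSB end map assigns to every nucleotide of a reference
sequence two non-negative numbers: the count of sequencing-read 5′ ends on
the top strand and on the bottom strand. In TDP2-seq-style libraries the
read's first template base is the nucleotide immediately next to the
break-proximal (biotinylated) adaptor, so after fill-in of the 5′ overhang
each DSB contributes one top-strand end and one bottom-strand end. For a
2-nt 5′ overhang with dyad pair (g, g+1) — the two unwound central bases —
the top-strand end falls on g and the bottom-strand end on g+1.

`strand_track` holds the two vectors per sequence, a units flag
(`raw_counts` or `RPM`), and the shared normalization denominator.
Normalization is reads-per-million over both strands jointly (one
library), so an unmasked RPM track sums to exactly 10^6. Masked positions
are `NA`, deliberately distinct from zero: writing masked runs as zeros
would bias correlations and composition backgrounds, so serialization puts
them in a sidecar BED instead.

Coordinates are 1-based inside R structures, matching the host language
and the Bioconductor containers the package builds on; BED and bedGraph
files are read and written in their standard 0-based half-open
conventions. Dyad-relative positions use the field's no-zero labelling
(…, −2, −1, +1, +2, …): for dyad pair (g, g+1), offset −k maps to
g − (k − 1) and +k to (g + 1) + (k − 1).

## The simulator: what it emulates

The generator plants a known cleavage landscape so that every analysis
stage can be validated against ground truth.

* **Genome.** I.i.d. residues with P(G) = P(C) = gc/2. The default
  50-kb, 45%-GC linear sequence is a neutral substrate of roughly
  bacterial-plasmid-library scale; it carries a few hundred matches to a
  6-bp degenerate motif, enough for site-averaged statistics without
  special structure.
* **Cleavage preference.** `cleavage_model` is a positive weight matrix
  M\[base, offset\] over offsets −h…−1, +1…+h (default h = 10). A dyad's
  score is the product of the weights of its window bases; scores
  normalised over all valid dyads give the sampling distribution.
  `default_model` sets weight 4 (all other weights 1) for G at −3, A at
  −1, T at +1 and C at +3. This encodes the observed dyad-proximal bias
  of SPO11-class enzymes, is exactly rotationally symmetric
  (M\[b, +k\] = M\[complement(b), −k\], the signature of two protomers on
  two half-sites), and makes the GNATNC family the unique best-scoring
  central hexamer. The boost value 4 makes the conditional fraction of G
  at −3 among cleavage sites ≈ 4p/(1+3p) ≈ 0.54 at p = 0.225 — the
  magnitude seen in strongly biased end maps.
* **Breaks.** Each of N DSBs is background with probability β (uniform
  over valid dyads) else drawn from the score distribution. The default
  N = 2,000 at β = 0.05 gives a map in which the strongest sites carry a
  handful of reads — a deliberately modest depth that keeps the test
  suite fast while leaving all signatures detectable.
* **Tracks.** Each break yields one top end at g and one bottom end at
  g+1 (the two ligatable ends of one DSB). Independently per end, with
  probability φ the fill-in is incomplete and the end is shifted by s nt
  toward the dyad interior of the opposite strand's position: top to
  g + s, bottom to (g + 1) − s. φ defaults to 0.1 with s = 1; φ is a free
  parameter of the simulation, not an estimate of any experiment's
  artifact rate. Ends shifted off a linear sequence are dropped with a
  warning. Raw counts therefore total 2N minus such drops.
* **Control.** A catalytically dead enzyme's library is random background:
  `simulate_control` places N top and N bottom ends uniformly and
  *independently* per strand. The two-ends-per-break pairing is
  intentionally absent — it is the pairing, not the uniformity, that
  creates the +1 cross-correlation offset, and dead-enzyme maps show no
  such offset. (A uniform-dyad simulation through `simulate_breaks(β = 1)`
  plus `simulate_tracks` retains the pairing and is *not* a faithful
  control for polarity analyses.)

What the simulator does **not** emulate: fragment shearing and length
selection, sequencing error, mappability variation, chromatin context,
nick capture, or resection. Passing tests therefore demonstrate the
correctness of the algorithms under the stated generative model, not
robustness to every artefact of real libraries.

## Peak calling and the fill-in artifact rule

A top-strand position q is a peak iff top\[q\] > t and (artifact check on)
top\[q\] ≥ top\[q − w\]; bottom-strand: bottom\[q\] > t and
bottom\[q\] ≥ bottom\[q + w\]. The neighbour comparison targets incomplete
fill-in: an unfilled top-strand end produces a read assigned one step to
the right of the genuine end, so a top candidate is compared against the
position w nt to its left — the site that would carry the genuine signal
were the candidate an artifact — and symmetrically for the bottom strand.

Numerical choices, all deliberate:

* strictly-greater at the threshold, greater-or-equal at the neighbour
  (only strict inferiority rejects; equal stacks survive);
* w defaults to 1 nt and is configurable for sensitivity analysis, since
  a 2-nt overhang could in principle misplace ends by 2;
* out-of-range and masked neighbours count as zero; circular sequences
  wrap; masked candidates are never callable;
* smoothed tracks are refused — smoothing is display-only.

A consequence worth stating: a genuine site whose artifact-side neighbour
is an adjacent, strictly stronger genuine site is excluded exactly as an
artifact would be. The rule cannot distinguish the two cases from counts
alone, and the tests assert the rule's contract rather than the idealized
"every true site survives" phrasing.

Thresholds are fixed RPM values chosen per substrate class; named presets
(`peak_threshold_presets`: plasmid 3,000; bacterial 10; yeast 15 RPM)
reflect typical working points for those substrate complexities. For the
simulated datasets the drivers use a read-count-denominated threshold
(e.g. three reads' worth of RPM at 4,000-read depth, eight reads' worth at
40,000) because the meaningful unit at simulation depth is reads, not RPM.
No multiple-testing machinery is attached: the caller is a thresholding
rule, not an enrichment model.

## Polarity by strand cross-correlation

r(k) is the Pearson correlation of (top\[i\], bottom\[i + k\]) over all
unmasked position pairs valid at lag k, pooled across sequences, for
k = −10…+10. Pearson over per-nucleotide values is this package's choice
of estimator — "cross-correlation" admits several definitions and the
strand-shift literature standardly uses Pearson at integer lags. The
computation is always on unsmoothed maps; a 21-bp Hann kernel would smear
a single-nucleotide offset into invisibility. Ties in the argmax break
deterministically toward the smallest |k|, then the smaller k.

Overhang inference is pure geometry: an L-nt 5′ overhang places the
bottom 5′ end L − 1 nt right of the top 5′ end, so L = k\* + 1, with
k\* = −1 meaning blunt and k\* < −1 (3′ overhangs) out of scope.
Enumerating the cases: blunt cut — both ends abut, bottom end 1 nt left
of top (k\* = −1, L = 0); 1-nt overhang — both 5′ ends on the same
position (k\* = 0, L = 1); 2-nt overhang — bottom 1 nt right (k\* = +1,
L = 2).

The replicate-correlation statistic behind "replicate maps are
reproducible" is likewise unspecified in the field; the package uses
Pearson on per-position RPM (both strands concatenated, masked positions
excluded), with a log10(x+1) option, and reports flag which was used.

## Composition, logos, and the GC correction

Windows around peaks are oriented so the assigned base sits at offset −1
on the read strand: top peaks keep genomic orientation (dyad pair
q, q+1); bottom peaks are reverse-complemented (dyad pair q, q−1 in
genomic coordinates), so re-orienting twice is an involution. Windows
running off linear ends or containing N are dropped and counted.

Composition is unweighted — each peak counts once — because site-level
preference, not read abundance, is the quantity of interest; a
count-weighted variant is available by passing a peak set expanded by
weight. Logo letters are scored as per-letter relative entropy against a
GC-split background, q_G = q_C = GC/2: this is the standard
information-content logo with a non-uniform background, chosen because
the substrate's base composition — not the uniform 25% — is the correct
null for "which bases are enriched at this offset". The background
defaults to the substrate genome's average GC; a local-GC override exists
for the case where the neighbourhood of mapped sites differs substantially
from the genome average (e.g. AT-rich genomes whose cleavage neighbourhood
is closer to 48% than 38% GC). Cells with f = 0 score 0 bits; display
column height is the sum of positive letter scores.

## Motif scanning

`scan_iupac` reports every top-strand match of an even-length IUPAC
pattern, overlapping matches included (the behaviour of classic
degenerate-pattern scanners), across the origin on circular sequences.
Only even-length patterns are accepted so the central dyad is unambiguous:
pattern position m of a 2m-length pattern is the offset −1 base. The two
patterns of interest, GNATNC and CNTANG, are self-reverse-complementary,
so a single-strand scan is complete. A genome N matches only the pattern
code N — an unknown base is never silently accepted as evidence of a
match. The enrichment summary divides the mean of the two expected signal
cells (top at −1, bottom at +1) by the median of both strands at
|offset| > 5, so a flat profile scores exactly 1.

## Problem sizes and determinism

Every stochastic function takes an explicit integer seed and restores the
caller's RNG state; identical inputs and seed give bit-identical outputs.
The shipped analyses and tests use 50-kb genomes with 2,000–20,000 breaks:
large enough for stable composition and correlation statistics (hundreds
of motif sites, thousands of windows), small enough that the whole
pipeline runs in seconds per stage. The acceptance script regenerates its
map from scratch at 2,000 breaks with exact end geometry (φ = 0), where
the cross-correlation argmax at +1 is essentially deterministic across
seeds.

## Known limitations

* The artifact filter compares only one neighbour distance w at a time.
* The cross-correlation is global; per-peak offset estimation is out of
  scope.
* The simulator's replicate model ties reads to breaks one-to-one, so
  replicate correlation at a given depth depends on how concentrated the
  planted landscape is; real libraries resample fragments and can show
  higher replicate correlation at equal depth.
* Composition analyses drop N-containing windows rather than imputing.
* bigWig output and alignment-stage processing are out of scope; the
  pipeline consumes already-assigned 5′-end positions (BED6) or bedGraph
  pairs.
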