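# breakmapr

Strand-specific analysis of DNA double-strand-break (DSB) 5′-end maps, with
a synthetic break-map generator that provides ground truth for every stage.

## The problem

Topoisomerase-family enzymes such as meiotic SPO11 cut duplex DNA leaving
covalent 5′ attachments and a 2-nt 5′ overhang whose midpoint is a two-fold
rotational symmetry (dyad) axis. Sequencing protocols in the TDP2-seq /
S1-seq family read out these breaks as strand-separated per-nucleotide
counts of read 5′ ends: each read's first template base is the nucleotide
immediately adjacent to the break-proximal adaptor. Analysing such maps
raises a recurring set of questions:

* **Polarity and overhang.** Fill-in of an L-nt 5′ overhang places the
  bottom-strand 5′ end L − 1 nt to the right of the top-strand 5′ end, so
  the lag k\* that maximises the strand cross-correlation
  r(k) = cor(top\[i\], bottom\[i + k\]) estimates the overhang as
  L = k\* + 1. A 2-nt overhang gives k\* = +1; a blunt cut gives k\* = −1.
* **Which positions are real cleavage ends?** Peaks are single nucleotides
  with strand-specific signal above a fixed RPM threshold, minus positions
  explainable as incomplete-fill-in artifacts: reads from an unfilled
  overhang pile up one step away from the genuine end, so a candidate whose
  artifact-source neighbour (own strand, −1 for top / +1 for bottom) holds
  strictly more reads is excluded.
* **What sequence does the enzyme prefer?** Windows around peaks are
  oriented so the assigned base sits at dyad offset −1 on the read strand
  (bottom-strand peaks reverse-complemented), base fractions f(b, k) are
  tallied per offset, and per-letter logo scores
  s(b, k) = f(b, k) · log2(f(b, k) / q_b) are computed against a G+C-split
  background q (genome-average GC by default, a local-GC override when
  appropriate). A two-protomer enzyme yields a rotationally symmetric
  signature, f(b, −k) = f(complement(b), +k).
* **Does a candidate motif attract signal?** IUPAC degenerate patterns
  (e.g. the preferred GNATNC family vs its non-preferred reverse CNTANG)
  are scanned genome-wide; strand-specific signal averaged over the motif
  dyads shows the end-geometry signature (top maximum at −1, bottom at +1)
  only for genuinely preferred sequences.

The package implements each step as a plain R function over simple S3
containers (`genome_sequence`, `strand_track`, `peak_set`,
`composition_profile`), reads and writes FASTA / BED / bedGraph in their
standard conventions, and ships a simulator
(`simulate_genome`, `default_model`, `simulate_breaks`, `simulate_tracks`,
`simulate_control`) whose planted cleavage-preference model, fill-in
artifact fraction and uniform background make every downstream claim
testable against known truth.

## Worked example

The `analysis/` scripts run the full pipeline on a simulated dataset
(50-kb genome at 45% GC, 2,000 DSBs from the default preference model,
two replicate track samplings, one dead-enzyme control):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_tracks.R
Rscript analysis/03_peaks.R
Rscript analysis/04_polarity.R
Rscript analysis/05_bias.R
Rscript analysis/06_motif.R
```

Output printed by the run (tables land under `results/`):

```
genome: 50,000 nt at GC = 0.4509
planted 1836 distinct cleavage dyads carrying 2000 DSBs
replicate r = 0.837 (signal), 0.001 (background)
threshold 500 RPM: 39 peaks (20 top / 19 bottom strand)
100% of top-strand peaks coincide with a planted dyad
signal map: k* = +1 (r = 0.8249) -> 2-nt 5' overhang
control map: max r = 0.0075 at k = -4 (no geometry)
logo maxima at -3/-1/+1/+3: G/A/T/C (planted: G/A/T/C)
GNATNC: 178 sites; CNTANG: 204 sites
enrichment E = 21.36 (GNATNC) vs 0.40 (CNTANG); ratio 53.39
```

Reading the numbers: replicate samplings of the same break landscape
correlate strongly while independent background maps do not; every called
top-strand peak is a planted dyad; the cross-correlation argmax at +1
recovers the 2-nt 5′ overhang while the control map shows no preferred
lag; the logo maxima recover the planted G/A/T/C bias at offsets
−3/−1/+1/+3; and dyad-proximal signal is ~53-fold enriched at preferred
motif sites relative to the non-preferred reverse sequence.

## Layout

* `R/` — package functions (simulation, track ops, peak calling,
  polarity, composition/logos, motif scanning, I/O).
* `analysis/` — the numbered pipeline drivers shown above.
* `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracles for the peak rule and the IUPAC scanner.
* `vignettes/breakmap-methods.Rmd` — the model, its assumptions, and the
  numerical choices, in detail.
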