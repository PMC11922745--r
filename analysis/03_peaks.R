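#!/usr/bin/env Rscript
# Stage 3: strand-specific peak calling with the fill-in artifact filter.
#
# Cleavage positions are nucleotides whose strand-specific RPM exceeds the
# threshold and that survive the incomplete-fill-in exclusion (a candidate
# is dropped when the position that would carry the genuine end, were the
# candidate an artifact, holds strictly more reads). At this simulated
# depth (4,000 reads over 50 kb) the working threshold is three reads'
# worth of RPM; reference substrate presets (plasmid 3,000; bacterial 10;
# yeast 15 RPM) are in peak_threshold_presets.

suppressPackageStartupMessages(library(breakmapr))

genome <- read_fasta("results/genome.fa")
rpm <- normalize_rpm(read_track_bedgraph("results/rep1.plus.bedgraph",
                                         "results/rep1.minus.bedgraph",
                                         genome))
thr <- 2 * 1e6 / rpm$total_mapped  # > 2 reads: >= 3 reads at this depth
peaks <- call_peaks(rpm, threshold = thr)
write_peaks_bed(peaks, "results/peaks.bed")
write_peaks_tsv(peaks, "results/peaks.tsv")
strongest <- top_peaks(peaks, 10)
write_peaks_tsv(strongest, "results/peaks_top10.tsv")

truth <- utils::read.table("results/truth.tsv", header = TRUE,
                           comment.char = "#")
top_pk <- peaks$pos[peaks$strand == "top"]
hit <- mean(top_pk %in% truth$dyad)

message(sprintf("threshold %.0f RPM: %d peaks (%d top / %d bottom strand)",
                thr, nrow(peaks), sum(peaks$strand == "top"),
                sum(peaks$strand == "bottom")))
message(sprintf("%.0f%% of top-strand peaks coincide with a planted dyad",
                100 * hit))
message(sprintf("strongest peak: %s:%d (%s) at %.0f RPM",
                strongest$seqname[1], strongest$pos[1],
                strongest$strand[1], max(strongest$signal)))
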