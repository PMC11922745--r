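#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# A 50-kb linear genome at 45% GC is cut 2,000 times by the default
# rotationally symmetric preference model (GNATNC-type central bias, 5%
# uniform background, 10% incomplete fill-in). Two replicate track
# samplings from the same break table emulate replicate libraries, and a
# pure-background map emulates a catalytically dead control. Everything
# downstream reads these files from results/.

suppressPackageStartupMessages(library(breakmapr))

dir.create("results", showWarnings = FALSE)
seed <- 20260101L %% 100000L

genome <- simulate_genome(50000L, gc = 0.45, circular = FALSE, seed = seed)
model <- default_model()  # h = 10, boost 4, beta 0.05, phi 0.1, shift 1
truth <- simulate_breaks(genome, model, 2000L, seed = seed + 1L)
rep1 <- suppressWarnings(simulate_tracks(truth, genome, seed = seed + 2L))
rep2 <- suppressWarnings(simulate_tracks(truth, genome, seed = seed + 3L))
ctrl <- simulate_control(genome, 2000L, seed = seed + 4L)

write_fasta(genome, "results/genome.fa")
write_truth_tsv(truth, "results/truth.tsv")
write_track_bedgraph(rep1, "results/rep1.plus.bedgraph",
                     "results/rep1.minus.bedgraph")
write_track_bedgraph(rep2, "results/rep2.plus.bedgraph",
                     "results/rep2.minus.bedgraph")
write_track_bedgraph(ctrl, "results/control.plus.bedgraph",
                     "results/control.minus.bedgraph")

message(sprintf("genome: 50,000 nt at GC = %.4f", gc_content(genome)))
message(sprintf("planted %d distinct cleavage dyads carrying %d DSBs",
                nrow(truth), sum(truth$count)))
message(sprintf("replicate 1 placed %s read 5'-ends; control placed %s",
                format(rep1$total_mapped, big.mark = ","),
                format(ctrl$total_mapped, big.mark = ",")))
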