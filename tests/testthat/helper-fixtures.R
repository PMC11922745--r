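# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written from the rule definitions, not from the package
# implementation paths they check.

toy_genome <- function(seqs, circular = FALSE) {
  genome_sequence(seqs, circular = circular)
}

# a strand_track with values poked in by hand
make_track <- function(genome, top = list(), bottom = list(),
                       units = "RPM", total_mapped = 1) {
  tr <- strand_track(genome, total_mapped = total_mapped)
  for (nm in names(top)) {
    v <- top[[nm]]
    tr$top[[nm]][as.integer(names(v))] <- unname(v)
  }
  for (nm in names(bottom)) {
    v <- bottom[[nm]]
    tr$bottom[[nm]][as.integer(names(v))] <- unname(v)
  }
  tr$units <- units
  tr
}

# position-by-position peak-calling oracle: strict > at the threshold,
# >= at the artifact neighbour, out-of-range/NA neighbours are 0
peak_oracle <- function(track, threshold, artifact_check = TRUE, w = 1L) {
  rows <- list()
  for (nm in track$seqnames) {
    len <- track$lengths[[nm]]
    circ <- track$circular[[nm]]
    val_at <- function(v, i) {
      if (circ) i <- ((i - 1L) %% len) + 1L
      if (i < 1L || i > len) return(0)
      x <- v[i]
      if (is.na(x)) 0 else x
    }
    for (q in seq_len(len)) {
      tv <- track$top[[nm]][q]
      if (!is.na(tv) && tv > threshold &&
          (!artifact_check || tv >= val_at(track$top[[nm]], q - w))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = nm, pos = q, strand = "top", signal = tv)
      }
      bv <- track$bottom[[nm]][q]
      if (!is.na(bv) && bv > threshold &&
          (!artifact_check || bv >= val_at(track$bottom[[nm]], q + w))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = nm, pos = q, strand = "bottom", signal = bv)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqname = character(), pos = integer(),
               strand = character(), signal = numeric())
  out <- out[order(out$seqname, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive IUPAC scan oracle on one linear sequence string; returns
# 1-based match start positions
IUPAC_ORACLE_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

iupac_scan_oracle <- function(seqstr, pattern) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  pchars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  n <- length(chars); plen <- length(pchars)
  if (n < plen) return(integer())
  ok <- rep(TRUE, n - plen + 1L)
  for (j in seq_len(plen)) {
    ok <- ok & chars[j:(n - plen + j)] %in% IUPAC_ORACLE_TABLE[[pchars[j]]]
  }
  which(ok)
}

# random uppercase ACGT string
random_seq <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# a small simulated study-condition dataset shared across tests
sim_dataset <- function(len = 50000L, gc = 0.45, N = 2000L, beta = 0.05,
                        phi = 0, seed = 11L, circular = FALSE) {
  genome <- simulate_genome(len, gc, circular = circular, seed = seed)
  model <- default_model(beta = beta, phi = phi)
  truth <- simulate_breaks(genome, model, N, seed = seed + 1L)
  track <- suppressWarnings(simulate_tracks(truth, genome, seed = seed + 2L))
  list(genome = genome, model = model, truth = truth,
       track = track, rpm = normalize_rpm(track))
}
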