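#' Genome sequence collection
#'
#' An ordered collection of named nucleotide sequences with per-sequence
#' circular/linear flags. Residues are uppercase over the alphabet A/C/G/T/N.
#' Circularity is an input flag (plasmid substrates such as pUC19), never
#' auto-detected.
#'
#' @param seqs Named character vector of sequences.
#' @param circular Logical vector (recycled or named) of circularity flags.
#' @return A `genome_sequence` object.
#' @export
genome_sequence <- function(seqs, circular = FALSE) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence name: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid residue in sequence '%s' at position %d",
                 names(seqs)[i], bad[i]))
  }
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence")
  if (!is.null(names(circular))) {
    circ <- stats::setNames(rep(FALSE, length(seqs)), names(seqs))
    unknown <- setdiff(names(circular), names(seqs))
    if (length(unknown)) stop("circular flag for unknown sequence: ",
                              paste(unknown, collapse = ", "))
    circ[names(circular)] <- circular
    circular <- circ
  } else {
    circular <- stats::setNames(rep_len(circular, length(seqs)), names(seqs))
  }
  structure(list(seq = seqs, circular = circular), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence: %d sequence(s), %s nt total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  for (nm in names(x$seq)) {
    cat(sprintf("  %s  %s nt  %s\n", nm,
                format(nchar(x$seq[[nm]]), big.mark = ","),
                if (x$circular[[nm]]) "circular" else "linear"))
  }
  invisible(x)
}

seq_lengths <- function(genome) {
  stats::setNames(nchar(genome$seq), names(genome$seq))
}

# split one sequence into a character vector (per-base access)
seq_chars <- function(genome, name) {
  strsplit(genome$seq[[name]], "", fixed = TRUE)[[1L]]
}

#' Read a FASTA file into a genome
#'
#' Sequence names are taken up to the first whitespace; residues are
#' uppercased and must be A/C/G/T/N. Circularity is assigned from
#' `circular_names` (pUC19-style substrates are circular).
#'
#' @param path FASTA file path.
#' @param circular_names Character vector of sequence names to flag circular.
#' @return A [genome_sequence()].
#' @export
read_fasta <- function(path, circular_names = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(set))
  seqs <- stats::setNames(toupper(as.character(set)), nms)
  if (anyDuplicated(nms)) {
    stop("duplicate sequence name in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  unknown <- setdiff(circular_names, nms)
  if (length(unknown)) stop("circular_names not present in FASTA: ",
                            paste(unknown, collapse = ", "))
  genome_sequence(seqs, circular = stats::setNames(
    rep(TRUE, length(circular_names)), circular_names))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_sequence()].
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Genome G+C fraction
#'
#' Average G+C content over the given sequences, N residues excluded from the
#' denominator. Used as the default logo-correction background.
#'
#' @param genome A [genome_sequence()].
#' @param include Optional character vector of sequence names to restrict to.
#' @return G+C fraction in `[0, 1]`.
#' @export
gc_content <- function(genome, include = NULL) {
  nms <- if (is.null(include)) names(genome$seq) else include
  unknown <- setdiff(nms, names(genome$seq))
  if (length(unknown)) stop("unknown sequence: ", paste(unknown, collapse = ", "))
  gc <- 0; acgt <- 0
  for (nm in nms) {
    f <- Biostrings::alphabetFrequency(Biostrings::DNAString(genome$seq[[nm]]))
    gc <- gc + f[["G"]] + f[["C"]]
    acgt <- acgt + f[["A"]] + f[["C"]] + f[["G"]] + f[["T"]]
  }
  if (acgt == 0) stop("no A/C/G/T residues")
  gc / acgt
}

# reverse complement of a plain character string (N-preserving)
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}
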