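# IUPAC degenerate nucleotide codes. A genome N matches only the pattern
# code N, never any other code.
IUPAC_MATCH <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)

#' Scan a genome for an IUPAC degenerate motif
#'
#' Reports every top-strand match position of an even-length degenerate
#' pattern (length `2m`), including overlapping matches; circular sequences
#' are scanned across the origin. Each match defines a dyad: the genomic
#' position of pattern position `m` (so pattern positions `m` and `m + 1`
#' sit at dyad-relative offsets -1 and +1). Self-reverse-complementary
#' patterns (e.g. GNATNC, CNTANG) need only this single-strand scan.
#' Matching follows dreg-style degenerate semantics, with the restriction
#' that a genome N matches only the pattern code N.
#'
#' @param genome A [genome_sequence()].
#' @param pattern IUPAC string of even length.
#' @return A `motif_site_set`: data.frame (`seqname`, `dyad`) sorted and
#'   unique, with the pattern attached as an attribute.
#' @export
scan_iupac <- function(genome, pattern) {
  pattern <- toupper(pattern)
  pchars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(pchars, names(IUPAC_MATCH))
  if (length(bad)) stop("invalid IUPAC code(s): ",
                        paste(unique(bad), collapse = ", "))
  plen <- length(pchars)
  if (plen < 2L || plen %% 2L != 0L) {
    stop("pattern length must be even and >= 2 (no central dyad otherwise)")
  }
  m <- plen %/% 2L
  rows <- list()
  for (nm in names(genome$seq)) {
    s <- genome$seq[[nm]]
    len <- nchar(s)
    subject <- if (genome$circular[[nm]] && len >= plen) {
      paste0(s, substr(s, 1L, plen - 1L))
    } else {
      s
    }
    hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                     fixed = "subject")
    starts <- Biostrings::start(hits)
    if (length(starts)) {
      # enforce the N rule: genome N only matches pattern N
      schars <- strsplit(subject, "", fixed = TRUE)[[1L]]
      ok <- vapply(starts, function(st) {
        win <- schars[st:(st + plen - 1L)]
        all(win != "N" | pchars == "N")
      }, logical(1))
      starts <- starts[ok]
    }
    if (genome$circular[[nm]]) starts <- starts[starts <= len]
    if (length(starts)) {
      dyads <- starts + m - 1L
      if (genome$circular[[nm]]) dyads <- wrap_index(dyads, len)
      rows[[nm]] <- data.frame(seqname = nm, dyad = sort(unique(dyads)))
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqname = character(), dyad = integer())
  sites <- sites[order(sites$seqname, sites$dyad), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("motif_site_set", "data.frame"),
            pattern = pattern)
}

#' Strand-specific signal averaged over motif-defined dyads
#'
#' For each motif site dyad `g`, reads off top- and bottom-strand track
#' values at dyad-relative offsets -h..+h (offset -1 at `g`) and averages
#' across sites per offset per strand. No reorientation: motif sites are
#' top-strand matches. With a break geometry that puts the top-strand 5' end
#' at the dyad -1 base and the bottom-strand 5' end at +1, a preferred motif
#' shows a top-strand maximum at -1 and a bottom-strand maximum at +1.
#'
#' @param sites A `motif_site_set` from [scan_iupac()].
#' @param track An RPM `strand_track`.
#' @param h Half-width in nt (default 20).
#' @return 2 x 2h matrix, rows `top` / `bottom`, columns offsets; mean RPM.
#' @export
motif_site_profiles <- function(sites, track, h = 20L) {
  if (track$units != "RPM") stop("motif_site_profiles requires RPM units")
  if (nrow(sites) == 0L) stop("empty motif site set")
  offs <- offset_labels(h)
  acc <- array(NA_real_, dim = c(nrow(sites), length(offs), 2L))
  for (i in seq_len(nrow(sites))) {
    nm <- sites$seqname[i]; g <- sites$dyad[i]
    len <- track$lengths[[nm]]; circ <- track$circular[[nm]]
    gidx <- offset_to_position(g, offs)
    if (circ) {
      idx <- wrap_index(gidx, len)
      acc[i, , 1L] <- track$top[[nm]][idx]
      acc[i, , 2L] <- track$bottom[[nm]][idx]
    } else {
      ok <- gidx >= 1L & gidx <= len
      acc[i, ok, 1L] <- track$top[[nm]][gidx[ok]]
      acc[i, ok, 2L] <- track$bottom[[nm]][gidx[ok]]
    }
  }
  slice <- function(k) {
    m <- acc[, , k, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    colMeans(m, na.rm = TRUE)
  }
  out <- rbind(top = slice(1L), bottom = slice(2L))
  colnames(out) <- as.character(offs)
  out
}

#' Enrichment of dyad-proximal signal at motif sites
#'
#' Summarizes a motif-site profile as the mean of the two expected signal
#' positions (top strand at offset -1, bottom strand at +1) over the median
#' of both strands at flank offsets `|k| > flank`, and contrasts a preferred
#' pattern against its non-preferred reverse. Flat profiles give E = 1.
#'
#' @param pref 2 x 2h profile matrix for the preferred pattern
#'   (from [motif_site_profiles()]).
#' @param rev Profile matrix for the non-preferred reverse pattern, same `h`.
#' @param flank Offsets with `|k| > flank` form the background (default 5).
#' @return List with `E_pref`, `E_rev` and `ratio = E_pref / E_rev`.
#' @export
preferred_vs_reverse <- function(pref, rev, flank = 5L) {
  if (!identical(dim(pref), dim(rev)) ||
      !identical(colnames(pref), colnames(rev))) {
    stop("profiles differ in half-width")
  }
  enrich <- function(p) {
    offs <- as.integer(colnames(p))
    centre <- mean(c(p["top", offs == -1L], p["bottom", offs == 1L]))
    fl <- stats::median(c(p["top", abs(offs) > flank],
                          p["bottom", abs(offs) > flank]))
    if (fl == 0) stop("zero flank median: enrichment undefined")
    centre / fl
  }
  E_pref <- enrich(pref)
  E_rev <- enrich(rev)
  list(E_pref = E_pref, E_rev = E_rev, ratio = E_pref / E_rev)
}

#' Write motif sites as BED
#'
#' One-nucleotide features at the dyad -1 base, strand `+` (top-strand
#' scan), 0-based half-open.
#'
#' @param sites A `motif_site_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(chrom = sites$seqname, start = sites$dyad - 1L,
                   end = sites$dyad, name = attr(sites, "pattern"),
                   score = 0L, strand = "+")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
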