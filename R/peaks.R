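#' Threshold-based strand-specific peak calling
#'
#' A top-strand position `q` is a peak iff `top[q] > threshold` and (when the
#' artifact check is on) `top[q] >= top[q - w]`; a bottom-strand position is
#' a peak iff `bottom[q] > threshold` and `bottom[q] >= bottom[q + w]`.
#' The neighbour comparison rejects positions whose reads could be
#' false-positively enriched by incomplete fill-in of the 2-nt 5' overhang:
#' such reads pile up one step away from the genuine end, on the side the
#' fill-in approaches from, so a candidate is compared against the position
#' that would carry the genuine signal were the candidate an artifact.
#' The threshold comparison is strictly greater; the neighbour comparison is
#' greater-or-equal (only strict inferiority rejects). Masked or out-of-range
#' neighbours count as 0; circular sequences wrap.
#'
#' Strand-specific RPM thresholds used for the reference substrates:
#' plasmid 3,000; bacterial genome 10; yeast genome 15
#' (see [peak_threshold_presets]).
#'
#' @param track An RPM `strand_track` (raw counts are refused).
#' @param threshold Strand-specific RPM threshold (exclusive).
#' @param artifact_check Apply the fill-in exclusion rule (default TRUE).
#' @param w Neighbour distance in nt for the artifact comparison (default 1).
#' @return A `peak_set`: data.frame (`seqname`, `pos`, `strand`, `signal`)
#'   sorted by (seqname, pos, strand), with calling parameters attached.
#' @export
call_peaks <- function(track, threshold, artifact_check = TRUE, w = 1L) {
  if (track$units != "RPM") {
    stop("peak calling requires RPM units; run normalize_rpm() first")
  }
  if (threshold <= 0) stop("threshold must be positive")
  if (isTRUE(track$smoothed)) {
    stop("refusing to call peaks on a smoothed (display-only) track")
  }
  rows <- list()
  for (nm in track$seqnames) {
    len <- track$lengths[[nm]]
    circ <- track$circular[[nm]]
    neighbour <- function(v, delta) {
      idx <- seq_len(len) + delta
      if (circ) {
        out <- v[wrap_index(idx, len)]
      } else {
        out <- rep(0, len)
        ok <- idx >= 1L & idx <= len
        out[ok] <- v[idx[ok]]
      }
      out[is.na(out)] <- 0
      out
    }
    for (strand in c("top", "bottom")) {
      v <- track[[strand]][[nm]]
      nb <- neighbour(v, if (strand == "top") -w else +w)
      hit <- !is.na(v) & v > threshold & (!artifact_check | v >= nb)
      if (any(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = nm, pos = which(hit), strand = strand,
          signal = v[hit])
      }
    }
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqname = character(), pos = integer(),
               strand = character(), signal = numeric())
  peaks <- peaks[order(peaks$seqname, peaks$pos, peaks$strand), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"),
            threshold = threshold, artifact_check = artifact_check, w = w)
}

#' Reference strand-specific RPM thresholds
#'
#' Named presets for the three reference substrate classes: a small plasmid
#' map (3,000 RPM), a bacterial genome (10 RPM) and a yeast genome (15 RPM).
#' @export
peak_threshold_presets <- c(plasmid = 3000, bacterial = 10, yeast = 15)

#' Strongest peaks
#'
#' The `n` highest-signal peaks, ties broken deterministically by
#' (seqname, pos, strand) order; all peaks when fewer than `n` exist.
#'
#' @param peaks A `peak_set`.
#' @param n Number of peaks (default 10).
#' @return A `peak_set`.
#' @export
top_peaks <- function(peaks, n = 10L) {
  if (n < 1L) stop("n must be >= 1")
  o <- order(-peaks$signal, peaks$seqname, peaks$pos, peaks$strand)
  sel <- o[seq_len(min(n, nrow(peaks)))]
  out <- peaks[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("threshold", "artifact_check", "w")] <-
    attributes(peaks)[c("threshold", "artifact_check", "w")]
  class(out) <- class(peaks)
  out
}

#' Write peaks as BED6
#'
#' One-nucleotide features, 0-based half-open; name = strand label,
#' score = RPM (BED convention caps display score, so full precision is in
#' the TSV written by [write_peaks_tsv()]). BED strand is `+` for top and
#' `-` for bottom.
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(chrom = peaks$seqname, start = peaks$pos - 1L,
                   end = peaks$pos, name = peaks$strand,
                   score = peaks$signal,
                   strand = ifelse(peaks$strand == "top", "+", "-"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks as TSV with full precision and parameter echo
#'
#' @param peaks A `peak_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  write_tsv_commented(
    as.data.frame(peaks), path,
    header = sprintf("peaks threshold=%g artifact_check=%s w=%d",
                     attr(peaks, "threshold"),
                     attr(peaks, "artifact_check"), attr(peaks, "w")))
}
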