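#' Dyad-oriented sequence windows around peaks
#'
#' Extracts the `2h`-nt sequence window around each peak, oriented so that
#' the assigned 5'-end nucleotide (the base immediately next to the
#' break-proximal adaptor) sits at dyad-relative offset -1 on the read
#' strand. A top-strand peak at `q` yields the genomic window
#' `[q - (h - 1), q + h]` as-is (dyad pair `q, q + 1`); a bottom-strand peak
#' at `q` yields the reverse complement of `[q - h, q + h - 1]`, putting the
#' complement of the base at `q` at offset -1 (dyad pair `q, q - 1` in
#' genomic coordinates). Windows running off a linear sequence or containing
#' N are dropped, with the dropped count reported via `message()` and an
#' attribute.
#'
#' @param peaks A `peak_set`.
#' @param genome A [genome_sequence()].
#' @param h Half-width in nt (default 10; offsets -h..-1, +1..+h).
#' @return Character vector of `2h`-nt oriented windows, with attributes
#'   `n_dropped` and `offsets`.
#' @export
oriented_windows <- function(peaks, genome, h = 10L) {
  if (h < 1L) stop("h must be >= 1")
  if (nrow(peaks) == 0L) stop("empty peak set")
  out <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(peaks))) {
    nm <- peaks$seqname[i]; q <- peaks$pos[i]
    len <- nchar(genome$seq[[nm]])
    circ <- genome$circular[[nm]]
    idx <- if (peaks$strand[i] == "top") {
      (q - h + 1L):(q + h)
    } else {
      (q - h):(q + h - 1L)
    }
    if (circ) {
      idx <- wrap_index(idx, len)
    } else if (idx[1L] < 1L || idx[length(idx)] > len) {
      dropped <- dropped + 1L
      next
    }
    wdw <- paste(seq_chars(genome, nm)[idx], collapse = "")
    if (peaks$strand[i] == "bottom") wdw <- revcomp(wdw)
    if (grepl("N", wdw, fixed = TRUE)) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- wdw
  }
  if (dropped > 0L) {
    message(sprintf("oriented_windows: dropped %d window(s) (edge or N)",
                    dropped))
  }
  structure(out, n_dropped = dropped, offsets = offset_labels(h))
}

#' Per-offset base composition across windows
#'
#' Unweighted base fractions at each dyad-relative offset across equal-length
#' oriented windows (each peak counts once).
#'
#' @param windows Character vector from [oriented_windows()] (equal lengths,
#'   even).
#' @return A `composition_profile` with fractions filled: `offsets`,
#'   `fractions` (4 x 2h, rownames A,C,G,T; columns sum to 1), `n`.
#' @export
base_composition <- function(windows) {
  if (length(windows) < 1L) stop("need at least one window")
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L) stop("windows differ in length")
  if (wlen %% 2L != 0L) stop("window length must be even (no-zero offsets)")
  h <- wlen %/% 2L
  m <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  frac <- sapply(seq_len(wlen), function(j) {
    tab <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab) / nrow(m)
  })
  rownames(frac) <- c("A", "C", "G", "T")
  offs <- offset_labels(h)
  colnames(frac) <- as.character(offs)
  structure(list(offsets = offs, fractions = frac, n = length(windows),
                 background = NULL, scores = NULL, signal = NULL),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile: offsets %+d..%+d, n = %d window(s)%s\n",
              min(x$offsets), max(x$offsets), x$n,
              if (!is.null(x$scores)) sprintf(", background GC = %.3f",
                                              2 * x$background[["G"]]) else ""))
  invisible(x)
}

#' G+C-corrected sequence-logo scores
#'
#' Per-letter relative-entropy logo scores against a GC-split background:
#' `q_G = q_C = background_gc / 2`, `q_A = q_T = (1 - background_gc) / 2`,
#' and `s[b, k] = f[b, k] * log2(f[b, k] / q_b)` (0 where `f = 0`), in bits.
#' The displayed column height is the sum of positive letter scores. The
#' background defaults to the substrate genome's average G+C content; a
#' local-GC override can be supplied when the neighbourhood of mapped sites
#' differs substantially from the genome average.
#'
#' @param profile A `composition_profile` from [base_composition()].
#' @param background_gc Background G+C fraction, strictly inside (0, 1).
#' @return The profile with `background` and `scores` filled.
#' @export
logo_scores <- function(profile, background_gc) {
  if (background_gc <= 0 || background_gc >= 1) {
    stop("background_gc must be strictly between 0 and 1")
  }
  q <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
         G = background_gc / 2, T = (1 - background_gc) / 2)
  f <- profile$fractions
  s <- f * log2(sweep(f, 1, q, "/"))
  s[f == 0] <- 0
  profile$background <- q
  profile$scores <- s
  profile
}

#' Averaged strand-specific signal profile around peaks
#'
#' For each peak, extracts the per-offset signal window on both strands,
#' oriented to the peak: bottom-strand peaks are flipped (offsets mirrored)
#' and strand-swapped so that all peaks align with the read strand as the
#' oriented top. Values are averaged per offset across peaks; masked or
#' off-sequence positions are excluded from the mean.
#'
#' @param peaks A `peak_set`.
#' @param track An RPM `strand_track` on the peak genome.
#' @param h Half-width in nt (default 10).
#' @return 2 x 2h matrix, rows `oriented_top` / `oriented_bottom`, columns
#'   dyad-relative offsets; mean RPM.
#' @export
averaged_profile <- function(peaks, track, h = 10L) {
  if (track$units != "RPM") stop("averaged_profile requires RPM units")
  if (nrow(peaks) == 0L) stop("empty peak set")
  offs <- offset_labels(h)
  acc_top <- matrix(0, nrow = nrow(peaks), ncol = length(offs))
  acc_bot <- matrix(0, nrow = nrow(peaks), ncol = length(offs))
  for (i in seq_len(nrow(peaks))) {
    nm <- peaks$seqname[i]; q <- peaks$pos[i]
    len <- track$lengths[[nm]]; circ <- track$circular[[nm]]
    if (peaks$strand[i] == "top") {
      # dyad pair (q, q+1): offset -k -> q-(k-1), +k -> q+k
      gidx <- offset_to_position(q, offs)
      top_src <- "top"; bot_src <- "bottom"
    } else {
      # dyad pair (q, q-1) genomically; oriented offset -k -> q+(k-1),
      # +k -> q-k; the read (bottom) strand becomes the oriented top
      gidx <- ifelse(offs < 0L, q - offs - 1L, q - offs)
      top_src <- "bottom"; bot_src <- "top"
    }
    grab <- function(strand) {
      v <- rep(NA_real_, length(gidx))
      idx <- gidx
      if (circ) {
        idx <- wrap_index(idx, len)
        v <- track[[strand]][[nm]][idx]
      } else {
        ok <- idx >= 1L & idx <= len
        v[ok] <- track[[strand]][[nm]][idx[ok]]
      }
      v
    }
    acc_top[i, ] <- grab(top_src)
    acc_bot[i, ] <- grab(bot_src)
  }
  out <- rbind(oriented_top = colMeans(acc_top, na.rm = TRUE),
               oriented_bottom = colMeans(acc_bot, na.rm = TRUE))
  colnames(out) <- as.character(offs)
  out
}

#' Write a composition profile (fractions and logo scores) as TSV
#'
#' @param profile A `composition_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(offset = profile$offsets,
                   t(profile$fractions), check.names = FALSE)
  names(df)[2:5] <- paste0("f_", c("A", "C", "G", "T"))
  if (!is.null(profile$scores)) {
    sc <- as.data.frame(t(profile$scores))
    names(sc) <- paste0("s_", c("A", "C", "G", "T"))
    df <- cbind(df, sc)
  }
  write_tsv_commented(
    df, path,
    header = c(sprintf("composition_profile n=%d", profile$n),
               if (!is.null(profile$background))
                 sprintf("background_gc=%.6f", 2 * profile$background[["G"]])))
}
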