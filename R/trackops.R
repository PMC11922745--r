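#' Normalize a raw-count track to RPM
#'
#' Scales every value by `1e6 / total_mapped`. Both strands share the one
#' denominator (a single library), so the sum over all positions and both
#' strands of an unmasked track is exactly one million.
#'
#' @param track A raw-count `strand_track`.
#' @return An RPM `strand_track`.
#' @export
normalize_rpm <- function(track) {
  if (track$units != "raw_counts") {
    stop("track is already in RPM units; normalize_rpm expects raw counts")
  }
  if (!is.finite(track$total_mapped) || track$total_mapped <= 0) {
    stop("total_mapped must be positive")
  }
  f <- 1e6 / track$total_mapped
  track$top <- lapply(track$top, function(v) v * f)
  track$bottom <- lapply(track$bottom, function(v) v * f)
  track$units <- "RPM"
  track
}

#' Apply a mask set to a track
#'
#' Masked positions become `NA` (missing, not zero) on both strands; they are
#' excluded from peak calling, correlation and composition analyses.
#' Whole-sequence exclusions are removed from the track entirely.
#'
#' @param track A `strand_track`.
#' @param masks A [mask_set()].
#' @return The masked `strand_track`.
#' @export
apply_mask <- function(track, masks) {
  keep <- setdiff(track$seqnames, masks$excluded)
  track$seqnames <- keep
  track$lengths <- track$lengths[keep]
  track$circular <- track$circular[keep]
  track$top <- track$top[keep]
  track$bottom <- track$bottom[keep]
  for (nm in intersect(names(masks$intervals), keep)) {
    m <- masks$intervals[[nm]]
    for (i in seq_len(nrow(m))) {
      idx <- m[i, 1L]:m[i, 2L]
      track$top[[nm]][idx] <- NA_real_
      track$bottom[[nm]][idx] <- NA_real_
    }
  }
  track$mask_applied <- TRUE
  track
}

# centred convolution with edge truncation / circular wrap via num/den trick
conv_renorm <- function(v, w, circular) {
  half <- (length(w) - 1L) %/% 2L
  na <- is.na(v)
  x <- ifelse(na, 0, v)
  ind <- as.numeric(!na)
  if (circular) {
    num <- stats::filter(x, w, method = "convolution", sides = 2,
                         circular = TRUE)
    den <- stats::filter(ind, w, method = "convolution", sides = 2,
                         circular = TRUE)
  } else {
    pad <- numeric(half)
    num <- stats::filter(c(pad, x, pad), w, method = "convolution", sides = 2)
    den <- stats::filter(c(pad, ind, pad), w, method = "convolution", sides = 2)
    num <- num[(half + 1L):(half + length(v))]
    den <- den[(half + 1L):(half + length(v))]
  }
  out <- as.numeric(num) / as.numeric(den)
  out[den == 0] <- 0
  out[na] <- NA_real_
  out
}

#' Hann smoothing for display
#'
#' Per-strand convolution with a Hann (raised-cosine) window
#' `w[n] = 0.5 * (1 - cos(2*pi*n / (width - 1)))`, `n = 0..width-1`,
#' normalized to sum 1. Circular sequences wrap; linear sequences (and
#' masked gaps) truncate-and-renormalize. The result is flagged smoothed and
#' is intended for display only, never as peak-calling input.
#'
#' @param track A `strand_track`.
#' @param width Odd window width in nt (default 21).
#' @return The smoothed `strand_track`.
#' @export
smooth_hann <- function(track, width = 21L) {
  if (width %% 2L == 0L || width < 3L) stop("width must be odd and >= 3")
  n <- 0:(width - 1L)
  w <- 0.5 * (1 - cos(2 * pi * n / (width - 1L)))
  w <- w / sum(w)
  for (nm in track$seqnames) {
    circ <- track$circular[[nm]]
    track$top[[nm]] <- conv_renorm(track$top[[nm]], w, circ)
    track$bottom[[nm]] <- conv_renorm(track$bottom[[nm]], w, circ)
  }
  track$smoothed <- TRUE
  track
}

#' Pearson correlation between replicate maps
#'
#' Correlates per-position values, both strands concatenated, across two
#' tracks on the same genome and units. Masked (`NA`) positions on either
#' side are excluded. Optionally restricted to the positions of a peak set
#' (each peak contributes its own strand's value).
#'
#' @param a,b `strand_track`s on the same genome and units.
#' @param positions Optional `peak_set` restricting the comparison.
#' @param transform `"none"` (default) or `"log10"` (`log10(x + 1)`).
#' @return Pearson r.
#' @export
replicate_correlation <- function(a, b, positions = NULL,
                                  transform = c("none", "log10")) {
  transform <- match.arg(transform)
  stop_unless_same_genome(a, b)
  if (!identical(a$units, b$units)) stop("tracks differ in units")
  if (is.null(positions)) {
    va <- unlist(c(a$top, a$bottom), use.names = FALSE)
    vb <- unlist(c(b$top, b$bottom), use.names = FALSE)
  } else {
    pick <- function(tr) {
      vapply(seq_len(nrow(positions)), function(i) {
        st <- if (positions$strand[i] == "top") "top" else "bottom"
        tr[[st]][[positions$seqname[i]]][positions$pos[i]]
      }, numeric(1))
    }
    va <- pick(a); vb <- pick(b)
  }
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  if (transform == "log10") { va <- log10(va + 1); vb <- log10(vb + 1) }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(va, vb)
}
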