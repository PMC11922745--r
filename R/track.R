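#' Strand-separated per-nucleotide signal track
#'
#' Holds one top-strand and one bottom-strand numeric vector per sequence,
#' aligned to the genome (1-based indices internally). Values are
#' non-negative; masked positions are `NA` (missing, distinct from 0).
#' Units are `raw_counts` or `RPM` (reads per million mapped reads); both
#' strands share one normalization denominator (`total_mapped`).
#'
#' @param genome A [genome_sequence()].
#' @param units `"raw_counts"` or `"RPM"`.
#' @param total_mapped Read count used as the RPM denominator.
#' @return A zero-filled `strand_track`.
#' @export
strand_track <- function(genome, units = "raw_counts", total_mapped = 0) {
  units <- match.arg(units, c("raw_counts", "RPM"))
  lens <- seq_lengths(genome)
  zero <- lapply(lens, function(n) numeric(n))
  structure(list(
    seqnames = names(lens), lengths = lens, circular = genome$circular,
    top = zero, bottom = zero,
    units = units, total_mapped = total_mapped,
    mask_applied = FALSE, smoothed = FALSE
  ), class = "strand_track")
}

#' @export
print.strand_track <- function(x, ...) {
  cat(sprintf(paste0("strand_track: %d sequence(s), units=%s, ",
                     "total_mapped=%s%s%s\n"),
              length(x$seqnames), x$units,
              format(x$total_mapped, big.mark = ","),
              if (x$mask_applied) ", masked" else "",
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

track_sum <- function(track, na.rm = TRUE) {
  sum(vapply(track$seqnames, function(nm) {
    sum(track$top[[nm]], na.rm = na.rm) + sum(track$bottom[[nm]], na.rm = na.rm)
  }, numeric(1)))
}

stop_unless_same_genome <- function(a, b) {
  if (!identical(a$seqnames, b$seqnames) || !identical(a$lengths, b$lengths)) {
    stop("tracks are on different genomes")
  }
}

#' Build a raw-count track from read 5'-ends in BED6
#'
#' Each BED record contributes one count at the 5'-most base of the read on
#' its own strand: `start` (0-based) for `+` records onto the top strand,
#' `end - 1` for `-` records onto the bottom strand. This is the nucleotide
#' immediately adjacent to the break-proximal adaptor in TDP2-seq-style
#' libraries. `total_mapped` is set to the number of records.
#'
#' @param path BED6 file.
#' @param genome A [genome_sequence()].
#' @return A raw-count `strand_track`.
#' @export
read_end_bed <- function(path, genome) {
  track <- strand_track(genome)
  if (file.size(path) == 0) return(track)
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  if (ncol(df) < 6L) stop("BED6 requires 6 columns")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  unknown <- setdiff(unique(df$chrom), track$seqnames)
  if (length(unknown)) stop("BED record on unknown sequence: ",
                            paste(unknown, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("BED strand must be + or -")
  lens <- track$lengths[df$chrom]
  if (any(df$start < 0L) || any(df$end > lens) || any(df$start >= df$end)) {
    stop("BED record out of sequence bounds")
  }
  pos <- ifelse(df$strand == "+", df$start + 1L, df$end)  # 1-based assigned base
  for (nm in unique(df$chrom)) {
    sel <- df$chrom == nm
    tp <- pos[sel & df$strand == "+"]
    bp <- pos[sel & df$strand == "-"]
    if (length(tp)) {
      t <- tabulate(tp, nbins = track$lengths[[nm]])
      track$top[[nm]] <- track$top[[nm]] + t
    }
    if (length(bp)) {
      b <- tabulate(bp, nbins = track$lengths[[nm]])
      track$bottom[[nm]] <- track$bottom[[nm]] + b
    }
  }
  track$total_mapped <- nrow(df)
  track
}

# ---- bedGraph pair I/O -------------------------------------------------

bedgraph_runs <- function(v, seqname) {
  # non-zero, non-NA runs as 0-based half-open intervals with a shared value
  keep <- !is.na(v) & v != 0
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  r <- rle(ifelse(is.na(v), NA_real_, v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- !is.na(r$values) & r$values != 0
  data.frame(chrom = seqname, start = starts[sel] - 1L, end = ends[sel],
             value = r$values[sel])
}

write_one_bedgraph <- function(track, strand, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units=%s", track$units), con)
  writeLines(sprintf("# total_mapped=%s",
                     format(track$total_mapped, scientific = FALSE)), con)
  for (nm in track$seqnames) {
    runs <- bedgraph_runs(track[[strand]][[nm]], nm)
    if (nrow(runs)) {
      writeLines(sprintf("%s\t%d\t%d\t%.17g", runs$chrom, runs$start,
                         runs$end, runs$value), con)
    }
  }
  invisible(path)
}

#' Write a track as a strand-separated bedGraph pair
#'
#' One bedGraph per strand, 0-based half-open, zero runs omitted; a commented
#' header carries units and `total_mapped` so that a round-trip read
#' reproduces the track exactly. If the track is masked, masked runs are
#' written to a sidecar BED (`<plus_path>.mask.bed`) rather than as zeros.
#'
#' @param track A `strand_track`.
#' @param plus_path Output path for the top strand.
#' @param minus_path Output path for the bottom strand.
#' @return `c(plus_path, minus_path)`, invisibly.
#' @export
write_track_bedgraph <- function(track, plus_path, minus_path) {
  write_one_bedgraph(track, "top", plus_path)
  write_one_bedgraph(track, "bottom", minus_path)
  if (track$mask_applied) {
    rows <- do.call(rbind, lapply(track$seqnames, function(nm) {
      na <- is.na(track$top[[nm]])
      if (!any(na)) return(NULL)
      r <- rle(na); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      data.frame(chrom = nm, start = starts[r$values] - 1L, end = ends[r$values])
    }))
    if (!is.null(rows)) {
      utils::write.table(rows, paste0(plus_path, ".mask.bed"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(c(plus_path, minus_path))
}

read_one_bedgraph <- function(path, genome, strand, track) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  units <- sub("^# units=", "", grep("^# units=", hdr, value = TRUE))
  tm <- sub("^# total_mapped=", "",
            grep("^# total_mapped=", hdr, value = TRUE))
  if (length(units) != 1L) stop("bedGraph missing units header: ", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body)) {
    df <- utils::read.table(text = body, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"))
    unknown <- setdiff(unique(df$chrom), track$seqnames)
    if (length(unknown)) stop("bedGraph record on unknown sequence: ",
                              paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(df))) {
      nm <- df$chrom[i]
      idx <- (df$start[i] + 1L):df$end[i]
      track[[strand]][[nm]][idx] <- df$value[i]
    }
  }
  list(track = track, units = units, total_mapped = as.numeric(tm))
}

#' Read a strand-separated bedGraph pair
#'
#' @param plus_path Top-strand bedGraph (written by [write_track_bedgraph()]).
#' @param minus_path Bottom-strand bedGraph.
#' @param genome A [genome_sequence()].
#' @param units If given, error when the file header's units differ.
#' @return A `strand_track`.
#' @export
read_track_bedgraph <- function(plus_path, minus_path, genome, units = NULL) {
  track <- strand_track(genome)
  p <- read_one_bedgraph(plus_path, genome, "top", track)
  m <- read_one_bedgraph(minus_path, genome, "bottom", p$track)
  track <- m$track
  if (!identical(p$units, m$units)) stop("strand files disagree on units")
  if (!is.null(units) && !identical(units, p$units)) {
    stop(sprintf("requested units '%s' but file has '%s'", units, p$units))
  }
  track$units <- p$units
  track$total_mapped <- p$total_mapped
  mask_bed <- paste0(plus_path, ".mask.bed")
  if (file.exists(mask_bed)) {
    md <- utils::read.table(mask_bed, sep = "\t",
                            col.names = c("chrom", "start", "end"))
    for (i in seq_len(nrow(md))) {
      idx <- (md$start[i] + 1L):md$end[i]
      track$top[[md$chrom[i]]][idx] <- NA_real_
      track$bottom[[md$chrom[i]]][idx] <- NA_real_
    }
    track$mask_applied <- TRUE
  }
  track
}
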