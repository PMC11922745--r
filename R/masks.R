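#' Mask set
#'
#' Per-sequence genomic intervals to exclude from downstream analyses, plus
#' whole-sequence exclusions (mitochondrial DNA, episomes). Intervals are
#' stored sorted and merged, 1-based closed internally; BED I/O uses the
#' standard 0-based half-open convention.
#'
#' @param intervals Named list of two-column matrices `cbind(start, end)` in
#'   1-based closed coordinates, one element per sequence.
#' @param excluded Character vector of sequence names masked entirely.
#' @param genome A [genome_sequence()] used for bounds checking.
#' @return A `mask_set` object.
#' @export
mask_set <- function(intervals = list(), excluded = character(), genome) {
  lens <- seq_lengths(genome)
  unknown <- setdiff(c(names(intervals), excluded), names(lens))
  if (length(unknown)) stop("mask on unknown sequence: ",
                            paste(unknown, collapse = ", "))
  merged <- lapply(names(intervals), function(nm) {
    m <- intervals[[nm]]
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    if (any(m[, 1L] < 1L) || any(m[, 2L] > lens[[nm]]) || any(m[, 1L] > m[, 2L])) {
      stop("mask interval out of bounds on ", nm)
    }
    ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1L], end = m[, 2L]))
    cbind(start = IRanges::start(ir), end = IRanges::end(ir))
  })
  names(merged) <- names(intervals)
  merged <- Filter(Negate(is.null), merged)
  structure(list(intervals = merged, excluded = unique(excluded)),
            class = "mask_set")
}

#' Build the standard analysis masks
#'
#' Masks `telomere_bp` nucleotides at both ends of every linear sequence
#' (circular sequences have no ends and receive no telomere mask), merges in
#' user intervals (e.g. the rDNA repeat region), and records whole-sequence
#' exclusions (e.g. mitochondrial DNA and episomal plasmids).
#'
#' @param genome A [genome_sequence()].
#' @param telomere_bp Nucleotides to mask at each linear end (default 500).
#' @param intervals Named list of `cbind(start, end)` matrices, 1-based closed.
#' @param excluded Sequence names excluded entirely.
#' @return A [mask_set()].
#' @export
build_masks <- function(genome, telomere_bp = 500L, intervals = list(),
                        excluded = character()) {
  if (telomere_bp < 0L) stop("telomere_bp must be >= 0")
  lens <- seq_lengths(genome)
  ivs <- intervals
  if (telomere_bp > 0L) {
    for (nm in names(lens)) {
      if (genome$circular[[nm]]) next
      tb <- min(telomere_bp, lens[[nm]])
      tel <- rbind(c(1L, tb), c(max(1L, lens[[nm]] - tb + 1L), lens[[nm]]))
      ivs[[nm]] <- rbind(ivs[[nm]], tel)
    }
  }
  mask_set(intervals = ivs, excluded = excluded, genome = genome)
}

#' Total masked length
#'
#' Sum of merged interval lengths (whole-sequence exclusions not counted).
#'
#' @param masks A [mask_set()].
#' @return Total masked nucleotides.
#' @export
masked_length <- function(masks) {
  sum(vapply(masks$intervals, function(m) sum(m[, 2L] - m[, 1L] + 1L),
             numeric(1)))
}

#' Write masks as BED3
#'
#' @param masks A [mask_set()].
#' @param path Output path (0-based half-open BED).
#' @return `path`, invisibly.
#' @export
write_masks_bed <- function(masks, path) {
  rows <- do.call(rbind, lapply(names(masks$intervals), function(nm) {
    m <- masks$intervals[[nm]]
    data.frame(chrom = nm, start = m[, 1L] - 1L, end = m[, 2L])
  }))
  if (is.null(rows)) rows <- data.frame(chrom = character(), start = integer(),
                                        end = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read masks from BED3
#'
#' @param path BED3 file (0-based half-open).
#' @param genome A [genome_sequence()].
#' @param excluded Sequence names excluded entirely.
#' @return A [mask_set()].
#' @export
read_masks_bed <- function(path, genome, excluded = character()) {
  if (file.size(path) == 0) return(mask_set(genome = genome, excluded = excluded))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  ivs <- split(df, df$chrom)
  ivs <- lapply(ivs, function(d) cbind(start = d$start + 1L, end = d$end))
  mask_set(intervals = ivs, excluded = excluded, genome = genome)
}
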