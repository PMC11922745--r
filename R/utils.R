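#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state so
#' that seeded package functions never disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# 1-based circular index wrap
wrap_index <- function(i, len) ((i - 1L) %% len) + 1L

#' Map dyad-relative offsets to genomic positions
#'
#' Dyad-relative labels follow the no-zero convention ..., -2, -1, +1, +2, ...
#' For a dyad pair (g, g+1) (1-based), offset -k maps to g - (k - 1) and
#' offset +k maps to (g + 1) + (k - 1).
#'
#' @param g 1-based genomic position of the relative -1 base.
#' @param offsets Integer offsets (no zero allowed).
#' @return Integer genomic positions (unwrapped; may fall outside a linear
#'   sequence).
#' @export
offset_to_position <- function(g, offsets) {
  if (any(offsets == 0L)) stop("dyad-relative offsets have no zero")
  ifelse(offsets < 0L, g + offsets + 1L, g + offsets)
}

#' Dyad-relative offset labels
#'
#' @param h Half-width in nucleotides.
#' @return Integer vector `c(-h:-1, 1:h)`.
#' @export
offset_labels <- function(h) c(-h:-1, 1:h)

# Write a TSV with commented header lines carrying provenance
write_tsv_commented <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ln in header) writeLines(paste0("# ", ln), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
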