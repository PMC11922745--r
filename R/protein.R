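# Average (isotope-weighted) residue masses in daltons for the 20 standard
# amino acids, plus one water added per chain.
AA_RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0513, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
WATER_MASS <- 18.0153

#' Average protein mass from sequence
#'
#' Sum of standard average residue masses plus one water. Useful for checking
#' predicted complex stoichiometry against size-exclusion or mass-photometry
#' estimates (e.g. a 1:1 heterodimer mass from its two chain sequences).
#'
#' @param aa_sequence One-letter amino-acid string over the 20 standard codes.
#' @return Mass in daltons.
#' @export
#' @examples
#' average_protein_mass("G")  # glycine: 57.0513 + water
average_protein_mass <- function(aa_sequence) {
  if (!is.character(aa_sequence) || length(aa_sequence) != 1L ||
      nchar(aa_sequence) == 0L) {
    stop("aa_sequence must be one non-empty string")
  }
  aa <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(AA_RESIDUE_MASS))
  if (length(bad)) {
    stop("invalid amino-acid letter(s): ", paste(unique(bad), collapse = ", "))
  }
  sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
}
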