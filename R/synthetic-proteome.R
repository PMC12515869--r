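#' Generate a random proteome
#'
#' Draws protein sequences by sampling residues independently from a
#' composition table, with log-normally distributed lengths (minimum 30
#' residues). Used as the sequence background for flanking-window and motif
#' analyses.
#'
#' @param n_proteins Number of proteins (>= 0).
#' @param mean_length Median protein length in residues; lengths are drawn
#'   log-normally around it. Default 480.
#' @param composition Named numeric vector of residue frequencies over the
#'   20 standard amino acids, summing to 1 (within 1e-9). Default
#'   [default_aa_composition()].
#' @param length_sdlog SD of log length. Default 0.6.
#' @param seed Integer seed.
#' @return A data.frame with columns `accession` (unique, `P0001`-style) and
#'   `sequence`.
#' @examples
#' prot <- generate_proteome(5, seed = 1)
#' nchar(prot$sequence)
#' @export
generate_proteome <- function(n_proteins, mean_length = 480,
                              composition = default_aa_composition(),
                              length_sdlog = 0.6, seed = 1L) {
  n_proteins <- assert_count(n_proteins, "n_proteins")
  if (is.null(names(composition)) ||
      !setequal(names(composition), AA_ALPHABET)) {
    stop_validation("'composition' must cover exactly the 20 standard residues")
  }
  if (abs(sum(composition) - 1) > 1e-9) {
    stop_validation("'composition' must sum to 1 (within 1e-9)")
  }
  if (any(composition < 0)) stop_validation("'composition' must be non-negative")
  composition <- composition[AA_ALPHABET]
  if (n_proteins == 0L) {
    return(data.frame(accession = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    lens <- pmax(30L, as.integer(round(rlnorm(n_proteins,
                                              meanlog = log(mean_length),
                                              sdlog = length_sdlog))))
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = composition),
            collapse = "")
    }, character(1))
    data.frame(accession = sprintf("P%04d", seq_len(n_proteins)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}
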