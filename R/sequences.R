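#' The amyloid-beta(1-42) sequence
#'
#' One-letter sequence of the human 42-residue amyloid-beta peptide, the
#' fibril-forming substrate whose surface binding site is being mapped.
#' Residue numbering throughout the package is 1-based on this sequence
#' (so K28 is residue 28, A42 the C-terminus, and the two serines sit at
#' positions 8 and 26).
#'
#' @return A single string of 42 one-letter amino-acid codes.
#' @export
#' @examples
#' nchar(abeta42_sequence())
abeta42_sequence <- function() {
  "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
}

#' Residue table for a peptide sequence
#'
#' @param sequence One-letter amino-acid string; defaults to
#'   [abeta42_sequence()].
#' @return A tibble with `residue_index` (1-based) and `residue_name`
#'   (one-letter code).
#' @export
#' @examples
#' residue_table() |> head()
residue_table <- function(sequence = abeta42_sequence()) {
  letters1 <- strsplit(sequence, "")[[1]]
  tibble::tibble(
    residue_index = seq_along(letters1),
    residue_name = letters1
  )
}
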