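#' The 20 canonical amino-acid one-letter codes
#'
#' Fixed alphabetical order (A, C, D, ..., Y). All pair indexing and feature
#' column layouts are defined over this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Policy for residues outside the canonical 20-letter alphabet
#'
#' Controls how records containing non-standard residue symbols (B, J, O, U,
#' X, Z, '*', ...) are handled. Under `"skip_pairs"` (the default) the record
#' is kept and any residue pair touching a non-standard position is simply
#' excluded from the pair counts; under `"reject_record"` the whole record is
#' excluded during validation.
#'
#' @param nonstandard_action `"skip_pairs"` or `"reject_record"`.
#' @return An `alphabet_policy` object.
#' @export
alphabet_policy <- function(nonstandard_action = c("skip_pairs", "reject_record")) {
  nonstandard_action <- match.arg(nonstandard_action)
  structure(
    list(standard_alphabet = aa_alphabet(),
         nonstandard_action = nonstandard_action),
    class = "alphabet_policy"
  )
}

#' Index of an ordered residue pair
#'
#' Maps an ordered pair of canonical residues to its position in the fixed
#' 400-pair enumeration AA, AC, AD, ..., AY, CA, ..., YY (first residue
#' major, alphabetical ranks).
#'
#' @param a,b Character vectors of single residues (vectorized, recycled).
#' @return Integer vector of 0-based indices in `[0, 400)`.
#' @export
#' @examples
#' pair_index("A", "A") # 0
#' pair_index("Y", "Y") # 399
pair_index <- function(a, b) {
  ra <- match(a, aa_alphabet())
  rb <- match(b, aa_alphabet())
  if (anyNA(ra) || anyNA(rb)) {
    bad <- unique(c(a[is.na(ra)], b[is.na(rb)]))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  20L * (ra - 1L) + (rb - 1L)
}

#' All 400 ordered residue pairs in index order
#'
#' @return Character vector "AA", "AC", ..., "YY" of length 400.
#' @export
pair_labels <- function() {
  ab <- aa_alphabet()
  as.vector(t(outer(ab, ab, paste0)))
}

# residue string -> integer codes 1..20, NA for non-standard symbols
residue_codes <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], aa_alphabet())
}
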