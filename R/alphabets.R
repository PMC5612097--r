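#' Amino-acid alphabets
#'
#' `aa_standard()` returns the 20 standard amino acids in canonical
#' single-letter order. `aa_array()` returns the 18-letter alphabet used for
#' combinatorial array synthesis, i.e. the 20 standard residues minus
#' cysteine and methionine (both are excluded from on-array synthesis because
#' they oxidize during light-directed coupling and storage).
#'
#' @return Character vector of single-letter residue codes.
#' @export
#' @examples
#' aa_standard()
#' aa_array()
aa_standard <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_standard
#' @export
aa_array <- function() {
  setdiff(aa_standard(), c("C", "M"))
}

#' Default forbidden dimer motifs for array library design
#'
#' Ordered two-letter motifs excluded from the combinatorial 5-mer library:
#' His/Arg/Lys adjacencies that interfere with synthesis or create
#' streptavidin-binding artifacts, plus HP and PQ.
#'
#' @return Character vector of 8 dimers.
#' @export
default_forbidden_dimers <- function() {
  c("HR", "RH", "HK", "KH", "RK", "KR", "HP", "PQ")
}

# single source of truth for validating residue vectors
check_alphabet <- function(alphabet, arg = "alphabet") {
  if (!is.character(alphabet) || length(alphabet) < 1) {
    stop(sprintf("`%s` must be a non-empty character vector", arg), call. = FALSE)
  }
  if (any(nchar(alphabet) != 1L) || any(!grepl("^[A-Za-z]$", alphabet))) {
    stop(sprintf("`%s` must contain single letters only", arg), call. = FALSE)
  }
  if (anyDuplicated(alphabet)) {
    stop(sprintf("`%s` contains duplicated letters", arg), call. = FALSE)
  }
  invisible(alphabet)
}
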