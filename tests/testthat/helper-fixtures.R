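# shared fixtures: small alphabets, hand-built signal tables, oracles

tiny_alphabet <- c("A", "G", "Q", "R", "Y", "E", "S", "K")

# a sublibrary spec whose full enumeration is cheap (8^5 = 32,768 peptides)
tiny_library_spec <- function(...) {
  library_spec(alphabet = tiny_alphabet, length = 5,
               forbid_adjacent_repeat = FALSE,
               forbidden_dimers = character(), ...)
}

# direct substring re-check of the exclusion rules, independent of the
# enumeration/counting code paths
violates_rules <- function(peptides, spec) {
  vapply(peptides, function(p) {
    ch <- strsplit(p, "")[[1]]
    if (spec$forbid_adjacent_repeat &&
        any(ch[-1] == ch[-length(ch)])) return(TRUE)
    dimers <- paste0(ch[-length(ch)], ch[-1])
    any(dimers %in% spec$forbidden_dimers)
  }, logical(1), USE.NAMES = FALSE)
}

# brute-force oracle: enumerate all strings and apply the substring re-check
brute_force_count <- function(spec) {
  g <- expand.grid(rep(list(spec$alphabet), spec$length),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  seqs <- do.call(paste0, g)
  sum(!violates_rules(seqs, spec))
}

# a two-replicate signal table from explicit (peptide, S1, S2) triples
signal_table_from_pairs <- function(peptide, s1, s2) {
  n <- length(peptide)
  tibble::tibble(
    feature_id = c(paste0(peptide, "_R1"), paste0(peptide, "_R2")),
    peptide = rep(peptide, 2),
    replicate = rep(1:2, each = n),
    intensity = c(s1, s2)
  )
}

# random small library spec for property tests
random_small_spec <- function() {
  a <- sample(LETTERS[1:8], sample(3:6, 1))
  len <- sample(1:5, 1)
  n_forb <- sample(0:3, 1)
  forb <- character(0)
  if (n_forb > 0) {
    all_dimers <- as.vector(outer(a, a, paste0))
    forb <- sample(all_dimers, min(n_forb, length(all_dimers)))
  }
  library_spec(alphabet = a, length = len,
               forbid_adjacent_repeat = sample(c(TRUE, FALSE), 1),
               forbidden_dimers = forb)
}
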