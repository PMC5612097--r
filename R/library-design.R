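#' Specify a combinatorial peptide library with exclusion rules
#'
#' A library specification describes every peptide of a fixed length over an
#' amino-acid alphabet, subject to two kinds of local exclusion rules:
#' a ban on adjacent identical residues (which also bans all longer
#' homopolymer runs), and a set of forbidden ordered dimers that may not
#' occur anywhere in the sequence. The defaults reproduce the ultra-dense
#' 5-mer array design: 18 amino acids (no Cys/Met), no adjacent repeats, and
#' the eight forbidden dimers HR, RH, HK, KH, RK, KR, HP, PQ, which yields
#' 1,360,732 unique 5-mers.
#'
#' @param alphabet Character vector of unique single-letter residue codes.
#'   The order of this vector defines the lexicographic enumeration order.
#' @param length Positive integer peptide length.
#' @param forbid_adjacent_repeat Ban two adjacent identical residues?
#' @param forbidden_dimers Character vector of ordered two-letter motifs that
#'   must not occur as contiguous substrings. May be empty.
#' @return An object of class `library_spec`.
#' @seealso [enumerate_library()], [count_library()]
#' @export
#' @examples
#' spec <- library_spec()
#' count_library(spec)
library_spec <- function(alphabet = aa_array(),
                         length = 5L,
                         forbid_adjacent_repeat = TRUE,
                         forbidden_dimers = default_forbidden_dimers()) {
  check_alphabet(alphabet)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  forbidden_dimers <- as.character(forbidden_dimers)
  if (length(forbidden_dimers) > 0) {
    if (any(nchar(forbidden_dimers) != 2L)) {
      stop("`forbidden_dimers` must all be two-letter motifs", call. = FALSE)
    }
    letters_used <- unique(unlist(strsplit(forbidden_dimers, "")))
    if (!all(letters_used %in% alphabet)) {
      stop("`forbidden_dimers` must be drawn from the alphabet", call. = FALSE)
    }
  }
  structure(
    list(
      alphabet = alphabet,
      length = length,
      forbid_adjacent_repeat = isTRUE(forbid_adjacent_repeat),
      forbidden_dimers = unique(forbidden_dimers)
    ),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  cat("<library_spec>\n")
  cat("  alphabet: ", paste(x$alphabet, collapse = ""),
      " (", length(x$alphabet), " letters)\n", sep = "")
  cat("  length: ", x$length, "\n", sep = "")
  cat("  adjacent-repeat ban: ", x$forbid_adjacent_repeat, "\n", sep = "")
  cat("  forbidden dimers: ",
      if (length(x$forbidden_dimers)) paste(x$forbidden_dimers, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

# 0/1 matrix of allowed residue transitions a -> b
transition_matrix <- function(spec) {
  a <- spec$alphabet
  m <- matrix(1, length(a), length(a), dimnames = list(a, a))
  if (spec$forbid_adjacent_repeat) diag(m) <- 0
  for (d in spec$forbidden_dimers) {
    m[substr(d, 1, 1), substr(d, 2, 2)] <- 0
  }
  m
}

#' Enumerate every peptide admitted by a library specification
#'
#' Generates all sequences of the specified length over the alphabet,
#' discards those violating the adjacent-repeat ban or containing a
#' forbidden dimer, and returns the survivors in lexicographic order
#' (most-significant position first, ordered by the alphabet vector).
#' With the default specification this reproduces the 1,360,732-peptide
#' 5-mer array library.
#'
#' @param spec A [library_spec()].
#' @return A tibble with columns `peptide_id` (1-based integer in
#'   enumeration order) and `peptide`. The generating rule is recorded in
#'   the `provenance` attribute.
#' @export
#' @examples
#' nrow(enumerate_library(library_spec(alphabet = c("A", "G", "S"), length = 3)))
enumerate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  a <- spec$alphabet
  L <- spec$length
  # expand.grid varies the first factor fastest, so feed positions reversed
  # to obtain lexicographic order with position 1 most significant
  grid <- expand.grid(rep(list(a), L), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)[, rev(seq_len(L)), drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  if (L >= 2) {
    trans <- transition_matrix(spec)
    for (i in seq_len(L - 1L)) {
      keep <- keep & trans[cbind(m[, i], m[, i + 1L])] == 1
    }
  }
  kept <- m[keep, , drop = FALSE]
  peptides <- do.call(paste0, lapply(seq_len(L), function(j) kept[, j]))
  out <- tibble::tibble(
    peptide_id = seq_along(peptides),
    peptide = as.character(peptides)
  )
  attr(out, "provenance") <- sprintf(
    "exhaustive length-%d library over {%s}%s%s", L,
    paste(a, collapse = ""),
    if (spec$forbid_adjacent_repeat) ", adjacent repeats banned" else "",
    if (length(spec$forbidden_dimers))
      paste0(", forbidden dimers ", paste(spec$forbidden_dimers, collapse = "/"))
    else ""
  )
  out
}

#' Count a constrained library without enumerating it
#'
#' Computes the exact cardinality of [enumerate_library()] by dynamic
#' programming over the residue-transition matrix (a transfer-matrix path
#' count): the number of admitted sequences equals the total number of
#' length-`length` walks through the allowed-transition graph. Runs in
#' `O(length * |alphabet|^2)` regardless of library size.
#'
#' @inheritParams enumerate_library
#' @return The library size as a double (exact for all realistic libraries;
#'   counts are integer-valued).
#' @export
#' @examples
#' count_library(library_spec()) # 1360732
count_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  n <- length(spec$alphabet)
  if (spec$length == 1L) return(as.double(n))
  trans <- transition_matrix(spec)
  # paths[b] = number of admitted prefixes ending in residue b
  paths <- rep(1, n)
  for (i in seq_len(spec$length - 1L)) {
    paths <- as.vector(crossprod(trans, paths))
  }
  sum(paths)
}

#' Specify a maturation (flank-extension) library
#'
#' A maturation library extends a fixed core motif with every combination of
#' `n_flank` residues on both termini, producing
#' `|flank_alphabet| ^ (2 * n_flank)` sequences with the core invariant.
#' Extending a 5-mer by two residues per terminus over the full 20-letter
#' alphabet yields the 160,000 9-mers used to refine array-discovered
#' recognition motifs.
#'
#' @param core Core peptide sequence (kept invariant).
#' @param n_flank Residues added per terminus (default 2).
#' @param flank_alphabet Alphabet for the flanks (default all 20 standard
#'   amino acids; maturation synthesis re-admits Cys and Met).
#' @return An object of class `maturation_spec`.
#' @export
maturation_spec <- function(core, n_flank = 2L, flank_alphabet = aa_standard()) {
  if (!is.character(core) || length(core) != 1L || nchar(core) < 1L) {
    stop("`core` must be a single non-empty peptide string", call. = FALSE)
  }
  core <- toupper(core)
  if (!grepl("^[A-Z]+$", core)) {
    stop("`core` must contain letters only", call. = FALSE)
  }
  check_alphabet(flank_alphabet, "flank_alphabet")
  n_flank <- as.integer(n_flank)
  if (is.na(n_flank) || n_flank < 1L) {
    stop("`n_flank` must be >= 1", call. = FALSE)
  }
  structure(
    list(core = core, n_flank = n_flank, flank_alphabet = flank_alphabet),
    class = "maturation_spec"
  )
}

#' Design a maturation library around a core motif
#'
#' @param spec A [maturation_spec()].
#' @return A tibble with columns `peptide_id` and `peptide`; every peptide
#'   contains the core at offset `n_flank`.
#' @export
#' @examples
#' nrow(design_maturation(maturation_spec("YRYRQ"))) # 160000
design_maturation <- function(spec) {
  stopifnot(inherits(spec, "maturation_spec"))
  a <- spec$flank_alphabet
  k <- spec$n_flank
  one_flank <- function() {
    g <- expand.grid(rep(list(a), k), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    m <- as.matrix(g)[, rev(seq_len(k)), drop = FALSE]
    if (k == 1L) as.vector(m) else apply(m, 1L, paste0, collapse = "")
  }
  flanks <- one_flank()
  peptides <- as.vector(t(outer(flanks, flanks,
                                function(n, c) paste0(n, spec$core, c))))
  out <- tibble::tibble(peptide_id = seq_along(peptides), peptide = peptides)
  attr(out, "provenance") <- sprintf(
    "maturation of core %s with %d-residue flanks over {%s}",
    spec$core, k, paste(a, collapse = "")
  )
  out
}

#' Design a single/double substitution-scan library
#'
#' Generates every unique sequence at Hamming distance 1 up to `max_subs`
#' from a parent peptide, substituting with all residues of the alphabet.
#' For a length-L parent and alphabet size A the counts are closed-form:
#' singles `L * (A - 1)`, doubles `choose(L, 2) * (A - 1)^2`.
#'
#' @param peptide Parent peptide sequence.
#' @param max_subs Maximum substitutions, 1 or 2.
#' @param alphabet Substitution alphabet (default all 20 standard residues).
#' @param include_parent Also include the unmodified parent? Default `FALSE`.
#' @return A tibble with columns `peptide_id`, `peptide`, and `n_subs`
#'   (Hamming distance from the parent).
#' @export
#' @examples
#' nrow(design_substitution_scan("YRYRQYRYR", max_subs = 1)) # 171
design_substitution_scan <- function(peptide, max_subs = 2L,
                                     alphabet = aa_standard(),
                                     include_parent = FALSE) {
  if (!is.character(peptide) || length(peptide) != 1L || nchar(peptide) < 1L) {
    stop("`peptide` must be a single non-empty string", call. = FALSE)
  }
  peptide <- toupper(peptide)
  check_alphabet(alphabet)
  max_subs <- as.integer(max_subs)
  if (!max_subs %in% c(1L, 2L)) {
    stop("`max_subs` must be 1 or 2", call. = FALSE)
  }
  L <- nchar(peptide)
  if (max_subs > L) {
    stop("`max_subs` exceeds the peptide length", call. = FALSE)
  }
  chars <- strsplit(peptide, "")[[1]]

  singles <- character(0)
  for (i in seq_len(L)) {
    for (r in setdiff(alphabet, chars[i])) {
      v <- chars
      v[i] <- r
      singles <- c(singles, paste0(v, collapse = ""))
    }
  }
  variants <- tibble::tibble(peptide = unique(singles), n_subs = 1L)

  if (max_subs >= 2L && L >= 2L) {
    pairs <- utils::combn(L, 2L)
    doubles <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      ri <- setdiff(alphabet, chars[i])
      rj <- setdiff(alphabet, chars[j])
      combo <- expand.grid(ri = ri, rj = rj, stringsAsFactors = FALSE)
      seqs <- vapply(seq_len(nrow(combo)), function(q) {
        v <- chars
        v[i] <- combo$ri[q]; v[j] <- combo$rj[q]
        paste0(v, collapse = "")
      }, character(1))
      doubles[[p]] <- seqs
    }
    doubles <- setdiff(unique(unlist(doubles)), variants$peptide)
    variants <- dplyr::bind_rows(
      variants,
      tibble::tibble(peptide = doubles, n_subs = 2L)
    )
  }
  if (include_parent) {
    variants <- dplyr::bind_rows(
      tibble::tibble(peptide = peptide, n_subs = 0L), variants
    )
  }
  out <- dplyr::mutate(variants, peptide_id = dplyr::row_number(),
                       .before = "peptide")
  attr(out, "provenance") <- sprintf(
    "substitution scan of %s, up to %d substitutions over {%s}",
    peptide, max_subs, paste(alphabet, collapse = "")
  )
  out
}

#' Specify synthesis linkers
#'
#' On-array peptides are flanked on both termini by short linkers synthesized
#' from a residue mixture; the default is the 3-residue Gly/Ser 3:1 mixture
#' used on ultra-dense arrays. Linkers are a synthesis detail: all downstream
#' analysis keys on the un-linkered core peptide.
#'
#' @param linker_length Residues per terminus (default 3).
#' @param composition Named numeric vector of residue probabilities summing
#'   to 1 (default `c(G = 0.75, S = 0.25)`).
#' @return An object of class `linker_spec`.
#' @export
linker_spec <- function(linker_length = 3L,
                        composition = c(G = 0.75, S = 0.25)) {
  linker_length <- as.integer(linker_length)
  if (is.na(linker_length) || linker_length < 0L) {
    stop("`linker_length` must be >= 0", call. = FALSE)
  }
  if (is.null(names(composition)) || any(names(composition) == "") ||
      any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    stop("`composition` must be a named probability vector summing to 1",
         call. = FALSE)
  }
  check_alphabet(names(composition), "names(composition)")
  structure(
    list(linker_length = linker_length, composition = composition),
    class = "linker_spec"
  )
}

#' Attach sampled synthesis linkers to peptides
#'
#' Draws concrete N- and C-terminal linkers position-wise from the linker
#' composition for each peptide. The result keeps the core `peptide` column
#' unchanged (downstream analysis identity) and adds `linker_n`, `linker_c`,
#' and the assembled `full_sequence`.
#'
#' @param peptides A tibble with a `peptide` column (e.g. from
#'   [enumerate_library()]) or a character vector.
#' @param linker A [linker_spec()].
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @return The input tibble with `linker_n`, `linker_c`, `full_sequence`.
#' @export
attach_linkers <- function(peptides, linker = linker_spec(), seed = 1L) {
  tbl <- as_peptide_tbl(peptides)
  stopifnot(inherits(linker, "linker_spec"))
  n <- nrow(tbl)
  k <- linker$linker_length
  residues <- names(linker$composition)
  set.seed(as.integer(seed))
  draw <- function() {
    if (k == 0L) return(rep("", n))
    m <- matrix(
      sample(residues, n * k, replace = TRUE, prob = linker$composition),
      nrow = n
    )
    if (k == 1L) as.vector(m) else apply(m, 1L, paste0, collapse = "")
  }
  tbl$linker_n <- draw()
  tbl$linker_c <- draw()
  tbl$full_sequence <- paste0(tbl$linker_n, tbl$peptide, tbl$linker_c)
  tbl
}

# accept either a peptide tibble or a bare character vector
as_peptide_tbl <- function(peptides) {
  if (is.character(peptides)) {
    return(tibble::tibble(peptide_id = seq_along(peptides),
                          peptide = peptides))
  }
  if (is.data.frame(peptides) && "peptide" %in% names(peptides)) {
    tbl <- tibble::as_tibble(peptides)
    if (!"peptide_id" %in% names(tbl)) {
      tbl <- dplyr::mutate(tbl, peptide_id = dplyr::row_number(),
                           .before = 1L)
    }
    return(tbl)
  }
  stop("`peptides` must be a character vector or a tibble with a `peptide` column",
       call. = FALSE)
}
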