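test_that("counting and enumeration agree with closed forms on the default design", {
  spec <- library_spec()
  expect_equal(length(spec$alphabet), 18)
  expect_false(any(c("C", "M") %in% spec$alphabet))

  # unconstrained and repeat-ban-only counts have closed forms
  free <- library_spec(forbid_adjacent_repeat = FALSE,
                       forbidden_dimers = character())
  expect_equal(count_library(free), 18^5)
  norep <- library_spec(forbidden_dimers = character())
  expect_equal(count_library(norep), 18 * 17^4)

  # length-2 default: all non-repeating dimers minus the 8 forbidden ones
  len2 <- library_spec(length = 2)
  expect_equal(count_library(len2), 18 * 17 - 8)
  expect_equal(nrow(enumerate_library(len2)), 298)

  # length 1: no transitions constrained
  expect_equal(count_library(library_spec(length = 1)), 18)
})

test_that("transfer-matrix count matches the enumeration oracle on random specs", {
  set.seed(42)
  for (rep in 1:40) {
    spec <- random_small_spec()
    expect_equal(count_library(spec), nrow(enumerate_library(spec)),
                 info = paste("alphabet", paste(spec$alphabet, collapse = ""),
                              "len", spec$length,
                              "forb", paste(spec$forbidden_dimers, collapse = ",")))
  }
})

test_that("every enumerated peptide passes a direct substring re-check", {
  spec <- library_spec(alphabet = c("A", "G", "H", "P", "Q", "R"), length = 4,
                       forbidden_dimers = c("HR", "RH", "HP", "PQ"))
  lib <- enumerate_library(spec)
  expect_false(any(violates_rules(lib$peptide, spec)))
  expect_false(anyDuplicated(lib$peptide) > 0)
  # lexicographic order in the alphabet ordering
  expect_equal(lib$peptide, sort(lib$peptide))
  expect_equal(nrow(lib), brute_force_count(spec))
})

test_that("removing an exclusion rule never decreases the count", {
  set.seed(7)
  for (rep in 1:15) {
    spec <- random_small_spec()
    n_full <- count_library(spec)
    if (length(spec$forbidden_dimers) > 0) {
      relaxed <- library_spec(spec$alphabet, spec$length,
                              spec$forbid_adjacent_repeat,
                              spec$forbidden_dimers[-1])
      expect_gte(count_library(relaxed), n_full)
    }
    if (spec$forbid_adjacent_repeat) {
      relaxed <- library_spec(spec$alphabet, spec$length,
                              FALSE, spec$forbidden_dimers)
      expect_gte(count_library(relaxed), n_full)
    }
  }
})

test_that("maturation design produces exactly the flank product, core invariant", {
  mat <- design_maturation(maturation_spec("YRYRQ", n_flank = 2))
  expect_equal(nrow(mat), 160000)
  expect_true(all(substr(mat$peptide, 3, 7) == "YRYRQ"))
  expect_true("AAYRYRQAA" %in% mat$peptide)
  expect_false(anyDuplicated(mat$peptide) > 0)

  small <- design_maturation(
    maturation_spec("Q", n_flank = 1, flank_alphabet = c("A", "G"))
  )
  expect_setequal(small$peptide, c("AQA", "AQG", "GQA", "GQG"))
})

test_that("substitution scans match closed-form and brute-force counts", {
  # closed form for a 9-mer over 20 residues
  singles <- design_substitution_scan("YRYRQYRYR", max_subs = 1)
  expect_equal(nrow(singles), 9 * 19)
  both <- design_substitution_scan("YRYRQYRYR", max_subs = 2)
  expect_equal(nrow(both), 9 * 19 + choose(9, 2) * 19^2)
  expect_false("YRYRQYRYR" %in% both$peptide)
  expect_true("YRYRQYRYR" %in%
                design_substitution_scan("YRYRQYRYR", max_subs = 1,
                                         include_parent = TRUE)$peptide)

  # brute-force oracle on a tiny case: all strings at Hamming distance <= 2
  parent <- "AGQ"
  alpha <- c("A", "G", "Q", "R")
  all_seqs <- do.call(paste0, expand.grid(rep(list(alpha), 3),
                                          stringsAsFactors = FALSE))
  hd <- vapply(all_seqs, function(s) {
    sum(strsplit(s, "")[[1]] != strsplit(parent, "")[[1]])
  }, numeric(1))
  scan <- design_substitution_scan(parent, max_subs = 2, alphabet = alpha)
  expect_setequal(scan$peptide, all_seqs[hd >= 1 & hd <= 2])

  expect_setequal(
    design_substitution_scan("Q", max_subs = 1, alphabet = c("A", "Q"))$peptide,
    "A"
  )
  expect_error(design_substitution_scan("Q", max_subs = 2,
                                        alphabet = c("A", "Q")),
               "exceeds")
})

test_that("linker attachment is seed-reproducible and follows the composition", {
  peps <- enumerate_library(tiny_library_spec())[1:10000, ]
  a <- attach_linkers(peps, linker_spec(), seed = 11)
  b <- attach_linkers(peps, linker_spec(), seed = 11)
  expect_identical(a, b)
  expect_equal(a$peptide, peps$peptide)  # core identity untouched
  expect_true(all(nchar(a$full_sequence) == 5 + 6))

  # degenerate composition
  g <- attach_linkers(peps[1:5, ], linker_spec(composition = c(G = 1)), seed = 1)
  expect_true(all(g$linker_n == "GGG" & g$linker_c == "GGG"))

  # position-wise Gly fraction within 3 binomial standard errors of 0.75
  chars <- do.call(rbind, strsplit(a$linker_n, ""))
  p_hat <- colMeans(chars == "G")
  se <- sqrt(0.75 * 0.25 / nrow(chars))
  expect_true(all(abs(p_hat - 0.75) < 3 * se))
})

test_that("specification validation rejects malformed inputs", {
  expect_error(library_spec(alphabet = c("A", "A")), "duplicated")
  expect_error(library_spec(alphabet = c("A", "1")), "single letters")
  expect_error(library_spec(length = 0), "positive")
  expect_error(library_spec(forbidden_dimers = "XY"), "alphabet")
  expect_error(linker_spec(composition = c(G = 0.5, S = 0.2)), "summing to 1")
  expect_error(maturation_spec(""), "non-empty")
})
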