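#' Replicate-concordance filter specification
#'
#' Duplicate-synthesized arrays carry two on-array copies of every peptide;
#' surface imperfections inflate single copies. The concordance statistic
#' `|(S1 - S2) / (S1 + S2)|` flags such features: peptides whose statistic
#' strictly exceeds the threshold (default 0.2) are excluded from analysis.
#'
#' @param threshold Positive exclusion threshold (default 0.2).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(threshold = 0.2) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a positive number", call. = FALSE)
  }
  structure(list(threshold = threshold,
                 statistic = "abs((S1 - S2) / (S1 + S2))"),
            class = "filter_spec")
}

#' Concordance statistic of two replicate intensities
#'
#' @param s1,s2 Nonnegative replicate intensities (vectorized).
#' @return `|(s1 - s2) / (s1 + s2)|`; `NA` where both are zero.
#' @export
#' @examples
#' concordance_statistic(100, 200) # 1/3
concordance_statistic <- function(s1, s2) {
  out <- abs((s1 - s2) / (s1 + s2))
  out[s1 + s2 == 0] <- NA_real_
  out
}

#' Filter a signal table by replicate concordance
#'
#' Removes peptides whose replicate pair fails the concordance criterion
#' `|(S1 - S2)/(S1 + S2)| > threshold` (strict inequality: a statistic
#' exactly at the threshold is retained). Peptides with both replicates zero
#' (undefined statistic) are also removed. The returned table keeps the
#' original long format, restricted to retained peptides; the exclusions,
#' with their replicate intensities and statistic, are attached as the
#' `exclusions` attribute.
#'
#' @param table A signal table with exactly two replicates per peptide
#'   (columns `peptide`, `replicate`, `intensity`).
#' @param spec A [filter_spec()].
#' @return The filtered signal table (tibble), with attribute `exclusions`:
#'   a tibble of (peptide, S1, S2, statistic, reason).
#' @export
concordance_filter <- function(table, spec = filter_spec()) {
  stopifnot(is.data.frame(table),
            all(c("peptide", "replicate", "intensity") %in% names(table)),
            inherits(spec, "filter_spec"))
  counts <- dplyr::count(table, .data$peptide)
  bad <- counts$peptide[counts$n != 2L]
  if (length(bad) > 0) {
    stop(sprintf(
      "concordance filtering needs exactly 2 replicates per peptide; violated by: %s%s",
      paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""
    ), call. = FALSE)
  }
  wide <- table |>
    dplyr::arrange(.data$peptide, .data$replicate) |>
    dplyr::summarise(S1 = .data$intensity[1], S2 = .data$intensity[2],
                     .by = "peptide") |>
    dplyr::mutate(statistic = concordance_statistic(.data$S1, .data$S2))
  excluded <- wide |>
    dplyr::filter(is.na(.data$statistic) | .data$statistic > spec$threshold) |>
    dplyr::mutate(reason = dplyr::if_else(is.na(.data$statistic),
                                          "zero_signal", "discordant"))
  out <- dplyr::filter(table, !(.data$peptide %in% excluded$peptide))
  out <- tibble::as_tibble(out)
  attr(out, "exclusions") <- excluded
  attr(out, "filter_threshold") <- spec$threshold
  out
}

#' Rank peptides by mean replicate intensity
#'
#' Averages intensity over replicates per peptide (arithmetic mean of the
#' on-array copies), sorts in descending order, and flags the top `k`.
#' Ties in mean intensity are broken lexicographically by sequence, so the
#' ranking is a deterministic permutation.
#'
#' @param table A (typically filtered) signal table.
#' @param k Selection size (default 22, the number of peptides tagged in a
#'   substrate-discovery plot).
#' @param enzyme Optional enzyme label stored on the result.
#' @return A ranked profile: tibble of (peptide, mean_intensity, rank,
#'   top_k), with attributes `k` and `enzyme`.
#' @export
rank_peptides <- function(table, k = 22L, enzyme = NULL) {
  stopifnot(is.data.frame(table),
            all(c("peptide", "intensity") %in% names(table)))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)
  prof <- table |>
    dplyr::summarise(mean_intensity = mean(.data$intensity),
                     .by = "peptide") |>
    dplyr::arrange(dplyr::desc(.data$mean_intensity), .data$peptide) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  top_k = .data$rank <= k)
  if (k > nrow(prof)) {
    stop(sprintf("`k` (%d) exceeds the number of peptides (%d)",
                 k, nrow(prof)), call. = FALSE)
  }
  attr(prof, "k") <- k
  attr(prof, "enzyme") <- enzyme
  prof
}

#' Average two per-array profiles of a concentration pair
#'
#' For a Lys-substrate screen run at two enzyme concentrations, each array is
#' filtered separately and the per-array mean intensities are then averaged
#' across arrays. Peptides failing the concordance filter on either array
#' are excluded from the pair analysis.
#'
#' @param pair A named list of two signal tables (as returned by
#'   [simulate_concentration_pair()]).
#' @param spec A [filter_spec()] applied per array.
#' @return A signal-table-shaped tibble with one pseudo-replicate per array
#'   (the per-array mean), restricted to peptides passing both filters;
#'   feed it to [rank_peptides()].
#' @export
average_concentration_pair <- function(pair, spec = filter_spec()) {
  stopifnot(is.list(pair), length(pair) == 2L)
  filt <- lapply(pair, concordance_filter, spec = spec)
  means <- lapply(seq_along(filt), function(i) {
    filt[[i]] |>
      dplyr::summarise(intensity = mean(.data$intensity), .by = "peptide") |>
      dplyr::mutate(replicate = i)
  })
  common <- intersect(means[[1]]$peptide, means[[2]]$peptide)
  dplyr::bind_rows(means) |>
    dplyr::filter(.data$peptide %in% common) |>
    dplyr::mutate(feature_id = sprintf("A%d_%s", .data$replicate, .data$peptide)) |>
    dplyr::select("feature_id", "peptide", "replicate", "intensity")
}

#' Cross-enzyme reactivity of one enzyme's top substrates
#'
#' Locates the top-k substrates of enzyme A within the signal distribution of
#' enzyme B: for each of A's top-k peptides, computes its percentile in B's
#' mean-intensity distribution (fraction of B's peptides with strictly lower
#' mean, with a midpoint correction for ties, times 100). Orthogonal enzymes
#' leave A's best substrates in the midfield of B's distribution; a
#' cross-reactive enzyme pushes them toward the top.
#'
#' @param profile_a Ranked profile of enzyme A (from [rank_peptides()]).
#' @param table_b Signal table of enzyme B (filtered).
#' @param k Number of A's top peptides to trace (default: profile attribute).
#' @return An object of class `cross_reactivity_report`: list with
#'   `percentiles` (tibble of peptide, percentile, missing) and `summary`
#'   (median, IQR bounds, n_missing). Peptides absent from B are reported as
#'   missing, never silently dropped.
#' @export
cross_reactivity <- function(profile_a, table_b, k = NULL) {
  stopifnot(is.data.frame(profile_a),
            all(c("peptide", "rank") %in% names(profile_a)),
            is.data.frame(table_b),
            all(c("peptide", "intensity") %in% names(table_b)))
  if (is.null(k)) k <- attr(profile_a, "k") %||% 22L
  top <- profile_a$peptide[profile_a$rank <= k]
  means_b <- table_b |>
    dplyr::summarise(mean_intensity = mean(.data$intensity), .by = "peptide")
  vals <- means_b$mean_intensity
  n <- length(vals)
  pct <- vapply(top, function(p) {
    i <- match(p, means_b$peptide)
    if (is.na(i)) return(NA_real_)
    x <- means_b$mean_intensity[i]
    100 * (sum(vals < x) + 0.5 * sum(vals == x)) / n
  }, numeric(1))
  percentiles <- tibble::tibble(
    peptide = top,
    percentile = unname(pct),
    missing = is.na(pct)
  )
  present <- percentiles$percentile[!percentiles$missing]
  qs <- if (length(present)) stats::quantile(present, c(0.25, 0.5, 0.75))
        else rep(NA_real_, 3)
  structure(
    list(
      percentiles = percentiles,
      summary = tibble::tibble(
        median_percentile = unname(qs[2]),
        iqr_lower = unname(qs[1]),
        iqr_upper = unname(qs[3]),
        n_top = length(top),
        n_missing = sum(percentiles$missing),
        n_b = n
      )
    ),
    class = "cross_reactivity_report"
  )
}

#' @export
print.cross_reactivity_report <- function(x, ...) {
  s <- x$summary
  cat("<cross_reactivity_report>\n")
  cat(sprintf("  %d top peptides traced into a %d-peptide distribution (%d missing)\n",
              s$n_top, s$n_b, s$n_missing))
  cat(sprintf("  median percentile %.1f (IQR %.1f-%.1f)\n",
              s$median_percentile, s$iqr_lower, s$iqr_upper))
  invisible(x)
}

#' @method tidy cross_reactivity_report
#' @export
tidy.cross_reactivity_report <- function(x, ...) x$percentiles

#' @method glance cross_reactivity_report
#' @export
glance.cross_reactivity_report <- function(x, ...) x$summary

#' Per-position residue enrichment of a top-k selection
#'
#' Compares the residue composition of the top-k peptides, position by
#' position, with a background peptide set, as
#' `log2((f_top + pc') / (f_bg + pc'))` on pseudocount-regularized
#' frequencies. The consensus of per-position maxima summarizes the enriched
#' motif.
#'
#' @param profile A ranked profile (uses rows with `top_k = TRUE`).
#' @param background Background peptides (tibble with `peptide` column or
#'   character vector), same length as the top-k peptides.
#' @param pseudocount Pseudocount added to every residue count (default 0.5).
#' @return A tibble of (position, residue, freq_top, freq_background,
#'   enrichment_log2) with attribute `consensus` (string of per-position
#'   argmax residues).
#' @export
positional_enrichment <- function(profile, background, pseudocount = 0.5) {
  stopifnot(is.data.frame(profile),
            all(c("peptide", "top_k") %in% names(profile)))
  top <- profile$peptide[profile$top_k]
  if (length(top) == 0) stop("the profile has no top-k peptides", call. = FALSE)
  bg <- as_peptide_tbl(background)$peptide
  L <- unique(nchar(top))
  if (length(L) != 1L || !all(nchar(bg) == L)) {
    stop("top-k and background peptides must share one length", call. = FALSE)
  }
  residues <- sort(unique(c(unlist(strsplit(top, "")),
                            unlist(strsplit(bg, "")))))
  count_freq <- function(seqs) {
    m <- do.call(rbind, strsplit(seqs, ""))
    sapply(seq_len(L), function(pos) {
      cnt <- table(factor(m[, pos], levels = residues))
      (as.numeric(cnt) + pseudocount) /
        (length(seqs) + pseudocount * length(residues))
    })
  }
  f_top <- count_freq(top)       # residues x positions
  f_bg <- count_freq(bg)
  out <- tidyr::expand_grid(position = seq_len(L), residue = residues) |>
    dplyr::mutate(
      freq_top = purrr::map2_dbl(.data$position, .data$residue,
                                 ~ f_top[match(.y, residues), .x]),
      freq_background = purrr::map2_dbl(.data$position, .data$residue,
                                        ~ f_bg[match(.y, residues), .x]),
      enrichment_log2 = log2(.data$freq_top / .data$freq_background)
    )
  consensus <- paste(vapply(seq_len(L), function(pos) {
    sub <- out[out$position == pos, ]
    sub$residue[which.max(sub$enrichment_log2)]
  }, character(1)), collapse = "")
  attr(out, "consensus") <- consensus
  out
}
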