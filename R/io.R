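#' Read and write peptide lists
#'
#' Peptide lists are exchanged as TSV with columns `peptide_id` and
#' `peptide`, or as FASTA with the row index as record id.
#'
#' @param peptides Peptide tibble or character vector.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return a peptide
#'   tibble.
#' @name peptide_io
NULL

#' @rdname peptide_io
#' @export
write_peptides_tsv <- function(peptides, path) {
  tbl <- as_peptide_tbl(peptides)
  readr::write_tsv(tbl[, c("peptide_id", "peptide")], path)
  invisible(path)
}

#' @rdname peptide_io
#' @export
read_peptides_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    peptide_id = readr::col_integer(),
    peptide = readr::col_character()
  ))
  check_parse_problems(tbl, path)
  tbl
}

#' @rdname peptide_io
#' @export
write_peptides_fasta <- function(peptides, path) {
  tbl <- as_peptide_tbl(peptides)
  aa <- Biostrings::AAStringSet(tbl$peptide)
  names(aa) <- as.character(tbl$peptide_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname peptide_io
#' @export
read_peptides_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- names(aa)
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicated FASTA ids (%s)", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(peptide_id = unname(ids),
                 peptide = unname(toupper(as.character(aa))))
}

# stop with line numbers if readr recorded parse problems
check_parse_problems <- function(tbl, path) {
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    first <- probs[1, ]
    stop(sprintf("%s: parse error at line %d, column %d: expected %s, got '%s'",
                 path, first$row, first$col, first$expected, first$actual),
         call. = FALSE)
  }
  invisible(tbl)
}

#' Read and write signal tables
#'
#' Signal tables are CSV/TSV with header
#' `feature_id, peptide, replicate, intensity` plus the optional truth
#' columns `true_activity` and `is_imperfection` written by the simulator.
#' Reading validates the header and fails with a line number on malformed
#' numeric fields.
#'
#' @param table A signal table tibble.
#' @param path File path; `.tsv` extension selects TSV, anything else CSV.
#' @return `write_signal_table` returns `path` invisibly;
#'   `read_signal_table` a signal table tibble.
#' @name signal_io
NULL

#' @rdname signal_io
#' @export
write_signal_table <- function(table, path) {
  need <- c("feature_id", "peptide", "replicate", "intensity")
  stopifnot(all(need %in% names(table)))
  keep <- intersect(c(need, "true_activity", "is_imperfection"), names(table))
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(table[, keep], path)
  invisible(path)
}

#' @rdname signal_io
#' @export
read_signal_table <- function(path) {
  is_tsv <- grepl("\\.tsv$", path)
  delim <- if (is_tsv) "\t" else ","
  header <- strsplit(readr::read_lines(path, n_max = 1), delim)[[1]]
  need <- c("feature_id", "peptide", "replicate", "intensity")
  missing_cols <- setdiff(need, header)
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  reader <- if (is_tsv) readr::read_tsv else readr::read_csv
  tbl <- reader(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    peptide = readr::col_character(),
    replicate = readr::col_integer(),
    intensity = readr::col_double(),
    .default = readr::col_guess()
  ))
  check_parse_problems(tbl, path)
  tbl
}

#' Read and write kinetic traces
#'
#' Kinetic traces are CSV with header `time_s, a340`; trace metadata
#' (substrate and enzyme concentration) lives in a JSON side-car
#' (`<path>.json`) so the trace file stays a plain two-column table.
#'
#' @param trace A kinetic trace tibble (e.g. from
#'   [simulate_kinetic_trace()]).
#' @param path CSV file path.
#' @param metadata Optional named list written to the side-car; defaults to
#'   the trace's `substrate_conc` attribute.
#' @return `write_kinetic_trace` returns `path` invisibly;
#'   `read_kinetic_trace` the trace tibble with metadata attributes
#'   restored.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_kinetic_trace <- function(trace, path, metadata = NULL) {
  stopifnot(all(c("time_s", "a340") %in% names(trace)))
  readr::write_csv(trace[, c("time_s", "a340")], path)
  if (is.null(metadata)) {
    sc <- attr(trace, "substrate_conc")
    if (!is.null(sc)) metadata <- list(substrate_conc = sc)
  }
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname trace_io
#' @export
read_kinetic_trace <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    a340 = readr::col_double()
  ))
  check_parse_problems(tbl, path)
  if (is.unsorted(tbl$time_s, strictly = TRUE)) {
    stop(sprintf("%s: time_s must be strictly increasing", path),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (nm in names(meta)) attr(tbl, nm) <- meta[[nm]]
  }
  tbl
}
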