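# Shared readers/writers. TSV with header is the universal tabular format
# (gzip handled transparently by readr); FASTA for sequences; JSON for
# nested results.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (plain or gzipped).
#' @param as_rna Convert T to U (default TRUE).
#' @return Tibble `name`, `sequence`; empty files give an empty tibble
#'   with a warning.
#' @export
read_fasta <- function(path, as_rna = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    warn(sprintf("empty FASTA: %s", path))
    return(tibble(name = character(0), sequence = character(0)))
  }
  seqs <- toupper(as.character(ss))
  if (as_rna) seqs <- chartr("T", "U", seqs)
  tibble(name = sub("\\s.*$", "", names(ss)), sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param data Tibble with columns `name` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  ss <- Biostrings::BStringSet(setNames(data$sequence, data$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a TSV file with schema validation
#'
#' @param path TSV file (plain or gzipped), with header.
#' @param required_cols Character vector of columns that must be present;
#'   a missing column raises an error naming it.
#' @return A tibble.
#' @export
read_tsv_checked <- function(path, required_cols = character(0)) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(out))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  out
}

#' Write a tabular report to TSV
#'
#' @param data A data frame (fit results, count tables, summaries).
#' @param path Output path (`.gz` suffix gzips transparently).
#' @return `path`, invisibly.
#' @export
write_report <- function(data, path) {
  readr::write_tsv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Write a nested result to JSON
#'
#' @param x A list or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required for JSON reports")
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
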