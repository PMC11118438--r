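# canonical metadata column names and the accepted aliases (lower-cased)
META_COLUMNS <- c("file_path", "dataset_filename", "massive_id", "taxon_name",
                  "ncbi_taxid", "redu_available", "is_blank_or_qc", "file_usi")

meta_aliases <- list(
  file_path = c("file_path", "filepath", "path"),
  dataset_filename = c("dataset_filename", "dataset/filename", "filename"),
  massive_id = c("massive_id", "massiveid", "massive"),
  taxon_name = c("taxon_name", "taxon"),
  ncbi_taxid = c("ncbi_taxid", "taxid", "ncbi_id", "ncbiid", "taxaid"),
  redu_available = c("redu_available", "redu"),
  is_blank_or_qc = c("is_blank_or_qc", "blank_qc", "blank", "is_blank"),
  file_usi = c("file_usi", "usi")
)

#' Read the reference-file metadata table
#'
#' Reads the eight-column metadata table describing each reference LC-MS/MS
#' file: file path, filename in `Dataset/Filename` form, MassIVE-style
#' accession, taxon name, NCBI taxonomy id, ReDU availability, blank/QC flag,
#' and the file's USI. Header matching is case-insensitive and
#' order-insensitive, with common aliases accepted (e.g. `taxid` for
#' `ncbi_taxid`, `usi` for `file_usi`). Flags are parsed from truthy tokens
#' `yes`/`true`/`1` (case-insensitive); everything else is `FALSE`. A row may
#' omit the taxid only when it is flagged blank/QC.
#'
#' @param path a CSV (`.csv`) or TSV table.
#' @return A `data.frame` with the canonical columns; `ncbi_taxid` is integer
#'   (`NA` for blanks), the two flags are logical.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), "spectax_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", comment.char = "")
  lc <- tolower(trimws(names(raw)))
  col_for <- vapply(META_COLUMNS, function(canon) {
    hit <- unlist(lapply(meta_aliases[[canon]], function(a) which(lc == a)))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, 0L)
  missing <- META_COLUMNS[is.na(col_for)]
  if (length(missing)) {
    abort(paste0("metadata table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          "spectax_schema_error")
  }
  out <- data.frame(
    file_path = trimws(raw[[col_for["file_path"]]]),
    dataset_filename = trimws(raw[[col_for["dataset_filename"]]]),
    massive_id = trimws(raw[[col_for["massive_id"]]]),
    taxon_name = trimws(raw[[col_for["taxon_name"]]]),
    ncbi_taxid = suppressWarnings(
      as.integer(trimws(raw[[col_for["ncbi_taxid"]]]))),
    redu_available = is_truthy(raw[[col_for["redu_available"]]]),
    is_blank_or_qc = is_truthy(raw[[col_for["is_blank_or_qc"]]]),
    file_usi = trimws(raw[[col_for["file_usi"]]]),
    stringsAsFactors = FALSE
  )
  bad_sep <- which(vapply(strsplit(out$dataset_filename, "/", fixed = TRUE),
                          length, 0L) != 2L)
  if (length(bad_sep)) {
    abort(sprintf("dataset_filename must contain exactly one '/': row %d ('%s')",
                  bad_sep[1L], out$dataset_filename[bad_sep[1L]]),
          "spectax_schema_error")
  }
  orphan <- which(is.na(out$ncbi_taxid) & !out$is_blank_or_qc)
  if (length(orphan)) {
    abort(sprintf("non-blank row(s) without an NCBI taxid: %s",
                  paste(out$dataset_filename[head(orphan, 5L)], collapse = ", ")),
          "spectax_schema_error")
  }
  out
}

#' Write a metadata table
#'
#' Inverse of [read_metadata_table()]; writes the canonical eight columns as
#' TSV (or CSV when `path` ends in `.csv`), with flags serialized as
#' `yes`/`no`.
#'
#' @param metadata data.frame with the canonical columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(metadata, path) {
  stopifnot(all(META_COLUMNS %in% names(metadata)))
  out <- metadata[, META_COLUMNS]
  out$redu_available <- ifelse(out$redu_available, "yes", "no")
  out$is_blank_or_qc <- ifelse(out$is_blank_or_qc, "yes", "no")
  out$ncbi_taxid <- ifelse(is.na(out$ncbi_taxid), "", as.character(out$ncbi_taxid))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
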