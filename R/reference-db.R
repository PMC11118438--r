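#' Build the reference spectral database
#'
#' Reads every MGF file, links each to its metadata row, preprocesses all
#' spectra, and assembles the searchable reference database. An MGF file is
#' linked to the metadata row whose `Dataset/Filename` equals
#' `basename(dirname(path))/basename(path)` (files laid out one directory
#' per dataset) or, failing that, whose `Filename` part equals
#' `basename(path)`. MGF files with no metadata row are a hard error listing
#' the orphans. Spectra are ordered deterministically by
#' `(dataset_filename, scan order)`; spectra emptied by preprocessing are
#' dropped with a warning.
#'
#' @param mgf_paths character vector of MGF file paths.
#' @param metadata a metadata data.frame (from [read_metadata_table()]) or a
#'   path to the table.
#' @param precursor_exclusion_da passed to [preprocess_spectrum()]
#'   (default `NULL`: off).
#' @param min_intensity_fraction passed to [preprocess_spectrum()].
#' @return An object of class `reference_db`: spectra, per-spectrum
#'   precursor/file vectors, metadata, and a `by_file` position map.
#' @export
build_reference_db <- function(mgf_paths, metadata,
                               precursor_exclusion_da = NULL,
                               min_intensity_fraction = 0) {
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- read_metadata_table(metadata)
  }
  stopifnot(is.data.frame(metadata), all(META_COLUMNS %in% names(metadata)))
  file_part <- vapply(strsplit(metadata$dataset_filename, "/", fixed = TRUE),
                      `[`, "", 2L)

  key1 <- paste(basename(dirname(mgf_paths)), basename(mgf_paths), sep = "/")
  row_of <- match(key1, metadata$dataset_filename)
  fallback <- is.na(row_of)
  row_of[fallback] <- match(basename(mgf_paths)[fallback], file_part)
  if (anyNA(row_of)) {
    abort(paste0("MGF file(s) with no metadata row: ",
                 paste(mgf_paths[is.na(row_of)], collapse = ", ")),
          "spectax_schema_error")
  }

  ord <- order(metadata$dataset_filename[row_of], method = "radix")
  mgf_paths <- mgf_paths[ord]
  row_of <- row_of[ord]

  spectra <- list()
  files <- character()
  n_dropped <- 0L
  for (k in seq_along(mgf_paths)) {
    dsfn <- metadata$dataset_filename[row_of[k]]
    raw <- read_mgf(mgf_paths[k])
    for (i in seq_along(raw)) {
      s <- raw[[i]]
      s$source_file <- dsfn
      if (is.na(s$spectrum_id) || s$spectrum_id == sprintf("scan=%d", i)) {
        s$spectrum_id <- sprintf("%s:scan:%d", dsfn, i)
      }
      s <- tryCatch(
        preprocess_spectrum(s, precursor_exclusion_da, min_intensity_fraction),
        spectax_empty_spectrum = function(e) NULL
      )
      if (is.null(s)) {
        n_dropped <- n_dropped + 1L
      } else {
        spectra[[length(spectra) + 1L]] <- s
        files[[length(files) + 1L]] <- dsfn
      }
    }
  }
  if (n_dropped > 0L) {
    warning(sprintf("%d reference spectra emptied by preprocessing were dropped",
                    n_dropped))
  }
  structure(
    list(
      spectra = spectra,
      precursor = vapply(spectra, `[[`, 0, "precursor_mz"),
      file = files,
      spectrum_id = vapply(spectra, `[[`, "", "spectrum_id"),
      metadata = metadata,
      by_file = split(seq_along(files), files)
    ),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  nb <- sum(!x$metadata$is_blank_or_qc)
  cat(sprintf("<reference_db> %d spectra in %d files (%d non-blank), %d metadata rows\n",
              length(x$spectra), length(x$by_file), nb, nrow(x$metadata)))
  invisible(x)
}

#' Build the binned fragment-ion inverted index
#'
#' Every reference peak is assigned to the integer bin
#' `floor(mz / bin_width)`; the index maps each occupied bin to the
#' `(spectrum, peak)` positions it contains, so candidate spectra sharing
#' fragment bins with a query can be retrieved without scoring the whole
#' database. It also stores the precursor m/z values in sorted order for the
#' precursor gate. `bin_width` should equal the fragment tolerance used at
#' search time: probing a query peak's bin and its two neighbours is then
#' guaranteed to cover every reference peak within tolerance.
#'
#' @param db a [build_reference_db()] result.
#' @param bin_width bin width in Da (> 0); default 0.05.
#' @return An object of class `fragment_index`.
#' @export
build_fragment_index <- function(db, bin_width = 0.05) {
  stopifnot(inherits(db, "reference_db"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort("bin_width must be a positive number", "spectax_parameter_error")
  }
  if (length(db$spectra) == 0L) {
    abort("reference database is empty", "spectax_parameter_error")
  }
  np <- vapply(db$spectra, n_peaks, 0L)
  spec_idx <- rep.int(seq_along(db$spectra), np)
  peak_idx <- unlist(lapply(np, seq_len), use.names = FALSE)
  mz <- unlist(lapply(db$spectra, function(s) s$peaks[, "mz"]), use.names = FALSE)
  bin <- floor(mz / bin_width)

  postings <- new.env(parent = emptyenv(), size = length(unique(bin)))
  parts <- split(seq_along(bin), bin)
  for (key in names(parts)) {
    sel <- parts[[key]]
    assign(key, cbind(spec = spec_idx[sel], peak = peak_idx[sel]),
           envir = postings)
  }
  ord <- order(db$precursor)
  structure(
    list(bin_width = bin_width,
         postings = postings,
         n_postings = length(bin),
         precursor_sorted = db$precursor[ord],
         precursor_order = ord),
    class = "fragment_index"
  )
}

#' @export
print.fragment_index <- function(x, ...) {
  cat(sprintf("<fragment_index> %d peak postings in %d bins (bin width %.3g Da), %d spectra\n",
              x$n_postings, length(ls(x$postings)), x$bin_width,
              length(x$precursor_sorted)))
  invisible(x)
}

#' Save / load a fragment-indexed reference database
#'
#' On-disk form is a versioned JSON container holding the spectra, metadata
#' and index parameters; the index postings are rebuilt on load (rebuilding
#' from the stored peaks is exact and cheap relative to I/O).
#'
#' @param db a `reference_db`.
#' @param index a `fragment_index` built from `db`.
#' @param path output file.
#' @return For `save_reference_index`, `path` invisibly; for
#'   `load_reference_index`, a list with elements `db` and `index`.
#' @export
save_reference_index <- function(db, index, path) {
  payload <- list(
    format = "spectax-reference-index",
    version = 1L,
    bin_width = index$bin_width,
    metadata = db$metadata,
    spectra = lapply(db$spectra, function(s) {
      list(id = s$spectrum_id, precursor_mz = s$precursor_mz,
           charge = s$charge, source_file = s$source_file,
           mz = s$peaks[, "mz"], intensity = s$peaks[, "intensity"])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname save_reference_index
#' @export
load_reference_index <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "spectax-reference-index")) {
    abort("not a spectax reference index file", "spectax_io_error")
  }
  metadata <- do.call(rbind, lapply(payload$metadata, function(r) {
    vals <- lapply(META_COLUMNS, function(cn) r[[cn]] %||% NA)
    names(vals) <- META_COLUMNS
    data.frame(vals, stringsAsFactors = FALSE)
  }))
  metadata$ncbi_taxid <- suppressWarnings(as.integer(metadata$ncbi_taxid))
  metadata$redu_available <- as.logical(metadata$redu_available)
  metadata$is_blank_or_qc <- as.logical(metadata$is_blank_or_qc)
  spectra <- lapply(payload$spectra, function(s) {
    ms_spectrum(s$id, s$precursor_mz, unlist(s$mz), unlist(s$intensity),
                charge = if (is.null(s$charge)) NA_integer_ else s$charge,
                source_file = s$source_file)
  })
  files <- vapply(spectra, `[[`, "", "source_file")
  db <- structure(
    list(spectra = spectra,
         precursor = vapply(spectra, `[[`, 0, "precursor_mz"),
         file = files,
         spectrum_id = vapply(spectra, `[[`, "", "spectrum_id"),
         metadata = metadata,
         by_file = split(seq_along(files), files)),
    class = "reference_db"
  )
  list(db = db, index = build_fragment_index(db, payload$bin_width))
}
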