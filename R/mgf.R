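#' Read an MGF (Mascot generic format) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks into [ms_spectrum()] objects, in file
#' order. `PEPMASS` may carry one or two values; only the first (the precursor
#' m/z) is kept. `CHARGE` accepts forms like `2+`, `1-` or plain integers.
#' Peaks are returned exactly as stored — preprocessing is a separate,
#' explicit step ([preprocess_spectrum()]).
#'
#' @param path path to an MGF file.
#' @return A list of `ms_spectrum`, one per block (empty list for an empty
#'   file).
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), "spectax_io_error")
  lines <- trimws(readLines(path, warn = FALSE))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(begins > ends)) {
    abort(sprintf("%s: unbalanced BEGIN IONS/END IONS blocks", path),
          "spectax_parse_error")
  }
  if (length(begins) == 0L) return(list())

  idx <- seq_along(lines)
  block <- findInterval(idx, begins)
  inside <- block >= 1L & idx > begins[pmax(block, 1L)] & idx < ends[pmax(block, 1L)]
  content <- inside & nzchar(lines) & !startsWith(lines, "#")

  is_kv <- content & grepl("=", lines, fixed = TRUE)
  is_peak <- content & !is_kv

  # key-value headers
  kv_block <- block[is_kv]
  kv_key <- toupper(sub("=.*$", "", lines[is_kv]))
  kv_val <- sub("^[^=]*=", "", lines[is_kv])
  header <- function(key) {
    out <- rep(NA_character_, length(begins))
    sel <- kv_key == key
    out[kv_block[sel]] <- kv_val[sel]
    out
  }
  pepmass <- header("PEPMASS")
  title <- header("TITLE")
  charge <- header("CHARGE")

  missing_pm <- which(is.na(pepmass))
  if (length(missing_pm)) {
    abort(sprintf("%s: block %d lacks PEPMASS", path, missing_pm[1L]),
          "spectax_parse_error")
  }

  # peak lines, parsed in one pass
  peak_lines <- which(is_peak)
  pk <- strsplit(lines[peak_lines], "[ \t]+")
  pk_mz <- suppressWarnings(as.numeric(vapply(pk, `[`, "", 1L)))
  pk_int <- suppressWarnings(as.numeric(vapply(pk, function(p) {
    if (length(p) >= 2L) p[2L] else NA_character_
  }, "")))
  bad <- which(is.na(pk_mz) | is.na(pk_int))
  if (length(bad)) {
    abort(sprintf("%s: malformed peak line %d: '%s'",
                  path, peak_lines[bad[1L]], lines[peak_lines[bad[1L]]]),
          "spectax_parse_error")
  }
  pk_block <- block[peak_lines]

  prec <- suppressWarnings(as.numeric(vapply(
    strsplit(pepmass, "[ \t]+"), `[`, "", 1L)))
  if (any(is.na(prec))) {
    abort(sprintf("%s: block %d has unparseable PEPMASS", path,
                  which(is.na(prec))[1L]), "spectax_parse_error")
  }
  chg <- rep(NA_integer_, length(begins))
  has_chg <- !is.na(charge)
  if (any(has_chg)) {
    raw <- charge[has_chg]
    sign <- ifelse(grepl("-", raw, fixed = TRUE), -1L, 1L)
    mag <- suppressWarnings(as.integer(gsub("[^0-9]", "", raw)))
    chg[has_chg] <- sign * mag
  }

  split_idx <- split(seq_along(pk_mz), factor(pk_block, levels = seq_along(begins)))
  lapply(seq_along(begins), function(b) {
    sel <- split_idx[[b]]
    id <- if (!is.na(title[b])) title[b] else sprintf("scan=%d", b)
    if (length(sel) == 0L) {
      abort(sprintf("%s: block %d has no peaks", path, b), "spectax_parse_error")
    }
    ms_spectrum(id, prec[b], pk_mz[sel], pk_int[sel], charge = chg[b])
  })
}

#' Write spectra to an MGF file
#'
#' Writes one `BEGIN IONS`/`END IONS` block per spectrum, in order. `TITLE`
#' carries the spectrum id. Round-tripping through [read_mgf()] preserves
#' precursor m/z and peaks to 1e-6 Da / 1e-6 relative intensity.
#'
#' @param spectra list of [ms_spectrum()] (each with at least one peak).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(is.list(spectra))
  blocks <- vapply(spectra, function(s) {
    stopifnot(inherits(s, "ms_spectrum"))
    if (n_peaks(s) < 1L) stop("cannot write a spectrum with no peaks: ", s$spectrum_id)
    hdr <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$spectrum_id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      if (!is.na(s$charge)) {
        sprintf("CHARGE=%d%s", abs(s$charge), if (s$charge < 0) "-" else "+")
      }
    )
    pk <- sprintf("%.6f %.8g", s$peaks[, "mz"], s$peaks[, "intensity"])
    paste(c(hdr, pk, "END IONS"), collapse = "\n")
  }, "")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(blocks, con, sep = "\n\n")
  invisible(path)
}
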