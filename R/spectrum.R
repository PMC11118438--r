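#' Construct an MS/MS spectrum
#'
#' The canonical in-memory form of one tandem mass spectrum: a precursor m/z,
#' an optional charge, and a peak list of (m/z, intensity) pairs. Peaks are
#' stored as a two-column numeric matrix. Construction does not preprocess;
#' use [preprocess_spectrum()] to sort, deduplicate and filter peaks before
#' scoring or searching.
#'
#' @param spectrum_id opaque identifier (scan id, USI, compound name, ...).
#' @param precursor_mz precursor mass-to-charge ratio in Da; must be > 0.
#' @param mz numeric vector of fragment m/z values (Da), all > 0.
#' @param intensity numeric vector of abundances, same length as `mz`.
#' @param charge optional integer charge (sign carries polarity). Charge is
#'   stored but never used for scoring: precursor m/z values are compared
#'   as-is, including for multiply charged ions.
#' @param source_file optional `Dataset/Filename` key linking the spectrum to
#'   a metadata entry.
#' @return An object of class `ms_spectrum`.
#' @examples
#' s <- ms_spectrum("q1", 500.2, c(100.1, 200.2, 300.3), c(10, 20, 5))
#' n_peaks(s)
#' @export
ms_spectrum <- function(spectrum_id, precursor_mz, mz, intensity,
                        charge = NA_integer_, source_file = NA_character_) {
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      is.na(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be a single positive number")
  }
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (any(is.na(mz)) || any(mz <= 0)) stop("all mz values must be positive")
  if (any(is.na(intensity))) stop("intensities must not be NA")
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      precursor_mz = as.numeric(precursor_mz),
      charge = as.integer(charge),
      peaks = cbind(mz = mz, intensity = intensity),
      source_file = as.character(source_file)
    ),
    class = "ms_spectrum"
  )
}

#' @rdname ms_spectrum
#' @param x an `ms_spectrum`.
#' @export
n_peaks <- function(x) nrow(x$peaks)

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum %s>  precursor m/z %.4f  %d peak%s",
              x$spectrum_id, x$precursor_mz, n_peaks(x),
              if (n_peaks(x) == 1L) "" else "s"))
  if (!is.na(x$charge)) cat(sprintf("  charge %+d", x$charge))
  cat("\n")
  invisible(x)
}

#' Preprocess a spectrum for searching
#'
#' Removes non-positive-intensity peaks, optionally removes peaks near or
#' above the precursor m/z, optionally applies a relative intensity floor,
#' sorts peaks ascending by m/z, and merges exact-duplicate m/z values by
#' summing their intensities. The operation is idempotent. Precursor-window
#' exclusion is off by default so that a raw pasted peak list is searched
#' exactly as given.
#'
#' @param s an [ms_spectrum()].
#' @param precursor_exclusion_da if non-`NULL`, peaks with
#'   `mz >= precursor_mz - precursor_exclusion_da` are removed.
#' @param min_intensity_fraction peaks with intensity below this fraction of
#'   the base peak are removed (default 0 = keep all).
#' @return The preprocessed `ms_spectrum`.
#' @examples
#' s <- ms_spectrum("q", 500, c(300, 100, 100), c(1, 2, 3))
#' preprocess_spectrum(s)$peaks
#' @export
preprocess_spectrum <- function(s, precursor_exclusion_da = NULL,
                                min_intensity_fraction = 0) {
  stopifnot(inherits(s, "ms_spectrum"))
  mz <- s$peaks[, "mz"]
  it <- s$peaks[, "intensity"]
  keep <- it > 0
  if (!is.null(precursor_exclusion_da)) {
    keep <- keep & (mz < s$precursor_mz - precursor_exclusion_da)
  }
  if (min_intensity_fraction > 0 && any(keep)) {
    keep <- keep & (it >= min_intensity_fraction * max(it[keep]))
  }
  mz <- mz[keep]
  it <- it[keep]
  if (length(mz) == 0L) {
    abort(sprintf("spectrum '%s': all peaks removed by preprocessing; unsearchable",
                  s$spectrum_id),
          "spectax_empty_spectrum")
  }
  if (anyDuplicated(mz)) {
    it <- as.numeric(rowsum(it, group = mz))  # rowsum sorts groups by mz
    mz <- sort(unique(mz))
  } else {
    o <- order(mz)
    mz <- mz[o]
    it <- it[o]
  }
  s$peaks <- cbind(mz = mz, intensity = it)
  s
}

# guard used by scoring / search entry points
check_searchable <- function(s, what = "spectrum") {
  if (!inherits(s, "ms_spectrum") || n_peaks(s) < 1L) {
    abort(sprintf("%s has no peaks; unsearchable", what),
          "spectax_empty_spectrum")
  }
  invisible(s)
}
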