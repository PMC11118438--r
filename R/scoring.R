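#' Search parameter set
#'
#' Bundles the thresholds and tolerances governing a library search. The
#' defaults are the standard single-spectrum search settings: cosine
#' threshold 0.7, at least 3 matched fragment peaks, 0.05 Da precursor and
#' fragment tolerances, analog search off. All tolerances are absolute Da
#' (never ppm). Threshold comparisons are inclusive (`>=`).
#'
#' @param cosine_threshold minimum similarity score in \[0, 1\].
#' @param min_matched_peaks minimum number of matched fragment peaks (>= 1).
#' @param precursor_tolerance precursor m/z tolerance in Da.
#' @param fragment_tolerance fragment m/z tolerance in Da.
#' @param analog_search if `TRUE`, the precursor gate widens to
#'   `analog_max_delta` and spectra are scored with the modified cosine.
#' @param analog_max_delta maximum |precursor delta| in Da admitted in analog
#'   mode.
#' @param sqrt_transform if `TRUE`, intensities are square-root transformed
#'   before normalization; default `FALSE` (classic raw-intensity cosine).
#' @return An object of class `search_params`.
#' @export
search_params <- function(cosine_threshold = 0.7,
                          min_matched_peaks = 3L,
                          precursor_tolerance = 0.05,
                          fragment_tolerance = 0.05,
                          analog_search = FALSE,
                          analog_max_delta = 200,
                          sqrt_transform = FALSE) {
  stopifnot(
    cosine_threshold >= 0, cosine_threshold <= 1,
    min_matched_peaks >= 1,
    precursor_tolerance > 0, fragment_tolerance > 0,
    analog_max_delta > 0,
    is.logical(analog_search), is.logical(sqrt_transform)
  )
  structure(
    list(cosine_threshold = as.numeric(cosine_threshold),
         min_matched_peaks = as.integer(min_matched_peaks),
         precursor_tolerance = as.numeric(precursor_tolerance),
         fragment_tolerance = as.numeric(fragment_tolerance),
         analog_search = isTRUE(analog_search),
         analog_max_delta = as.numeric(analog_max_delta),
         sqrt_transform = isTRUE(sqrt_transform)),
    class = "search_params"
  )
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf(
    "<search_params> cosine >= %.2f, matched peaks >= %d, prec tol %.3g Da, frag tol %.3g Da, analog %s",
    x$cosine_threshold, x$min_matched_peaks, x$precursor_tolerance,
    x$fragment_tolerance,
    if (x$analog_search) sprintf("on (max delta %.3g Da)", x$analog_max_delta) else "off"))
  cat("\n")
  invisible(x)
}

# unit-norm intensity vector (optionally sqrt-transformed)
norm_intensities <- function(x, sqrt_transform = FALSE) {
  if (sqrt_transform) x <- sqrt(x)
  x / sqrt(sum(x^2))
}

#' Pair peaks between two spectra within a fragment tolerance
#'
#' Enumerates all candidate pairs `(i, j, shift)` with
#' `|mz_a[i] - (mz_b[j] + shift)| <= fragment_tolerance` over the supplied
#' shift channels, then selects a one-to-one pairing greedily by descending
#' normalized-intensity product, breaking ties deterministically by smaller
#' |delta m/z|, then lower query index, then lower reference index. Each peak
#' of either spectrum is used at most once, across all shift channels.
#'
#' Use `shifts = 0` for the direct cosine; the modified cosine adds the
#' precursor m/z difference as a second channel.
#'
#' @param a,b [ms_spectrum()] objects (preprocessed).
#' @param fragment_tolerance absolute tolerance in Da.
#' @param shifts numeric vector of allowed m/z offsets applied to `b`'s peaks.
#' @param sqrt_transform see [search_params()].
#' @return A data.frame with columns `index_a`, `index_b`, `shift_used`,
#'   `product` (normalized intensity product), `delta_mz`.
#' @export
match_peak_pairs <- function(a, b, fragment_tolerance = 0.05, shifts = 0,
                             sqrt_transform = FALSE) {
  check_searchable(a, "query spectrum")
  check_searchable(b, "reference spectrum")
  stopifnot(length(shifts) >= 1L, fragment_tolerance > 0)
  na <- norm_intensities(a$peaks[, "intensity"], sqrt_transform)
  nb <- norm_intensities(b$peaks[, "intensity"], sqrt_transform)
  mza <- a$peaks[, "mz"]
  mzb <- b$peaks[, "mz"]

  empty <- data.frame(index_a = integer(), index_b = integer(),
                      shift_used = numeric(), product = numeric(),
                      delta_mz = numeric())
  cand_i <- integer(); cand_j <- integer()
  cand_s <- numeric(); cand_d <- numeric()
  for (s in unique(shifts)) {
    d <- outer(mza, mzb + s, "-")
    hit <- which(abs(d) <= fragment_tolerance, arr.ind = TRUE)
    if (nrow(hit)) {
      cand_i <- c(cand_i, hit[, 1L])
      cand_j <- c(cand_j, hit[, 2L])
      cand_s <- c(cand_s, rep(s, nrow(hit)))
      cand_d <- c(cand_d, d[hit])
    }
  }
  if (length(cand_i) == 0L) return(empty)
  prod <- na[cand_i] * nb[cand_j]
  ord <- order(-prod, abs(cand_d), cand_i, cand_j)

  used_a <- logical(length(mza))
  used_b <- logical(length(mzb))
  keep <- integer(0)
  for (k in ord) {
    if (!used_a[cand_i[k]] && !used_b[cand_j[k]]) {
      used_a[cand_i[k]] <- TRUE
      used_b[cand_j[k]] <- TRUE
      keep <- c(keep, k)
    }
  }
  data.frame(index_a = cand_i[keep], index_b = cand_j[keep],
             shift_used = cand_s[keep], product = prod[keep],
             delta_mz = cand_d[keep])
}

similarity_result <- function(score, pairs) {
  structure(list(score = score, n_matched_peaks = nrow(pairs), pairs = pairs),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity> score %.4f, %d matched peak%s\n",
              x$score, x$n_matched_peaks,
              if (x$n_matched_peaks == 1L) "" else "s"))
  invisible(x)
}

#' Cosine similarity between two MS/MS spectra
#'
#' Normalized dot product over tolerance-matched peak pairs: each spectrum's
#' intensity vector is scaled to unit Euclidean norm and the score is the sum
#' of products over the one-to-one pairing chosen by [match_peak_pairs()]
#' with a single direct (shift 0) channel, clipped to \[0, 1\]. A spectrum
#' scored against itself gives 1; spectra with no peaks within tolerance give
#' 0.
#'
#' @inheritParams match_peak_pairs
#' @return A `similarity_result` with fields `score`, `n_matched_peaks`,
#'   `pairs`.
#' @examples
#' a <- ms_spectrum("a", 400, c(100, 200), c(1, 1))
#' b <- ms_spectrum("b", 400, c(100, 300), c(1, 1))
#' cosine_score(a, b)$score  # 0.5: one shared peak, both unit-normalized
#' @export
cosine_score <- function(a, b, fragment_tolerance = 0.05,
                         sqrt_transform = FALSE) {
  pairs <- match_peak_pairs(a, b, fragment_tolerance, shifts = 0,
                            sqrt_transform = sqrt_transform)
  score <- min(1, max(0, sum(pairs$product)))
  similarity_result(score, pairs)
}

#' Modified cosine (analog) similarity
#'
#' Like [cosine_score()], but peaks may also pair when offset by the
#' precursor m/z difference between the two spectra. This recovers matches to
#' structural analogs, adducts, multimers and in-source fragments, where part
#' of the fragment ladder is shifted by the precursor delta. Both channels
#' compete for peaks; no peak is used twice. When the precursor delta is 0
#' the result equals the plain cosine exactly.
#'
#' @inheritParams match_peak_pairs
#' @return A `similarity_result`.
#' @export
modified_cosine_score <- function(a, b, fragment_tolerance = 0.05,
                                  sqrt_transform = FALSE) {
  shifts <- unique(c(0, a$precursor_mz - b$precursor_mz))
  pairs <- match_peak_pairs(a, b, fragment_tolerance, shifts = shifts,
                            sqrt_transform = sqrt_transform)
  score <- min(1, max(0, sum(pairs$product)))
  similarity_result(score, pairs)
}

#' Does a similarity result pass the acceptance thresholds?
#'
#' `TRUE` iff `score >= cosine_threshold` and
#' `n_matched_peaks >= min_matched_peaks` (both inclusive).
#'
#' @param r a `similarity_result` (or any list with `score` and
#'   `n_matched_peaks`).
#' @param p a [search_params()].
#' @return logical scalar.
#' @export
passes_thresholds <- function(r, p) {
  r$score >= p$cosine_threshold && r$n_matched_peaks >= p$min_matched_peaks
}
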