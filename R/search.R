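empty_match_df <- function() {
  data.frame(query_id = character(), ref_spectrum_id = character(),
             ref_file = character(), massive_id = character(),
             taxon_name = character(), ncbi_taxid = integer(),
             score = numeric(), n_matched_peaks = integer(),
             precursor_delta = numeric(), analog = logical(),
             usi = character(), stringsAsFactors = FALSE)
}

# score the given candidate spectra and assemble the filtered, sorted table
score_candidates <- function(db, query, cand, params) {
  if (length(cand) == 0L) return(empty_match_df())
  rows <- vector("list", length(cand))
  n <- 0L
  for (ci in cand) {
    ref <- db$spectra[[ci]]
    r <- if (params$analog_search) {
      modified_cosine_score(query, ref, params$fragment_tolerance,
                            params$sqrt_transform)
    } else {
      cosine_score(query, ref, params$fragment_tolerance,
                   params$sqrt_transform)
    }
    if (passes_thresholds(r, params)) {
      n <- n + 1L
      rows[[n]] <- list(ci = ci, score = r$score, npk = r$n_matched_peaks)
    }
  }
  if (n == 0L) return(empty_match_df())
  rows <- rows[seq_len(n)]
  ci <- vapply(rows, `[[`, 0L, "ci")
  meta_row <- match(db$file[ci], db$metadata$dataset_filename)
  delta <- query$precursor_mz - db$precursor[ci]
  out <- data.frame(
    query_id = query$spectrum_id,
    ref_spectrum_id = db$spectrum_id[ci],
    ref_file = db$file[ci],
    massive_id = db$metadata$massive_id[meta_row],
    taxon_name = db$metadata$taxon_name[meta_row],
    ncbi_taxid = db$metadata$ncbi_taxid[meta_row],
    score = vapply(rows, `[[`, 0, "score"),
    n_matched_peaks = vapply(rows, `[[`, 0L, "npk"),
    precursor_delta = delta,
    analog = abs(delta) > params$precursor_tolerance,
    usi = db$metadata$file_usi[meta_row],
    stringsAsFactors = FALSE
  )
  ord <- order(-out$score, abs(out$precursor_delta),
               out$ref_spectrum_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# candidate spectra passing the fragment-bin prefilter: spectra for which at
# least min_matched_peaks DISTINCT QUERY PEAKS have a reference peak in the
# query peak's bin or either neighbour. Counting distinct query peaks (rather
# than distinct bins) keeps the prefilter lossless: every true matched pair
# involves a distinct query peak whose partner must lie in a probed bin.
prefilter_candidates <- function(index, query, params) {
  bw <- index$bin_width
  qb <- floor(query$peaks[, "mz"] / bw)
  counts <- new.env(parent = emptyenv())
  tallies <- integer(0)
  ids <- integer(0)
  for (k in seq_along(qb)) {
    hits <- integer(0)
    for (b in (qb[k] - 1):(qb[k] + 1)) {
      p <- index$postings[[as.character(b)]]
      if (!is.null(p)) hits <- c(hits, p[, "spec"])
    }
    if (length(hits)) {
      for (sp in unique(hits)) {
        key <- as.character(sp)
        cur <- counts[[key]]
        if (is.null(cur)) {
          counts[[key]] <- 1L
        } else {
          counts[[key]] <- cur + 1L
        }
      }
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) return(integer(0))
  vals <- vapply(keys, function(k) counts[[k]], 0L)
  as.integer(keys[vals >= params$min_matched_peaks])
}

#' Search a query spectrum against the indexed reference database
#'
#' Exact mode (the default) gates candidates by
#' `|precursor delta| <= precursor_tolerance`, prefilters them through the
#' fragment-bin index (a candidate must share at least `min_matched_peaks`
#' query peaks' bins, probing each bin and both neighbours — a lossless
#' filter), scores survivors with [cosine_score()], keeps results passing
#' [passes_thresholds()], and sorts by (score desc, |precursor delta| asc,
#' reference spectrum id asc). Analog mode widens the precursor gate to
#' `analog_max_delta`, scores every gated candidate with
#' [modified_cosine_score()] (no bin prefilter, so the shifted channel can
#' never be missed), and flags results whose |delta| exceeds the precursor
#' tolerance as analog.
#'
#' @param db a [build_reference_db()] result.
#' @param index a [build_fragment_index()] result (may be `NULL` in analog
#'   mode).
#' @param query a preprocessed [ms_spectrum()] with at least one peak.
#' @param params a [search_params()].
#' @return A data.frame of per-reference-spectrum matches with columns
#'   `query_id`, `ref_spectrum_id`, `ref_file`, `massive_id`, `taxon_name`,
#'   `ncbi_taxid`, `score`, `n_matched_peaks`, `precursor_delta`, `analog`,
#'   `usi` (zero rows if nothing passes).
#' @seealso [brute_force_search()] for the index-free verification twin.
#' @export
search_library <- function(db, index, query, params = search_params()) {
  check_searchable(query, "query spectrum")
  stopifnot(inherits(db, "reference_db"))
  if (params$analog_search) {
    cand <- which(abs(db$precursor - query$precursor_mz) <= params$analog_max_delta)
    return(score_candidates(db, query, cand, params))
  }
  stopifnot(inherits(index, "fragment_index"))
  gate <- which(abs(db$precursor - query$precursor_mz) <= params$precursor_tolerance)
  if (length(gate) == 0L) return(empty_match_df())
  shared <- prefilter_candidates(index, query, params)
  cand <- intersect(gate, shared)
  score_candidates(db, query, cand, params)
}

#' Brute-force search (verification twin)
#'
#' Identical contract to [search_library()] but with no fragment-bin
#' prefilter: every reference spectrum passing the precursor gate is scored.
#' Exists as an independent correctness oracle for the indexed search; the
#' two must return identical match sets with scores agreeing to 1e-9.
#'
#' @inheritParams search_library
#' @return Same as [search_library()].
#' @export
brute_force_search <- function(db, query, params = search_params()) {
  check_searchable(query, "query spectrum")
  stopifnot(inherits(db, "reference_db"))
  tol <- if (params$analog_search) params$analog_max_delta else params$precursor_tolerance
  cand <- which(abs(db$precursor - query$precursor_mz) <= tol)
  score_candidates(db, query, cand, params)
}

#' Annotate a query against a named spectral library
#'
#' Scores the query against an annotated library (compound names in the MGF
#' `TITLE` field or as spectrum ids) under the same scoring, gating and
#' filtering rules as [search_library()], returning compound names with
#' scores. In exact mode the precursor gate applies; in analog mode the
#' modified cosine and the analog window are used.
#'
#' @param query a preprocessed [ms_spectrum()].
#' @param annotated_library a list of [ms_spectrum()] whose `spectrum_id` is
#'   the compound name, or a path to an annotated MGF file.
#' @param params a [search_params()].
#' @return A data.frame with columns `compound`, `score`, `n_matched_peaks`,
#'   `precursor_delta`, `analog`, sorted like [search_library()] output.
#' @export
annotate_query <- function(query, annotated_library, params = search_params()) {
  check_searchable(query, "query spectrum")
  if (is.character(annotated_library)) {
    annotated_library <- lapply(read_mgf(annotated_library), preprocess_spectrum)
  }
  if (length(annotated_library) == 0L) {
    return(data.frame(compound = character(), score = numeric(),
                      n_matched_peaks = integer(), precursor_delta = numeric(),
                      analog = logical(), stringsAsFactors = FALSE))
  }
  prec <- vapply(annotated_library, `[[`, 0, "precursor_mz")
  tol <- if (params$analog_search) params$analog_max_delta else params$precursor_tolerance
  cand <- which(abs(prec - query$precursor_mz) <= tol)
  rows <- list()
  for (ci in cand) {
    ref <- annotated_library[[ci]]
    r <- if (params$analog_search) {
      modified_cosine_score(query, ref, params$fragment_tolerance,
                            params$sqrt_transform)
    } else {
      cosine_score(query, ref, params$fragment_tolerance, params$sqrt_transform)
    }
    if (passes_thresholds(r, params)) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound = ref$spectrum_id, score = r$score,
        n_matched_peaks = r$n_matched_peaks,
        precursor_delta = query$precursor_mz - ref$precursor_mz,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(compound = character(), score = numeric(),
                      n_matched_peaks = integer(), precursor_delta = numeric(),
                      analog = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$analog <- abs(out$precursor_delta) > params$precursor_tolerance
  out <- out[order(-out$score, abs(out$precursor_delta), out$compound,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse spectrum-level matches to file-level matches
#'
#' A reference file matches a query if at least one of its spectra matches;
#' this is the granularity at which taxonomic aggregation operates ("all
#' data files where the queried spectrum has been observed"). Keeps, per
#' file, the best-scoring spectrum-level row.
#'
#' @param matches output of [search_library()]/[brute_force_search()].
#' @return A data.frame with one row per matched reference file.
#' @export
matches_by_file <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  best <- !duplicated(matches$ref_file)  # matches are sorted best-first
  out <- matches[best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a match table as TSV
#'
#' Columns: `query_id`, `ref_file` (Dataset/Filename), `massive_id`,
#' `taxon_name`, `ncbi_taxid`, `score`, `n_matched_peaks`,
#' `precursor_delta`, `analog_flag`, `usi`.
#'
#' @param matches a match data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(matches, path) {
  out <- data.frame(
    query_id = matches$query_id,
    ref_file = matches$ref_file,
    massive_id = matches$massive_id,
    taxon_name = matches$taxon_name,
    ncbi_taxid = matches$ncbi_taxid,
    score = sprintf("%.6f", matches$score),
    n_matched_peaks = matches$n_matched_peaks,
    precursor_delta = sprintf("%.6f", matches$precursor_delta),
    analog_flag = ifelse(matches$analog, "yes", "no"),
    usi = matches$usi,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
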