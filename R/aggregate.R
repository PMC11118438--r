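#' Summarize matches per taxonomic node
#'
#' Collapses spectrum-level matches to files ("samples"), then reports for
#' every tree node with at least one sample the total number of non-blank
#' files in its subtree, the number of those with at least one passing
#' match, and their ratio. This is the per-node statistic the result tree
#' displays: the percentage of samples at that taxonomic level in which the
#' queried spectrum was observed. A file is counted once per node; blanks
#' are excluded.
#'
#' @param matches a match data.frame ([search_library()] output).
#' @param metadata the reference metadata table.
#' @param tree a `taxon_tree` with sample counts attached
#'   ([attach_sample_counts()]).
#' @return A data.frame (one row per node with `n_total_samples > 0`, in
#'   tree traversal order) with columns `taxid`, `rank`, `name`,
#'   `n_total_samples`, `n_matched_samples`, `fraction_matched`.
#' @export
summarize_by_taxon <- function(matches, metadata, tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  matched_files <- unique(matches$ref_file)
  pos <- match(matched_files, metadata$dataset_filename)
  if (anyNA(pos)) {
    abort(paste0("match references file(s) absent from metadata: ",
                 paste(matched_files[is.na(pos)], collapse = ", ")),
          "spectax_schema_error")
  }
  pos <- pos[!metadata$is_blank_or_qc[pos]]
  node_pos <- match(metadata$ncbi_taxid[pos], tree$nodes$taxid)
  if (anyNA(node_pos)) {
    abort("matched file taxid not present in tree", "spectax_taxonomy_error")
  }
  m_direct <- tabulate(node_pos, nbins = nrow(tree$nodes))
  n_matched <- accumulate_counts(tree, m_direct)
  sel <- tree$nodes$n_samples > 0L
  out <- data.frame(
    taxid = tree$nodes$taxid[sel],
    rank = tree$nodes$rank[sel],
    name = tree$nodes$name[sel],
    n_total_samples = tree$nodes$n_samples[sel],
    n_matched_samples = n_matched[sel],
    stringsAsFactors = FALSE
  )
  out$fraction_matched <- out$n_matched_samples / out$n_total_samples
  rownames(out) <- NULL
  out
}

#' Write a taxon summary table as TSV
#'
#' @param summary a [summarize_by_taxon()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxon_summary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Presence matrix of query compounds across taxa at one rank
#'
#' Rows are query compounds, columns are the taxa at the requested rank (in
#' tree traversal order, restricted to taxa with samples), cells are the
#' compound's `fraction_matched` at that taxon (0 where absent). All
#' summaries must come from the same tree.
#'
#' @param summaries a named list of [summarize_by_taxon()] results, one per
#'   query compound.
#' @param tree the shared `taxon_tree` (counts attached).
#' @param rank the taxonomic rank for the columns (default `"species"`).
#' @return A numeric matrix (compounds x taxa); column names are taxon
#'   names (made unique), with the taxids in `attr(, "taxids")`.
#' @export
presence_matrix <- function(summaries, tree, rank = "species") {
  stopifnot(is.list(summaries), length(summaries) > 0L)
  if (is.null(names(summaries)) || any(!nzchar(names(summaries)))) {
    stop("summaries must be a named list (names = query compounds)")
  }
  taxa <- taxa_at_rank(tree, rank)
  mat <- matrix(0, nrow = length(summaries), ncol = nrow(taxa),
                dimnames = list(names(summaries), make.unique(taxa$name)))
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    hit <- match(taxa$taxid, s$taxid)
    vals <- ifelse(is.na(hit), 0, s$fraction_matched[hit])
    mat[i, ] <- vals
  }
  attr(mat, "taxids") <- taxa$taxid
  attr(mat, "rank") <- rank
  mat
}

#' Per-sample matched percentage
#'
#' For each query sample (a set of MS/MS spectra, e.g. one LC-MS/MS file of
#' a fecal extract), computes the percentage of its spectra with at least
#' one passing match in the reference database. The default parameters for
#' this cohort-screening mode are stricter than the single-query defaults:
#' cosine 0.7, at least 4 matched peaks, 0.02 Da tolerances, analog off.
#' Samples with no spectra are excluded with a warning.
#'
#' @param query_sets a named list mapping sample id to a list of
#'   preprocessed [ms_spectrum()].
#' @param db,index reference database and fragment index.
#' @param params a [search_params()]; see Details for the defaults.
#' @return A data.frame with columns `sample_id`, `n_query_spectra`,
#'   `n_matched_spectra`, `percent_matched`.
#' @export
per_sample_match_rate <- function(query_sets, db, index,
                                  params = search_params(
                                    cosine_threshold = 0.7,
                                    min_matched_peaks = 4L,
                                    precursor_tolerance = 0.02,
                                    fragment_tolerance = 0.02,
                                    analog_search = FALSE)) {
  stopifnot(is.list(query_sets), !is.null(names(query_sets)))
  rows <- list()
  for (sample_id in names(query_sets)) {
    spectra <- query_sets[[sample_id]]
    if (length(spectra) == 0L) {
      warning(sprintf("sample '%s' has no query spectra; excluded", sample_id))
      next
    }
    n_matched <- 0L
    for (q in spectra) {
      hits <- search_library(db, index, q, params)
      if (nrow(hits) > 0L) n_matched <- n_matched + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample_id,
      n_query_spectra = length(spectra),
      n_matched_spectra = n_matched,
      percent_matched = 100 * n_matched / length(spectra),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(sample_id = character(), n_query_spectra = integer(),
                      n_matched_spectra = integer(),
                      percent_matched = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export mirror-plot data for one match
#'
#' Emits both peak lists plus the matched-pair annotations (shared peaks
#' flagged, shift channel recorded) as JSON, the payload a mirror-plot
#' renderer needs. The similarity is recomputed with the scoring mode the
#' match was produced under (modified cosine for analog matches).
#'
#' @param query the query [ms_spectrum()].
#' @param match_row one row of a match data.frame.
#' @param db the reference database.
#' @param fragment_tolerance tolerance used for pairing (default 0.05 Da).
#' @param path optional output file.
#' @return The JSON string (invisibly when `path` is given).
#' @export
export_mirror_plot_data <- function(query, match_row, db,
                                    fragment_tolerance = 0.05, path = NULL) {
  stopifnot(nrow(match_row) == 1L)
  pos <- match(match_row$ref_spectrum_id, db$spectrum_id)
  if (is.na(pos)) {
    abort(paste0("reference spectrum not in database: ", match_row$ref_spectrum_id),
          "spectax_schema_error")
  }
  ref <- db$spectra[[pos]]
  r <- if (isTRUE(match_row$analog)) {
    modified_cosine_score(query, ref, fragment_tolerance)
  } else {
    cosine_score(query, ref, fragment_tolerance)
  }
  shared_q <- logical(n_peaks(query))
  shared_r <- logical(n_peaks(ref))
  shared_q[r$pairs$index_a] <- TRUE
  shared_r[r$pairs$index_b] <- TRUE
  doc <- list(
    format = "spectax-mirror-plot", version = 1L,
    score = r$score, n_matched_peaks = r$n_matched_peaks,
    query = list(id = query$spectrum_id, precursor_mz = query$precursor_mz,
                 mz = query$peaks[, "mz"], intensity = query$peaks[, "intensity"],
                 shared = shared_q),
    reference = list(id = ref$spectrum_id, precursor_mz = ref$precursor_mz,
                     mz = ref$peaks[, "mz"], intensity = ref$peaks[, "intensity"],
                     shared = shared_r),
    pairs = r$pairs
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Mirror plot of a query against a reference spectrum
#'
#' Query peaks point up, reference peaks point down; matched peaks are
#' drawn in color. Intensities are scaled to the base peak of each spectrum.
#'
#' @param query,ref [ms_spectrum()] objects.
#' @param result optional `similarity_result` (recomputed with
#'   [modified_cosine_score()] if missing).
#' @param ... passed to [graphics::plot()].
#' @return `result`, invisibly.
#' @export
plot_mirror <- function(query, ref, result = NULL, ...) {
  if (is.null(result)) result <- modified_cosine_score(query, ref)
  qi <- query$peaks[, "intensity"] / max(query$peaks[, "intensity"])
  ri <- ref$peaks[, "intensity"] / max(ref$peaks[, "intensity"])
  xlim <- range(query$peaks[, "mz"], ref$peaks[, "mz"])
  graphics::plot(NA, xlim = xlim, ylim = c(-1, 1), xlab = "m/z",
                 ylab = "relative intensity",
                 main = sprintf("score %.3f, %d matched peaks",
                                result$score, result$n_matched_peaks), ...)
  graphics::abline(h = 0, col = "grey60")
  colq <- rep("grey30", n_peaks(query))
  colr <- rep("grey30", n_peaks(ref))
  colq[result$pairs$index_a] <- "firebrick"
  colr[result$pairs$index_b] <- "firebrick"
  graphics::segments(query$peaks[, "mz"], 0, query$peaks[, "mz"], qi, col = colq)
  graphics::segments(ref$peaks[, "mz"], 0, ref$peaks[, "mz"], -ri, col = colr)
  invisible(result)
}
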