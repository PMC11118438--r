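#' Configuration for single and batch runs
#'
#' Collects everything a run needs: the reference side (either prebuilt
#' `db`/`index`/`tree` objects, or paths to MGF files, the metadata table
#' and a lineage table to build them from), the search parameters, the
#' output directory, and an optional offline USI resolver (a named list
#' mapping USI string to [ms_spectrum()]). There are no network calls: a
#' USI that the resolver does not know is an explicit error.
#'
#' @param out_dir output directory (created if needed).
#' @param db,index,tree prebuilt reference objects (optional).
#' @param ref_mgf_paths,metadata,lineage paths used to build the reference
#'   side when prebuilt objects are not supplied; `lineage` is a lineage
#'   table data.frame or TSV path with columns `record_taxid`, `taxid`,
#'   `name`, `rank`.
#' @param params a [search_params()].
#' @param usi_resolver named list mapping USI to spectrum (offline backend).
#' @param force overwrite existing outputs?
#' @param seed optional seed recorded in the manifest (fixture workflows).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       db = NULL, index = NULL, tree = NULL,
                       ref_mgf_paths = NULL, metadata = NULL, lineage = NULL,
                       params = search_params(),
                       usi_resolver = NULL,
                       force = FALSE, seed = NULL) {
  stopifnot(inherits(params, "search_params"))
  structure(
    list(out_dir = out_dir, db = db, index = index, tree = tree,
         ref_mgf_paths = ref_mgf_paths, metadata = metadata,
         lineage = lineage, params = params, usi_resolver = usi_resolver,
         force = isTRUE(force), seed = seed),
    class = "run_config"
  )
}

# build (or pass through) the reference objects a run needs
ensure_reference <- function(config) {
  if (is.null(config$db)) {
    if (is.null(config$ref_mgf_paths) || is.null(config$metadata)) {
      stop("run_config needs either a prebuilt db or ref_mgf_paths + metadata")
    }
    config$db <- build_reference_db(config$ref_mgf_paths, config$metadata)
  }
  if (is.null(config$index)) {
    config$index <- build_fragment_index(config$db,
                                         config$params$fragment_tolerance)
  }
  if (is.null(config$tree)) {
    if (is.null(config$lineage)) {
      stop("run_config needs either a prebuilt tree or a lineage table")
    }
    lin <- config$lineage
    if (is.character(lin)) {
      lin <- read.table(lin, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    }
    config$tree <- attach_sample_counts(build_taxon_tree(lin),
                                        config$db$metadata)
  }
  config
}

resolve_usi_query <- function(config, usi) {
  parse_usi(usi)  # validates the grammar before resolution
  q <- config$usi_resolver[[usi]]
  if (is.null(q)) {
    abort(paste0("USI resolver unavailable for '", usi,
                 "' (offline resolver has no entry; no network calls are made)"),
          "spectax_resolver_error")
  }
  q
}

run_outputs <- function(out_dir) {
  c(matches = file.path(out_dir, "matches.tsv"),
    summary = file.path(out_dir, "taxon_summary.tsv"),
    tree = file.path(out_dir, "tree.json"),
    manifest = file.path(out_dir, "manifest.json"))
}

write_manifest <- function(config, path, extra = list()) {
  digest_of <- function(p) {
    if (is.character(p) && length(p) == 1L && file.exists(p)) {
      unname(tools::md5sum(p))
    } else NA_character_
  }
  doc <- c(list(
    tool = "spectax",
    version = as.character(utils::packageVersion("spectax")),
    params = unclass(config$params),
    seed = config$seed,
    metadata_digest = digest_of(config$metadata),
    lineage_digest = if (is.character(config$lineage)) digest_of(config$lineage) else NA_character_
  ), extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run a single-query search end to end
#'
#' Searches one spectrum against the reference database and writes a result
#' bundle to `config$out_dir`: the spectrum-level match table
#' (`matches.tsv`), the per-taxon summary (`taxon_summary.tsv`), the result
#' tree pruned to the matched taxa and their ancestors (`tree.json`), and a
#' run manifest (`manifest.json`) recording all parameters and input
#' digests. Outputs are deterministic for fixed inputs and are never
#' overwritten unless `force = TRUE` was set.
#'
#' @param config a [run_config()].
#' @param query a preprocessed [ms_spectrum()] (peaks mode), or `NULL` when
#'   `usi` is given.
#' @param usi a USI string resolved through the configured offline resolver.
#' @return Invisibly, a list with `matches`, `summary`, `paths`.
#' @export
run_single <- function(config, query = NULL, usi = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(query) == is.null(usi)) {
    stop("supply exactly one of query= or usi=")
  }
  if (!is.null(usi)) query <- resolve_usi_query(config, usi)
  check_searchable(query, "query spectrum")
  config <- ensure_reference(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- run_outputs(config$out_dir)
  exists <- file.exists(paths)
  if (any(exists) && !config$force) {
    stop("output file(s) already exist (use force = TRUE to overwrite): ",
         paste(paths[exists], collapse = ", "))
  }

  matches <- search_library(config$db, config$index, query, config$params)
  summary <- summarize_by_taxon(matches, config$db$metadata, config$tree)
  matched_nodes <- summary$taxid[summary$n_matched_samples > 0L]
  pruned <- prune_tree_to_results(config$tree, matched_nodes)

  write_match_table(matches, paths[["matches"]])
  write_taxon_summary(summary, paths[["summary"]])
  tree_to_json(pruned, paths[["tree"]])
  write_manifest(config, paths[["manifest"]],
                 extra = list(mode = if (is.null(usi)) "peaks" else "usi",
                              query_id = query$spectrum_id,
                              n_matches = nrow(matches)))
  invisible(list(matches = matches, summary = summary, paths = paths))
}

#' Run a batch of queries
#'
#' Accepts a query MGF file, a CSV/TSV table of USIs (column `usi`), or a
#' list of spectra. Each query gets its own result bundle in a namespaced
#' subdirectory of `config$out_dir`; a combined table of
#' (query, matched file) rows, a failure log for malformed queries (the run
#' continues past them), and a batch manifest are written at the top level.
#'
#' @param config a [run_config()].
#' @param query_mgf path to an MGF of query spectra.
#' @param usi_table path to a CSV/TSV with a `usi` column.
#' @param queries a list of preprocessed [ms_spectrum()].
#' @return Invisibly, a list with `results` (per-query run_single results),
#'   `combined` (data.frame), `failures` (data.frame).
#' @export
run_batch <- function(config, query_mgf = NULL, usi_table = NULL,
                      queries = NULL) {
  stopifnot(inherits(config, "run_config"))
  supplied <- c(!is.null(query_mgf), !is.null(usi_table), !is.null(queries))
  if (sum(supplied) != 1L) {
    stop("supply exactly one of query_mgf=, usi_table= or queries=")
  }
  usis <- NULL
  if (!is.null(query_mgf)) {
    queries <- lapply(read_mgf(query_mgf), preprocess_spectrum)
  } else if (!is.null(usi_table)) {
    sep <- if (grepl("\\.csv$", usi_table, ignore.case = TRUE)) "," else "\t"
    tab <- read.table(usi_table, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    if (!"usi" %in% names(tab)) {
      abort("USI table must have a 'usi' column", "spectax_schema_error")
    }
    usis <- tab$usi
    queries <- vector("list", length(usis))
  }
  if (length(queries) == 0L) stop("no queries")

  config <- ensure_reference(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  combined <- list()
  failures <- list()
  for (i in seq_along(queries)) {
    qid <- if (!is.null(usis)) usis[i] else queries[[i]]$spectrum_id
    sub <- file.path(config$out_dir,
                     sprintf("query_%03d_%s", i, gsub("[^A-Za-z0-9._-]", "_", qid)))
    sub_config <- config
    sub_config$out_dir <- sub
    res <- tryCatch({
      if (!is.null(usis)) {
        run_single(sub_config, usi = usis[i])
      } else {
        run_single(sub_config, query = queries[[i]])
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        query_id = qid, error = conditionMessage(res),
        stringsAsFactors = FALSE)
      next
    }
    results[[qid]] <- res
    if (nrow(res$matches) > 0L) {
      combined[[length(combined) + 1L]] <-
        cbind(query_id = qid,
              matches_by_file(res$matches)[, c("ref_file", "massive_id",
                                               "taxon_name", "ncbi_taxid",
                                               "score", "n_matched_peaks")])
    }
  }
  combined <- if (length(combined)) do.call(rbind, combined) else
    data.frame(query_id = character(), ref_file = character(),
               massive_id = character(), taxon_name = character(),
               ncbi_taxid = integer(), score = numeric(),
               n_matched_peaks = integer(), stringsAsFactors = FALSE)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(query_id = character(), error = character(),
               stringsAsFactors = FALSE)
  write.table(combined, file.path(config$out_dir, "combined_matches.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(failures)) {
    write.table(failures, file.path(config$out_dir, "failures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 extra = list(mode = "batch", n_queries = length(queries),
                              n_failed = nrow(failures)))
  invisible(list(results = results, combined = combined, failures = failures))
}
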