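#' Specification for a synthetic test world
#'
#' Describes a deterministic synthetic taxonomy, reference library and query
#' set with known ground truth, so the whole search pipeline is testable
#' offline. The defaults give a small but structured world: 3 families x 2
#' genera x 2 species, 2 files per species, 4 spectra per file, 8-16 peaks
#' per spectrum drawn uniformly over \[50, precursor - 10\] Da with
#' exponential intensities; query m/z jitter sd 0.01 Da (a fifth of the
#' default fragment tolerance, so planted matches stay recoverable), 20%
#' peak dropout, a hexose-like +162.053 Da analog shift, and 10% blank/QC
#' files.
#'
#' Each generation stage draws from its own RNG stream derived from the
#' master seed, so changing one stage's parameters does not perturb the
#' others.
#'
#' @param seed master RNG seed.
#' @param n_families,genera_per_family,species_per_genus taxonomy shape.
#' @param files_per_species,spectra_per_file library shape.
#' @param peaks_min,peaks_max range of peaks per spectrum.
#' @param precursor_min,precursor_max precursor m/z range in Da.
#' @param intensity_rate rate of the exponential intensity distribution.
#' @param jitter_sd Gaussian m/z jitter sd (Da) applied to exact queries.
#' @param dropout_fraction fraction of peaks dropped from exact queries.
#' @param n_exact_queries,n_analog_queries,n_decoy_queries query counts.
#' @param analog_shifts candidate precursor/fragment shifts (Da) for analog
#'   queries.
#' @param blank_fraction blank/QC files as a fraction of non-blank files.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L,
                         n_families = 3L, genera_per_family = 2L,
                         species_per_genus = 2L,
                         files_per_species = 2L, spectra_per_file = 4L,
                         peaks_min = 8L, peaks_max = 16L,
                         precursor_min = 150, precursor_max = 800,
                         intensity_rate = 1,
                         jitter_sd = 0.01, dropout_fraction = 0.2,
                         n_exact_queries = 10L, n_analog_queries = 5L,
                         n_decoy_queries = 5L,
                         analog_shifts = 162.053,
                         blank_fraction = 0.1) {
  stopifnot(
    n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
    files_per_species >= 1, spectra_per_file >= 1,
    peaks_min >= 3, peaks_max >= peaks_min,
    precursor_min > 60, precursor_max > precursor_min,
    intensity_rate > 0, jitter_sd >= 0,
    dropout_fraction >= 0, dropout_fraction < 1,
    n_exact_queries >= 0, n_analog_queries >= 0, n_decoy_queries >= 0,
    blank_fraction >= 0, blank_fraction < 1
  )
  structure(as.list(environment()), class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  n_sp <- x$n_families * x$genera_per_family * x$species_per_genus
  cat(sprintf(
    "<fixture_spec> seed %d: %d families -> %d species, %d files, %d spectra/file\n",
    x$seed, x$n_families, n_sp, n_sp * x$files_per_species, x$spectra_per_file))
  invisible(x)
}

#' Generate a synthetic taxonomy as a lineage table
#'
#' Builds a balanced plant-like taxonomy under a single kingdom / phylum /
#' class / order spine, with the configured numbers of families, genera and
#' species, and returns one lineage record per species in the long form
#' [build_taxon_tree()] consumes. Taxids are assigned deterministically
#' (kingdom 10, phylum 11, class 12, order 13, families 100+, genera 1000+,
#' species 1000000+), so the table is identical for identical specs.
#'
#' @param spec a [fixture_spec()].
#' @return A data.frame with columns `record_taxid`, `taxid`, `name`,
#'   `rank`.
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  spine <- data.frame(
    taxid = c(10, 11, 12, 13),
    name = c("Synviridae", "Synstreptophyta", "Synopsida", "Synales"),
    rank = c("kingdom", "phylum", "class", "order"),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (f in seq_len(spec$n_families)) {
    fam_id <- 100 + f
    fam <- sprintf("Famaceae%02d", f)
    for (g in seq_len(spec$genera_per_family)) {
      gen_id <- 1000 + (f - 1) * spec$genera_per_family + g
      gen <- sprintf("Genus%02d_%02d", f, g)
      for (s in seq_len(spec$species_per_genus)) {
        sp_id <- 1e6 + ((f - 1) * spec$genera_per_family + (g - 1)) *
          spec$species_per_genus + s
        sp <- sprintf("%s specius%02d", gen, s)
        rec <- rbind(
          spine,
          data.frame(taxid = c(fam_id, gen_id, sp_id),
                     name = c(fam, gen, sp),
                     rank = c("family", "genus", "species"),
                     stringsAsFactors = FALSE)
        )
        rec$record_taxid <- sp_id
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("record_taxid", "taxid", "name", "rank")]
}

#' Generate a synthetic reference library on disk
#'
#' Writes one MGF per reference file (laid out `dir/<Dataset>/<Filename>`)
#' plus the eight-column metadata TSV. Each species receives
#' `files_per_species` files of `spectra_per_file` spectra; peak m/z values
#' are uniform on \[50, precursor - 10\] with exponential intensities. A
#' `blank_fraction` of additional files is flagged blank/QC (no taxid).
#' Output is byte-identical for identical specs.
#'
#' @param spec a [fixture_spec()].
#' @param lineage a [generate_taxonomy()] table.
#' @param dir output directory (created if needed).
#' @return A list of class `fixture_library`: `mgf_paths`, `metadata_path`,
#'   `metadata`, `lineage`, `dir`.
#' @export
generate_reference_library <- function(spec, lineage, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(stage_seed(spec$seed, "library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  species <- unique(lineage[lineage$rank == "species",
                            c("record_taxid", "name")])
  fam_of <- vapply(split(lineage, lineage$record_taxid), function(rec) {
    rec$name[rec$rank == "family"][1L]
  }, "")
  fam_names <- unique(lineage$name[lineage$rank == "family"])
  dataset_of_family <- setNames(
    sprintf("SYNMSV%06d", 100000 + seq_along(fam_names)), fam_names)

  meta <- list()
  mgf_paths <- character()
  make_spectrum <- function(id) {
    prec <- runif(1, spec$precursor_min, spec$precursor_max)
    npk <- sample(spec$peaks_min:spec$peaks_max, 1L)
    mz <- sort(runif(npk, 50, prec - 10))
    it <- rexp(npk, spec$intensity_rate)
    ms_spectrum(id, prec, mz, it)
  }
  write_reference_file <- function(dataset, filename, taxid, taxon_name,
                                   is_blank) {
    dsfn <- paste(dataset, filename, sep = "/")
    subdir <- file.path(dir, dataset)
    dir.create(subdir, showWarnings = FALSE)
    spectra <- lapply(seq_len(spec$spectra_per_file), function(k) {
      make_spectrum(sprintf("%s:scan:%d", dsfn, k))
    })
    path <- file.path(subdir, filename)
    write_mgf(spectra, path)
    mgf_paths[[length(mgf_paths) + 1L]] <<- path
    meta[[length(meta) + 1L]] <<- data.frame(
      file_path = path,
      dataset_filename = dsfn,
      massive_id = dataset,
      taxon_name = taxon_name,
      ncbi_taxid = if (is_blank) NA_integer_ else as.integer(taxid),
      redu_available = !is_blank,
      is_blank_or_qc = is_blank,
      file_usi = sprintf("mzspec:%s:%s:scan:1", dataset, filename),
      stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(nrow(species))) {
    taxid <- species$record_taxid[i]
    fam <- fam_of[[as.character(taxid)]]
    dataset <- dataset_of_family[[fam]]
    for (r in seq_len(spec$files_per_species)) {
      write_reference_file(dataset,
                           sprintf("sp%d_r%02d.mgf", taxid, r),
                           taxid, species$name[i], is_blank = FALSE)
    }
  }
  n_blank <- ceiling(spec$blank_fraction * length(mgf_paths))
  for (b in seq_len(n_blank)) {
    write_reference_file(dataset_of_family[[1L]],
                         sprintf("blank_%02d.mgf", b),
                         NA, "blank", is_blank = TRUE)
  }

  metadata <- do.call(rbind, meta)
  metadata_path <- file.path(dir, "metadata.tsv")
  write_metadata_table(metadata, metadata_path)
  structure(list(mgf_paths = mgf_paths, metadata_path = metadata_path,
                 metadata = metadata, lineage = lineage, dir = dir),
            class = "fixture_library")
}

# dropout that keeps the planted query recoverable: redraws the dropped
# subset (up to 20 times, then drops fewer peaks) until the kept peaks carry
# at least 75% of the squared intensity, so the true cosine (the kept L2
# fraction) stays well above the 0.7 default threshold
recoverable_dropout <- function(mz, it, n_drop, min_keep = 3L,
                                min_l2_fraction = 0.75) {
  n <- length(mz)
  n_drop <- min(n_drop, n - min_keep)
  total2 <- sum(it^2)
  while (n_drop > 0L) {
    for (try in 1:20) {
      keep <- sort(sample.int(n, n - n_drop))
      if (sum(it[keep]^2) / total2 >= min_l2_fraction) return(keep)
    }
    n_drop <- n_drop - 1L
  }
  seq_len(n)
}

#' Generate a query set with ground truth
#'
#' Draws exact queries (copies of reference spectra with Gaussian m/z jitter
#' and recoverable random peak dropout), analog queries (unjittered copies
#' with precursor and every fragment shifted by an analog delta), and decoy
#' queries whose fragments live in an m/z regime disjoint from all reference
#' fragments (so they can never share `min_matched_peaks` fragment bins with
#' any reference — decoy rejection is exact by construction, not
#' statistical).
#'
#' @param spec a [fixture_spec()].
#' @param db a [build_reference_db()] built from the fixture library.
#' @return A list: `queries` (list of [ms_spectrum()]) and `ground_truth`
#'   (data.frame with `query_id`, `kind`, `ref_spectrum_id`, `ref_file`,
#'   `ncbi_taxid`, `shift`).
#' @export
generate_query_set <- function(spec, db) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(db, "reference_db"))
  set.seed(stage_seed(spec$seed, "queries"))
  blank_files <- db$metadata$dataset_filename[db$metadata$is_blank_or_qc]
  eligible <- which(!(db$file %in% blank_files))
  stopifnot(length(eligible) > 0L)
  taxid_of_file <- setNames(db$metadata$ncbi_taxid,
                            db$metadata$dataset_filename)

  queries <- list()
  gt <- list()
  add <- function(q, kind, ref_idx, shift) {
    queries[[length(queries) + 1L]] <<- q
    gt[[length(gt) + 1L]] <<- data.frame(
      query_id = q$spectrum_id, kind = kind,
      ref_spectrum_id = if (is.na(ref_idx)) NA_character_ else db$spectrum_id[ref_idx],
      ref_file = if (is.na(ref_idx)) NA_character_ else db$file[ref_idx],
      ncbi_taxid = if (is.na(ref_idx)) NA_integer_ else
        taxid_of_file[[db$file[ref_idx]]],
      shift = shift, stringsAsFactors = FALSE)
  }

  for (k in seq_len(spec$n_exact_queries)) {
    ref_idx <- sample(eligible, 1L)
    ref <- db$spectra[[ref_idx]]
    mz <- ref$peaks[, "mz"]
    it <- ref$peaks[, "intensity"]
    keep <- recoverable_dropout(mz, it,
                                n_drop = floor(spec$dropout_fraction * length(mz)))
    mz <- mz[keep] + rnorm(length(keep), sd = spec$jitter_sd)
    q <- ms_spectrum(sprintf("exact_%03d", k), ref$precursor_mz,
                     mz[order(mz)], it[keep][order(mz)])
    add(q, "exact", ref_idx, 0)
  }
  for (k in seq_len(spec$n_analog_queries)) {
    ref_idx <- sample(eligible, 1L)
    ref <- db$spectra[[ref_idx]]
    shift <- if (length(spec$analog_shifts) == 1L) spec$analog_shifts else
      sample(spec$analog_shifts, 1L)
    q <- ms_spectrum(sprintf("analog_%03d", k), ref$precursor_mz + shift,
                     ref$peaks[, "mz"] + shift, ref$peaks[, "intensity"])
    add(q, "analog", ref_idx, shift)
  }
  if (spec$n_decoy_queries > 0L) {
    # decoy fragment regime: strictly above every reference fragment bin
    decoy_lo <- max(spec$precursor_max, 1000) + 100
    for (k in seq_len(spec$n_decoy_queries)) {
      prec <- runif(1, spec$precursor_min, spec$precursor_max)
      npk <- sample(spec$peaks_min:spec$peaks_max, 1L)
      mz <- sort(runif(npk, decoy_lo, decoy_lo + 500))
      q <- ms_spectrum(sprintf("decoy_%03d", k), prec, mz, rexp(npk, spec$intensity_rate))
      add(q, "decoy", NA, 0)
    }
  }
  list(queries = queries, ground_truth = do.call(rbind, gt))
}

#' Evaluate a query set against its ground truth
#'
#' Runs every query through [search_library()] and scores recovery: an
#' exact/analog query is recovered if its source file is among the matched
#' files; a decoy is a false positive if it matches anything.
#'
#' @param db,index reference database and index.
#' @param query_set a [generate_query_set()] result.
#' @param params a [search_params()] (analog queries are evaluated with
#'   `analog_search = TRUE` when `analog = TRUE` is passed).
#' @param analog evaluate in analog mode?
#' @return A list with `recall` (fraction of recoverable queries recovered:
#'   exact queries always, analog queries only in analog mode),
#'   `n_decoy_matches`, and the per-query data.frame `detail`.
#' @export
evaluate_query_set <- function(db, index, query_set,
                               params = search_params(), analog = FALSE) {
  if (analog) params$analog_search <- TRUE
  gt <- query_set$ground_truth
  rows <- lapply(seq_along(query_set$queries), function(i) {
    q <- query_set$queries[[i]]
    hits <- search_library(db, index, q, params)
    data.frame(query_id = q$spectrum_id,
               kind = gt$kind[i],
               n_matches = nrow(hits),
               recovered = !is.na(gt$ref_file[i]) &&
                 gt$ref_file[i] %in% hits$ref_file,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, rows)
  planted <- detail$kind == "exact" |
    (detail$kind == "analog" & params$analog_search)
  list(
    recall = if (any(planted)) mean(detail$recovered[planted]) else NA_real_,
    n_decoy_matches = sum(detail$n_matches[detail$kind == "decoy"]),
    detail = detail
  )
}

#' Inventory counts of a reference collection
#'
#' Distinct non-blank taxids in the metadata plus the number of families,
#' genera and species represented in the tree (nodes of that rank with at
#' least one sample in their subtree).
#'
#' @param metadata the metadata table.
#' @param tree a `taxon_tree` with sample counts attached.
#' @return A named list: `n_distinct_taxids`, `n_families`, `n_genera`,
#'   `n_species`.
#' @export
db_inventory <- function(metadata, tree) {
  nb <- metadata[!metadata$is_blank_or_qc, , drop = FALSE]
  list(
    n_distinct_taxids = length(unique(nb$ncbi_taxid)),
    n_families = nrow(taxa_at_rank(tree, "family")),
    n_genera = nrow(taxa_at_rank(tree, "genus")),
    n_species = nrow(taxa_at_rank(tree, "species"))
  )
}
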