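test_that("build_reference_db links spectra to metadata and orders deterministically", {
  w <- make_world(seed = 51)
  expect_s3_class(w$db, "reference_db")
  expect_equal(length(w$db$spectra),
               nrow(w$lib$metadata) * w$spec$spectra_per_file)
  expect_equal(length(w$db$by_file), nrow(w$lib$metadata))
  expect_false(is.unsorted(w$db$file))
  # every spectrum resolves to exactly one metadata row
  expect_true(all(w$db$file %in% w$lib$metadata$dataset_filename))
})

test_that("an MGF with no metadata row is a hard error naming the orphan", {
  w <- make_world(seed = 52)
  orphan <- tempfile(fileext = ".mgf")
  write_mgf(list(ms_spectrum("o", 300, c(100, 150), c(1, 1))), orphan)
  expect_error(
    build_reference_db(c(w$lib$mgf_paths, orphan), w$lib$metadata),
    basename(orphan)
  )
})

test_that("fragment index conserves postings and bins by floor(mz / width)", {
  w <- make_world(seed = 53)
  total_peaks <- sum(vapply(w$db$spectra, n_peaks, 0L))
  expect_equal(w$idx$n_postings, total_peaks)
  expect_error(build_fragment_index(w$db, 0), class = "spectax_parameter_error")

  # one tiny db: bin arithmetic
  dir <- tempfile(); dir.create(file.path(dir, "D"), recursive = TRUE)
  write_mgf(list(ms_spectrum("s", 300, c(100.00, 100.06, 250.2), c(1, 1, 1))),
            file.path(dir, "D", "f.mgf"))
  meta <- data.frame(file_path = file.path(dir, "D", "f.mgf"),
                     dataset_filename = "D/f.mgf", massive_id = "D",
                     taxon_name = "t", ncbi_taxid = 1L,
                     redu_available = TRUE, is_blank_or_qc = FALSE,
                     file_usi = "mzspec:D:f:scan:1")
  db1 <- build_reference_db(file.path(dir, "D", "f.mgf"), meta)
  idx1 <- build_fragment_index(db1, 0.05)
  expect_equal(idx1$n_postings, 3L)
  expect_equal(nrow(idx1$postings[["2000"]]), 1L)  # floor(100.00 / 0.05)
  expect_equal(nrow(idx1$postings[["2001"]]), 1L)  # floor(100.06 / 0.05)
})

test_that("a query identical to a reference spectrum scores 1.0 for its file", {
  w <- make_world(seed = 54)
  q <- w$db$spectra[[17]]
  hits <- search_library(w$db, w$idx, q)
  expect_true(w$db$file[17] %in% hits$ref_file)
  self_row <- hits[hits$ref_spectrum_id == w$db$spectrum_id[17], ]
  expect_equal(self_row$score, 1, tolerance = 1e-9)
})

test_that("the precursor gate excludes references outside the tolerance", {
  dir <- tempfile(); dir.create(file.path(dir, "D"), recursive = TRUE)
  ref <- ms_spectrum("r", 300.2, c(100, 150, 200), c(1, 1, 1))
  write_mgf(list(ref), file.path(dir, "D", "f.mgf"))
  meta <- data.frame(file_path = file.path(dir, "D", "f.mgf"),
                     dataset_filename = "D/f.mgf", massive_id = "D",
                     taxon_name = "t", ncbi_taxid = 1L,
                     redu_available = TRUE, is_blank_or_qc = FALSE,
                     file_usi = "mzspec:D:f:scan:1")
  db <- build_reference_db(file.path(dir, "D", "f.mgf"), meta)
  idx <- build_fragment_index(db)
  q <- ms_spectrum("q", 300.0, c(100, 150, 200), c(1, 1, 1))
  expect_equal(nrow(search_library(db, idx, q)), 0L)
  expect_equal(nrow(brute_force_search(db, q)), 0L)
  # within tolerance it matches
  q2 <- ms_spectrum("q2", 300.16, c(100, 150, 200), c(1, 1, 1))
  expect_equal(nrow(search_library(db, idx, q2)), 1L)
})

test_that("indexed search equals brute force on fuzzed queries (small world)", {
  w <- make_world(seed = 55, n_exact_queries = 30L, n_analog_queries = 0L,
                  n_decoy_queries = 15L)
  qs <- generate_query_set(w$spec, w$db)
  set.seed(56)
  randoms <- lapply(1:30, function(k) {
    prec <- sample(w$db$precursor, 1) + runif(1, -0.04, 0.04)
    rand_spectrum(sprintf("r%02d", k), sample(5:15, 1), precursor = prec)
  })
  p <- search_params()
  for (q in c(qs$queries, randoms)) {
    expect_same_matches(search_library(w$db, w$idx, q, p),
                        brute_force_search(w$db, q, p))
  }
})

test_that("indexed search equals brute force in analog mode", {
  w <- make_world(seed = 57, n_exact_queries = 10L, n_analog_queries = 10L,
                  n_decoy_queries = 5L)
  qs <- generate_query_set(w$spec, w$db)
  p <- search_params(analog_search = TRUE)
  for (q in qs$queries) {
    expect_same_matches(search_library(w$db, w$idx, q, p),
                        brute_force_search(w$db, q, p))
  }
})

test_that("brute force on an empty database returns an empty table", {
  w <- make_world(seed = 58)
  empty_db <- build_reference_db(character(0), w$lib$metadata)
  q <- rand_spectrum("q", 10, 500)
  expect_equal(nrow(brute_force_search(empty_db, q)), 0L)
})

test_that("raising thresholds never adds matches", {
  w <- make_world(seed = 59, n_exact_queries = 10L)
  qs <- generate_query_set(w$spec, w$db)
  for (q in qs$queries[1:10]) {
    base <- search_library(w$db, w$idx, q, search_params())
    stricter_cos <- search_library(w$db, w$idx, q,
                                   search_params(cosine_threshold = 0.9))
    stricter_pk <- search_library(w$db, w$idx, q,
                                  search_params(min_matched_peaks = 6L))
    expect_true(all(stricter_cos$ref_spectrum_id %in% base$ref_spectrum_id))
    expect_true(all(stricter_pk$ref_spectrum_id %in% base$ref_spectrum_id))
  }
})

test_that("analog-shifted queries match only in analog mode", {
  w <- make_world(seed = 60, n_exact_queries = 0L, n_analog_queries = 8L,
                  n_decoy_queries = 0L)
  qs <- generate_query_set(w$spec, w$db)
  gt <- qs$ground_truth
  for (i in seq_along(qs$queries)) {
    q <- qs$queries[[i]]
    exact <- search_library(w$db, w$idx, q, search_params())
    expect_equal(nrow(exact), 0L)
    analog <- search_library(w$db, w$idx, q, search_params(analog_search = TRUE))
    expect_true(gt$ref_file[i] %in% analog$ref_file)
    best <- analog[analog$ref_spectrum_id == gt$ref_spectrum_id[i], ]
    expect_equal(best$score, 1, tolerance = 1e-9)
    expect_true(best$analog)
  }
})

test_that("annotate_query names the query compound and respects analog gating", {
  w <- make_world(seed = 61)
  q <- w$db$spectra[[5]]
  lib <- list(q, w$db$spectra[[9]])
  lib[[1]]$spectrum_id <- "compound A"
  ann <- annotate_query(q, lib)
  expect_equal(ann$compound[1], "compound A")
  expect_equal(ann$score[1], 1, tolerance = 1e-9)

  expect_equal(nrow(annotate_query(q, list())), 0L)

  shift <- 162.053
  analog_q <- ms_spectrum("aq", q$precursor_mz + shift,
                          q$peaks[, "mz"] + shift, q$peaks[, "intensity"])
  expect_equal(nrow(annotate_query(analog_q, lib)), 0L)
  ann2 <- annotate_query(analog_q, lib, search_params(analog_search = TRUE))
  expect_equal(ann2$compound[1], "compound A")
  expect_true(ann2$analog[1])
})

test_that("saved reference index reloads to identical search results", {
  w <- make_world(seed = 62, n_exact_queries = 5L)
  path <- tempfile(fileext = ".json")
  save_reference_index(w$db, w$idx, path)
  re <- load_reference_index(path)
  qs <- generate_query_set(w$spec, w$db)
  for (q in qs$queries[1:5]) {
    expect_same_matches(search_library(w$db, w$idx, q),
                        search_library(re$db, re$index, q))
  }
})
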