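test_that("read_mgf parses blocks, keeps the first PEPMASS value, reads charge", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=first",
    "PEPMASS=500.2 12345.6",
    "CHARGE=2+",
    "100.1 10",
    "200.2 20",
    "300.3 5",
    "END IONS",
    "",
    "BEGIN IONS",
    "PEPMASS=123.4",
    "50.5\t1",
    "END IONS"
  ), path)
  spectra <- read_mgf(path)
  expect_length(spectra, 2L)
  expect_equal(spectra[[1]]$precursor_mz, 500.2)
  expect_equal(spectra[[1]]$spectrum_id, "first")
  expect_equal(spectra[[1]]$charge, 2L)
  expect_equal(n_peaks(spectra[[1]]), 3L)
  expect_equal(spectra[[1]]$peaks[, "intensity"], c(10, 20, 5))
  expect_equal(unname(spectra[[2]]$peaks[, "mz"]), 50.5)  # tab-separated peak line
  expect_true(is.na(spectra[[2]]$charge))
})

test_that("read_mgf handles degenerate and malformed inputs", {
  empty <- tempfile(fileext = ".mgf")
  file.create(empty)
  expect_identical(read_mgf(empty), list())

  no_pepmass <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "100 1", "END IONS"), no_pepmass)
  expect_error(read_mgf(no_pepmass), "block 1 lacks PEPMASS",
               class = "spectax_parse_error")

  bad_peak <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "100 1", "oops nope", "END IONS"),
             bad_peak)
  expect_error(read_mgf(bad_peak), "line 4", class = "spectax_parse_error")
})

test_that("MGF round trip preserves precursor, charge and peaks", {
  set.seed(11)
  spectra <- lapply(1:20, function(i) {
    s <- rand_spectrum(sprintf("s%02d", i), n = sample(3:25, 1),
                       precursor = runif(1, 150, 900))
    s$charge <- sample(c(NA, 1L, 2L, -1L), 1)
    s
  })
  path <- tempfile(fileext = ".mgf")
  write_mgf(spectra, path)
  back <- read_mgf(path)
  expect_length(back, length(spectra))
  for (i in seq_along(spectra)) {
    expect_equal(back[[i]]$spectrum_id, spectra[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_mz, spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$charge, spectra[[i]]$charge)
    expect_equal(back[[i]]$peaks[, "mz"], spectra[[i]]$peaks[, "mz"],
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(back[[i]]$peaks[, "intensity"],
                 spectra[[i]]$peaks[, "intensity"],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # empty list round trips to an empty file
  p2 <- tempfile(fileext = ".mgf")
  write_mgf(list(), p2)
  expect_identical(read_mgf(p2), list())
})

test_that("USI parsing follows the grammar and serialization is its inverse", {
  u <- parse_usi("mzspec:MSV000086989:somefile:scan:123")
  expect_equal(u$collection, "MSV000086989")
  expect_equal(u$run, "somefile")
  expect_equal(u$index_type, "scan")
  expect_equal(u$index_value, "123")
  expect_true(is.na(u$interpretation))

  expect_error(parse_usi("notausi"), class = "spectax_usi_error")
  expect_error(parse_usi("mzspec:A:B:scan"), class = "spectax_usi_error")
  expect_error(parse_usi("mzspec:A:B:frame:1"), class = "spectax_usi_error")

  set.seed(5)
  for (i in 1:50) {
    parts <- c("mzspec",
               sprintf("MSV%06d", sample(1e6, 1)),
               paste0(sample(letters, 8, TRUE), collapse = ""),
               sample(c("scan", "index", "nativeId"), 1),
               as.character(sample(1e5, 1)))
    if (runif(1) < 0.5) {
      parts <- c(parts, "PEPTIDE", as.character(sample(3, 1)))  # interpretation with ':'
    }
    usi <- paste(parts, collapse = ":")
    expect_identical(serialize_usi(parse_usi(usi)), usi)
  }
})

test_that("metadata table reads with flexible headers and validates taxids", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("File_Path", "Dataset_Filename", "MassIVE_ID", "Taxon_Name",
          "TaxID", "ReDU", "Blank_QC", "USI", sep = "\t"),
    paste("/a/f1.mzML", "MSV01/f1.mzML", "MSV01", "Arabidopsis thaliana",
          "3702", "yes", "no", "mzspec:MSV01:f1:scan:1", sep = "\t"),
    paste("/a/f2.mzML", "MSV01/f2.mzML", "MSV01", "Zea mays",
          "4577", "no", "0", "mzspec:MSV01:f2:scan:1", sep = "\t"),
    paste("/a/b1.mzML", "MSV01/b1.mzML", "MSV01", "blank",
          "", "no", "TRUE", "mzspec:MSV01:b1:scan:1", sep = "\t")
  ), path)
  meta <- read_metadata_table(path)
  expect_equal(nrow(meta), 3L)
  expect_identical(meta$is_blank_or_qc, c(FALSE, FALSE, TRUE))
  expect_identical(meta$redu_available, c(TRUE, FALSE, FALSE))
  expect_equal(meta$ncbi_taxid, c(3702L, 4577L, NA))

  # non-blank row with empty taxid is a schema error
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste(META_COLUMNS <- c("file_path", "dataset_filename", "massive_id",
                            "taxon_name", "ncbi_taxid", "redu_available",
                            "is_blank_or_qc", "file_usi"), collapse = "\t"),
    paste("/a/x", "D/x", "D", "t", "", "no", "no", "u", sep = "\t")
  ), bad)
  expect_error(read_metadata_table(bad), "without an NCBI taxid",
               class = "spectax_schema_error")

  # missing mandatory column is named in the error
  miss <- tempfile(fileext = ".tsv")
  writeLines(c("file_path\tdataset_filename", "/a\tD/f"), miss)
  expect_error(read_metadata_table(miss), "massive_id",
               class = "spectax_schema_error")
})

test_that("metadata write/read round trips", {
  w <- make_world(seed = 3)
  p <- tempfile(fileext = ".csv")
  write_metadata_table(w$lib$metadata, p)
  back <- read_metadata_table(p)
  expect_equal(back$dataset_filename, w$lib$metadata$dataset_filename)
  expect_equal(back$ncbi_taxid, w$lib$metadata$ncbi_taxid)
  expect_equal(back$is_blank_or_qc, w$lib$metadata$is_blank_or_qc)
})

test_that("preprocess_spectrum sorts, filters, merges and is idempotent", {
  s <- ms_spectrum("x", 500, c(300, 100, 200, 200), c(1, 0, 2, 3))
  p <- preprocess_spectrum(s)
  expect_equal(p$peaks[, "mz"], c(200, 300), ignore_attr = TRUE)
  expect_equal(p$peaks[, "intensity"], c(5, 1), ignore_attr = TRUE)  # duplicates merged

  # precursor-window exclusion arithmetic
  s2 <- ms_spectrum("y", 500, c(480, 490), c(1, 1))
  p2 <- preprocess_spectrum(s2, precursor_exclusion_da = 17)
  expect_equal(p2$peaks[, "mz"], 480, ignore_attr = TRUE)

  # idempotency on random spectra
  set.seed(21)
  for (i in 1:20) {
    raw <- ms_spectrum("z", 600, runif(15, 50, 590),
                       rexp(15) * sample(c(0, 1), 15, TRUE, c(0.2, 0.8)))
    once <- tryCatch(preprocess_spectrum(raw),
                     spectax_empty_spectrum = function(e) NULL)
    if (!is.null(once)) expect_identical(preprocess_spectrum(once), once)
  }

  expect_error(preprocess_spectrum(ms_spectrum("w", 100, 99, 0)),
               class = "spectax_empty_spectrum")
})
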