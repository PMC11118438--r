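Package: spectax
Title: Taxonomically Informed Tandem Mass Spectrometry Library Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Search engine core for matching query MS/MS spectra against a
    file-level reference library of organism extracts and mapping the matches
    onto a rank-filtered NCBI-style taxonomic tree. Provides MGF and metadata
    table input/output, Universal Spectrum Identifier (USI) parsing, cosine
    and modified-cosine spectral similarity with tolerance-based greedy peak
    pairing, a binned fragment-ion inverted index with a brute-force search
    twin for verification, per-taxon matched-sample summaries, presence
    matrices and per-sample match rates, a batch runner, and a deterministic
    synthetic fixture generator (taxonomies, reference libraries, planted
    queries) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
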