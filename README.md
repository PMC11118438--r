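# spectax

Taxonomically informed tandem mass spectrometry (MS/MS) library search in R.

## What problem this solves

A single MS/MS spectrum is a fragment-ion fingerprint of one molecule.
Given such a fingerprint — a precursor m/z plus a list of
(m/z, intensity) peaks, or a Universal Spectrum Identifier (USI) —
researchers in natural products chemistry, chemotaxonomy and nutrition
want to know *in which organisms that molecule has been observed*.
spectax matches a query spectrum against a file-level reference library of
organism extracts (every reference spectrum tied to an LC-MS/MS file,
every file to an NCBI-style taxon) and reports, for every node of a
rank-filtered taxonomic tree, the fraction of samples in that clade
containing the queried spectrum.

The package is aimed at computational metabolomics users: it provides the
search core (I/O, scoring, indexing, taxonomy, aggregation, batch runs)
plus a deterministic synthetic-fixture generator so the full pipeline is
testable offline, with no reference downloads.

## The method in brief

Two spectra are compared by the **cosine similarity over tolerance-matched
peak pairs**: intensities are scaled to unit Euclidean norm, peaks pair
one-to-one when |Δm/z| ≤ τ_f (greedy by descending intensity product,
deterministic tie-breaks), and the score is the sum of products,

score(A, B) = Σ_{(i,j) paired} â_i · b̂_j ∈ [0, 1].

The **modified cosine** adds a second pairing channel shifted by the
precursor mass difference, recovering structural analogs, adducts and
multimers ("analog search"). A match is accepted when score ≥ 0.7 with ≥ 3
matched peaks at 0.05 Da precursor/fragment tolerances (the defaults; all
adjustable, all tolerances absolute Da). Search is accelerated by a binned
fragment-ion inverted index with a provably lossless candidate prefilter;
a brute-force twin (`brute_force_search()`) verifies the index on every
test run. Matches are collapsed from spectra to files (a file with ≥ 1
passing match is a matched sample) and aggregated over the taxonomy with
an exact per-node conservation invariant.

See `vignettes/spectral-taxonomy-search.Rmd` for the full account of the
model, parameter choices, and what the synthetic fixtures do and do not
emulate.

## Worked example

Build a small synthetic reference world and search a spectrum against it:

```r
library(spectax)

spec    <- fixture_spec(seed = 42)                    # 3 families, 12 species, 24 files
lineage <- generate_taxonomy(spec)
lib     <- generate_reference_library(spec, lineage, "demo_refs")
db      <- build_reference_db(lib$mgf_paths, lib$metadata_path)
index   <- build_fragment_index(db, bin_width = 0.05)
tree    <- attach_sample_counts(build_taxon_tree(lineage), db$metadata)

query <- db$spectra[[25]]   # a spectrum from one reference file
query
#> <ms_spectrum SYNMSV100001/sp1000002_r02.mgf:scan:1>  precursor m/z 495.1206  14 peaks

hits <- search_library(db, index, query, search_params())
hits[, c("ref_file", "taxon_name", "score", "n_matched_peaks")]
#>                         ref_file           taxon_name score n_matched_peaks
#> 1 SYNMSV100001/sp1000002_r02.mgf Genus01_01 specius02     1              14
```

The query is found (only) in its own source file, at cosine 1 with all 14
peaks matched. Aggregating over the tree:

```r
summ <- summarize_by_taxon(hits, db$metadata, tree)
subset(summ, n_matched_samples > 0)
#>     taxid    rank                 name n_total_samples n_matched_samples fraction_matched
#> 1      10 kingdom           Synviridae              24                 1       0.04166667
#> 2      11  phylum      Synstreptophyta              24                 1       0.04166667
#> 3      12   class            Synopsida              24                 1       0.04166667
#> 4      13   order              Synales              24                 1       0.04166667
#> 5     101  family           Famaceae01               8                 1       0.12500000
#> 6    1001   genus           Genus01_01               4                 1       0.25000000
#> 8 1000002 species Genus01_01 specius02               2                 1       0.50000000
```

Reading the last row: the matched species has 2 reference samples, 1 of
which contains the query, so 50% of its samples match; going up the tree
the same single matched file is 1 of 4 genus samples (25%), 1 of 8 family
samples (12.5%), and 1 of 24 samples overall. These are the per-node
percentages a results tree displays. `prune_tree_to_results()` +
`tree_to_json()` export exactly that result tree;
`run_single()`/`run_batch()` write the whole bundle (match TSV, taxon
summary TSV, pruned tree JSON, manifest) in one call, and
`inst/scripts/search-cli.R` wraps them for shell use.

Analog search (`search_params(analog_search = TRUE)`) scores with the
modified cosine over a ±200 Da precursor window — e.g. a glycosylated form
shifted by +162.053 Da matches its aglycone's spectrum at score 1.

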