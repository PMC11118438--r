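---
title: "Taxonomically informed MS/MS library search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomically informed MS/MS library search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectax)
```

## The problem

An untargeted LC-MS/MS experiment on an organism extract produces thousands
of tandem (MS/MS) spectra, each a fragment-ion fingerprint of one ionized
molecule. Given one such fingerprint — a precursor m/z and a list of
(m/z, intensity) fragment peaks — a natural question is: *in which organisms
has this molecule been observed?* spectax answers it by searching the query
spectrum against a reference library in which every spectrum is tied to an
LC-MS/MS file, and every file to a taxon (an NCBI-style taxonomy id). The
result is reported twice: as a flat table of matching files, and aggregated
over a rank-filtered taxonomic tree as the fraction of samples under each
node that contain the queried spectrum.

## Spectral similarity

Two spectra are compared with the **cosine similarity over tolerance-matched
peak pairs**. Each spectrum's intensity vector is scaled to unit Euclidean
norm; peaks `i` of the query and `j` of the reference are *candidate*
partners when

$$|m_i - (m_j + s)| \le \tau_f$$

for a shift channel `s` and fragment tolerance $\tau_f$ (Da). From the
candidates a one-to-one pairing is selected and the score is the sum of
normalized intensity products over selected pairs, so a spectrum scored
against itself gives exactly 1 and Cauchy–Schwarz bounds every score by 1.

* **Direct cosine** uses the single channel `s = 0`.
* **Modified cosine** adds `s = precursor(query) − precursor(reference)`.
  A structural analog, adduct or multimer shifts part of the fragment ladder
  by exactly the precursor delta; the second channel lets those peaks pair.
  Both channels compete for peaks and no peak is ever used twice.

**Pairing rule.** Candidates are ranked by descending normalized-intensity
product, with deterministic tie-breaks (smaller |Δm/z|, then lower query
index, then lower reference index), and accepted greedily subject to the
one-to-one constraint. We chose greedy selection over an optimal assignment
solver because it is the behavior of widely used spectral-search tools,
it is deterministic and fast, and on realistic spectra (sparse candidate
sets at 0.05 Da tolerance) it coincides with the optimum: the test suite
checks greedy against an exhaustive assignment oracle on hundreds of
randomized pairs of up to 8 peaks, including two-channel (modified-cosine)
cases, and on a fully ambiguous 2×2 candidate block, where the product
structure of the weights makes greedy provably optimal.

**Intensity weighting.** Raw intensities are unit-normalized with no
square-root transform; a `sqrt_transform` switch exists for users who prefer
variance-stabilized weighting. This choice is stated prominently because
score parity with any specific hosted service is not promised — the exact
cosine variant of such backends is generally unpublished.

A match is *accepted* when `score >= cosine_threshold` **and**
`n_matched_peaks >= min_matched_peaks`, both inclusive. Inclusivity is our
documented reading of thresholds quoted as bare numbers.

## Search parameters

| parameter | default | units | role |
|---|---|---|---|
| `cosine_threshold` | 0.7 | – | minimum accepted similarity |
| `min_matched_peaks` | 3 | count | minimum one-to-one peak pairs |
| `precursor_tolerance` | 0.05 | Da | exact-mode precursor gate |
| `fragment_tolerance` | 0.05 | Da | peak pairing window (= index bin width) |
| `analog_search` | off | – | widens the gate, scores with modified cosine |
| `analog_max_delta` | 200 | Da | analog-mode precursor window |

All tolerances are absolute Da, never ppm. The single-query defaults above
are the standard web-search settings for this family of tools; the
cohort-screening mode used by `per_sample_match_rate()` (e.g. scoring fecal
metabolomes for plant-derived molecules across diet groups) defaults to the
stricter 0.7 / 4 matched peaks / 0.02 Da / analog off. The analog precursor
window is not standardized anywhere we could rely on; 200 Da covers common
glycosylations, adduct exchanges and small multimer gaps, and is
configurable — treat it as a reporting choice, not a scientific constant.

Charge is parsed and stored but never used in scoring: precursor m/z values
are compared as-is, including multiply charged ions. Peak preprocessing
(dropping non-positive intensities, merging exact duplicate m/z, optional
precursor-window exclusion, optional relative intensity floor) is explicit
and idempotent; precursor exclusion is **off** by default so that a pasted
raw peak list is searched exactly as given.

## Indexed search and its verification twin

Exact-mode search proceeds in three stages:

1. **Precursor gate** — reference spectra with
   `|precursor delta| <= precursor_tolerance`.
2. **Fragment-bin prefilter** — every reference peak lives in bin
   `floor(mz / bin_width)` of an inverted index with
   `bin_width = fragment_tolerance`. For each query peak the bin and both
   neighbours are probed; a candidate must accumulate at least
   `min_matched_peaks` *distinct query peaks* with hits. Because any true
   pair within tolerance falls in a probed bin, and matched pairs use
   distinct query peaks, the filter is lossless: it can never remove a
   spectrum that would have passed the thresholds. (Counting distinct
   *bins* instead could undercount when two query peaks share a bin, which
   is why the per-query-peak count is used.)
3. **Scoring** — survivors are scored with the direct cosine and filtered by
   the thresholds; results sort by (score desc, |precursor delta| asc,
   reference spectrum id asc) so outputs are diffable.

Analog mode replaces the gate with `|delta| <= analog_max_delta` and scores
every gated candidate with the modified cosine, *without* the bin
prefilter: a shifted-channel-only match shares no unshifted bins, so
prefiltering would not be lossless there. At desk scale the wider gate is
affordable; a shifted-bin prefilter would be an opt-in optimization.

`brute_force_search()` implements the identical contract with no index and
no prefilter. It exists purely as an independent oracle: the suite and the
acceptance script check that indexed and brute-force searches return
identical match sets with scores agreeing to 1e-9 across a thousand fuzzed
queries on a 200-file × 50-spectrum world.

## The taxonomic tree

Lineage records (one ordered root-to-taxon path per taxon) are filtered to
the rank whitelist — kingdom, phylum, class, order, family, genus,
subgenus, species, subspecies, varietas ("varietas" being the NCBI rank
name we adopt for botanical varieties) — with descendants of removed ranks
re-attached to the nearest kept ancestor. Duplicate taxids collapse to one
node; conflicting parentage is an error, not a silent choice. Multiple
kingdoms join under a synthetic root (taxid 1, rank "no rank"). We do not
pad missing intermediate ranks to equalize path lengths; node identity and
counts, not plotted depth, are the contract here.

Sample counts attach per node: a non-blank reference file counts at the
node of its taxid — which may be an internal node, e.g. a sample identified
only to genus — and at every ancestor, never at descendants. Blank/QC files
are carried in the metadata (their spectra remain searchable) but are
excluded from all taxonomic totals. The conservation invariant

```
n_samples(node) = n_direct(node) + sum over children of n_samples(child)
```

is validated tree-wide by `validate_taxon_tree()`. Aggregation of matches
is **per file, not per spectrum**: a file with at least one passing match
is a matched sample, and a node's fraction is matched samples over total
samples in its subtree. Spectrum-level tables are exported alongside for
transparency.

Serialization is Newick (taxid labels on all nodes, so any phylogenetics
tool can read the topology) and a versioned JSON carrying name, rank,
taxid, `n_samples` and children; both round-trip in the test suite, the
Newick independently through `ape`.

## The synthetic world generator

Everything is testable offline because the generator builds complete study
worlds with known ground truth: a balanced taxonomy (default 3 families ×
2 genera × 2 species under a fixed kingdom–phylum–class–order spine), a
reference library (2 files per species, 4 spectra per file, 8–16 peaks
uniform on \[50, precursor − 10\] Da with exponential intensities,
precursors uniform on \[150, 800\] Da, 10% blank files), and three query
classes:

* **exact** — copies of reference spectra with Gaussian m/z jitter
  (sd 0.01 Da, a fifth of the fragment tolerance) and 20% random peak
  dropout;
* **analog** — unjittered copies with precursor and all fragments shifted
  by +162.053 Da (a hexose increment) by default;
* **decoy** — spectra whose fragments occupy an m/z regime strictly above
  every reference fragment, so they can never share `min_matched_peaks`
  fragment bins with any reference. Decoy rejection is therefore exact by
  construction rather than statistical.

Because the true cosine of a dropped-out copy equals the L2 fraction of
intensity retained, a random 20% dropout of exponentially distributed
intensities can occasionally remove dominant peaks and push that fraction
below the acceptance threshold. The generator's recoverability contract
therefore redraws the dropout subset (up to 20 attempts, then drops fewer
peaks) until the kept peaks carry ≥ 75% of the squared intensity — planted
exact queries are *recoverable by construction*, which is what makes the
100%-recall property a test of the search engine rather than of the dice.

Each generation stage (taxonomy, library, queries, fuzz) draws from its own
RNG stream derived from the master seed, so changing one stage's parameters
never perturbs another stage's output.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: real fragmentation chemistry (peaks are
uniform, not governed by bond energies), instrument-dependent intensity
response, collision-energy differences between query and reference spectra
of the same molecule, isomers with near-identical spectra, co-eluting
chimeric spectra, and real taxonomies' wildly unbalanced shapes. Recall on
real repositories will be lower than on planted fixtures for exactly these
reasons; the fixtures establish the *algorithmic* guarantees (losslessness
of the index, correctness of scoring and aggregation, gating behavior),
not biological sensitivity.

## Numerical and degenerate-input choices

* Tolerance comparisons are inclusive (`<=`); boundary peaks pair.
* Scores are clipped to \[0, 1\] after summation to absorb float drift.
* Peak pairing ties break deterministically (|Δm/z|, then indices); R's
  stable radix ordering makes results platform-independent.
* A spectrum emptied by preprocessing is an explicit classed error
  (`spectax_empty_spectrum`), not a zero-score result; in batch runs such
  rows are logged to a failure table and the run continues.
* MGF `PEPMASS` lines with two values keep the first (the precursor m/z);
  writing uses enough digits that a round trip is identity to 1e-6.
* USI resolution is an injectable offline map; an unknown USI is an
  explicit "resolver unavailable" error. No network calls anywhere.
* Problem sizes in the checks: the oracle-equivalence world uses 200
  non-blank files × 50 spectra (~10⁴ spectra, ~1.5×10⁵ indexed peaks) and
  1,000 fuzzed queries; property tests use 24-file worlds. These sizes
  exercise every code path while keeping the full suite under a minute.

## Known limitations

* Exact score parity with hosted search services is not guaranteed (their
  cosine variants are unpublished); the defaults and thresholds match the
  published search settings, the formula is the classic unit-norm cosine.
* The greedy pairing can in principle differ from the optimal assignment on
  adversarial candidate structures (partial 2×2 blocks with crossing
  products); the oracle tests bound this on fixtures, and no such case has
  been observed at 0.05 Da tolerances on realistic peak densities.
* `modified_cosine >= cosine` holds on all fixture pairs but is not a
  theorem under greedy selection; an adversarial extra-channel candidate
  can in principle block two direct pairs.
* Analog mode scores every spectrum within a 200 Da precursor window, which
  scales linearly with library density; very large libraries would want the
  opt-in shifted-bin prefilter.
* Group statistics on per-sample match rates (normality tests, two-sample
  comparisons between cohorts) are deliberately left to standard R
  (`shapiro.test`, `t.test`, `wilcox.test`) on the `per_sample_match_rate()`
  output; the package's contract ends at the rates table.
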