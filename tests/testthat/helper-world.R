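# shared fixture builders and independent oracles

make_world <- function(seed = 42, ...) {
  spec <- fixture_spec(seed = seed, ...)
  lin <- generate_taxonomy(spec)
  lib <- generate_reference_library(spec, lin, tempfile("world"))
  db <- build_reference_db(lib$mgf_paths, lib$metadata_path)
  idx <- build_fragment_index(db, 0.05)
  tree <- attach_sample_counts(build_taxon_tree(lin), db$metadata)
  list(spec = spec, lin = lin, lib = lib, db = db, idx = idx, tree = tree)
}

rand_spectrum <- function(id, n = 10, precursor = 500, mz_min = 50,
                          mz_max = NULL) {
  if (is.null(mz_max)) mz_max <- precursor - 10
  mz <- sort(runif(n, mz_min, mz_max))
  ms_spectrum(id, precursor, mz, rexp(n))
}

# exhaustive one-to-one assignment oracle: the maximum total
# normalized-intensity product over all matchings of tolerance-compatible
# peak pairs (any shift channel). Independent of the greedy implementation.
oracle_best_score <- function(a, b, tol = 0.05, shifts = 0) {
  na <- a$peaks[, "intensity"] / sqrt(sum(a$peaks[, "intensity"]^2))
  nb <- b$peaks[, "intensity"] / sqrt(sum(b$peaks[, "intensity"]^2))
  ci <- integer(); cj <- integer(); cp <- numeric()
  for (s in unique(shifts)) {
    d <- outer(a$peaks[, "mz"], b$peaks[, "mz"] + s, "-")
    hit <- which(abs(d) <= tol, arr.ind = TRUE)
    if (nrow(hit)) {
      ci <- c(ci, hit[, 1]); cj <- c(cj, hit[, 2])
      cp <- c(cp, na[hit[, 1]] * nb[hit[, 2]])
    }
  }
  if (length(ci) == 0L) return(0)
  rec <- function(k, ua, ub) {
    if (k > length(ci)) return(0)
    best <- rec(k + 1L, ua, ub)
    if (!ua[ci[k]] && !ub[cj[k]]) {
      ua[ci[k]] <- TRUE; ub[cj[k]] <- TRUE
      best <- max(best, cp[k] + rec(k + 1L, ua, ub))
    }
    best
  }
  min(1, rec(1L, logical(n_peaks(a)), logical(n_peaks(b))))
}

# ancestors-closure oracle for tree pruning
oracle_ancestor_closure <- function(tree, taxids) {
  parent_of <- stats::setNames(tree$nodes$parent, as.character(tree$nodes$taxid))
  out <- numeric(0)
  for (t in c(tree$root, taxids)) {
    while (!is.na(t) && !(t %in% out)) {
      out <- c(out, t)
      t <- parent_of[[as.character(t)]]
    }
  }
  sort(out)
}

expect_same_matches <- function(m, b, tol = 1e-9) {
  expect_identical(m$ref_spectrum_id, b$ref_spectrum_id)
  if (nrow(m) > 0) {
    expect_lt(max(abs(m$score - b$score)), tol)
    expect_identical(m$n_matched_peaks, b$n_matched_peaks)
  }
}
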