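toy_lineage <- function() {
  # two species sharing one genus, one species in a second family
  spine <- function(rec, extra) {
    df <- rbind(
      data.frame(taxid = c(1e3, 2e3), name = c("Plantkingdom", "Greenphylum"),
                 rank = c("kingdom", "phylum"), stringsAsFactors = FALSE),
      extra
    )
    df$record_taxid <- rec
    df
  }
  rbind(
    spine(11, data.frame(taxid = c(31, 41, 11),
                         name = c("Famaceae", "Genusa", "Genusa una"),
                         rank = c("family", "genus", "species"))),
    spine(12, data.frame(taxid = c(31, 41, 12),
                         name = c("Famaceae", "Genusa", "Genusa due"),
                         rank = c("family", "genus", "species"))),
    spine(13, data.frame(taxid = c(32, 42, 13),
                         name = c("Fambaceae", "Genusb", "Genusb tre"),
                         rank = c("family", "genus", "species")))
  )
}

toy_metadata <- function(files) {
  # files: named integer vector taxid -> number of files (NA name = blank)
  rows <- list()
  k <- 0
  for (i in seq_along(files)) {
    taxid <- as.integer(names(files)[i])
    for (j in seq_len(files[i])) {
      k <- k + 1
      rows[[k]] <- data.frame(
        file_path = sprintf("/x/f%02d.mzML", k),
        dataset_filename = sprintf("DS/f%02d.mzML", k),
        massive_id = "DS",
        taxon_name = if (is.na(taxid)) "blank" else as.character(taxid),
        ncbi_taxid = taxid,
        redu_available = TRUE,
        is_blank_or_qc = is.na(taxid),
        file_usi = sprintf("mzspec:DS:f%02d:scan:1", k),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("build_taxon_tree shares ancestors and collapses duplicate taxids", {
  tree <- build_taxon_tree(toy_lineage())
  expect_equal(sum(tree$nodes$rank == "genus"), 2L)
  expect_equal(sum(tree$nodes$taxid == 41), 1L)  # shared genus appears once
  expect_equal(sum(tree$nodes$rank == "species"), 3L)
  # duplicate records collapse to one leaf
  tree2 <- build_taxon_tree(rbind(toy_lineage(), toy_lineage()))
  expect_equal(nrow(tree2$nodes), nrow(tree$nodes))
  validate_taxon_tree(tree)
})

test_that("non-whitelisted ranks are removed and children re-attached", {
  lin <- toy_lineage()
  # splice a tribe between family 31 and genus 41 in record 11
  rec <- lin[lin$record_taxid == 11, ]
  tribe <- data.frame(taxid = 99, name = "Tribus", rank = "tribe",
                      record_taxid = 11, stringsAsFactors = FALSE)
  i <- which(rec$rank == "family")
  rec <- rbind(rec[1:i, ], tribe[, names(rec)], rec[(i + 1):nrow(rec), ])
  lin <- rbind(rec, lin[lin$record_taxid != 11, ])
  tree <- build_taxon_tree(lin)
  expect_false(99 %in% tree$nodes$taxid)
  expect_equal(tree$nodes$parent[tree$nodes$taxid == 41], 31)  # genus under family
  validate_taxon_tree(tree)
})

test_that("conflicting parentage for one taxid is a consistency error", {
  lin <- toy_lineage()
  lin$taxid[lin$record_taxid == 12 & lin$rank == "family"] <- 32
  expect_error(build_taxon_tree(lin), "conflicting",
               class = "spectax_taxonomy_error")
})

test_that("multiple kingdoms join under a synthetic root", {
  lin <- toy_lineage()
  other <- data.frame(record_taxid = 500, taxid = c(5e3, 500),
                      name = c("Otherkingdom", "Otherkingdom species"),
                      rank = c("kingdom", "species"), stringsAsFactors = FALSE)
  tree <- build_taxon_tree(rbind(lin, other))
  expect_equal(tree$root, 1)
  expect_equal(tree$nodes$rank[tree$nodes$taxid == 1], "no rank")
  expect_equal(sort(tree$nodes$taxid[tree$nodes$parent %in% 1]), c(1e3, 5e3))
  validate_taxon_tree(tree)
})

test_that("sample counts aggregate up, place internal-rank files correctly, skip blanks", {
  tree <- build_taxon_tree(toy_lineage())
  files <- c("11" = 5L, "13" = 2L, "41" = 3L)  # 41 is a genus-level file set
  meta <- rbind(toy_metadata(files),
                toy_metadata(setNames(c(1L, 1L), c(NA, NA))))  # two blanks
  tree <- attach_sample_counts(tree, meta)
  n <- function(t) tree$nodes$n_samples[tree$nodes$taxid == t]
  expect_equal(n(11), 5L)
  expect_equal(n(12), 0L)
  expect_equal(n(41), 8L)   # genus: 5 from species 11 + 3 direct
  expect_equal(n(31), 8L)
  expect_equal(n(13), 2L)
  expect_equal(n(1e3), 10L) # root excludes the 2 blanks
  expect_equal(tree$nodes$n_direct[tree$nodes$taxid == 41], 3L)
  validate_taxon_tree(tree)

  bad <- toy_metadata(c("777" = 1L))
  expect_error(attach_sample_counts(build_taxon_tree(toy_lineage()), bad),
               class = "spectax_taxonomy_error")
})

test_that("Newick serialization round trips topology (and ape agrees)", {
  single <- build_taxon_tree(data.frame(record_taxid = 7, taxid = 7,
                                        name = "solo", rank = "kingdom"))
  expect_equal(tree_to_newick(single), "7;")

  w <- make_world(seed = 71)
  nw <- tree_to_newick(w$tree)
  topo <- tree_from_newick(nw)
  expect_setequal(topo$taxid, w$tree$nodes$taxid)
  expect_equal(
    topo$parent[match(w$tree$nodes$taxid, topo$taxid)],
    w$tree$nodes$parent
  )

  # independent parser: ape reads the same topology
  ape_tree <- ape::read.tree(text = nw)
  labels <- c(ape_tree$tip.label, ape_tree$node.label)
  expect_setequal(as.numeric(labels), w$tree$nodes$taxid)
  n_tips <- sum(vapply(w$tree$nodes$taxid,
                       function(t) length(setdiff(which(w$tree$nodes$parent == t), NA)) == 0,
                       TRUE))
  expect_equal(length(ape_tree$tip.label), n_tips)
})

test_that("JSON serialization round trips topology and annotations", {
  w <- make_world(seed = 72)
  js <- tree_to_json(w$tree)
  back <- tree_from_json(js)
  ord <- match(w$tree$nodes$taxid, back$nodes$taxid)
  expect_false(anyNA(ord))
  expect_equal(back$nodes$parent[ord], w$tree$nodes$parent)
  expect_equal(back$nodes$n_samples[ord], w$tree$nodes$n_samples)
  expect_equal(back$nodes$rank[ord], w$tree$nodes$rank)
  expect_equal(back$nodes$name[ord], w$tree$nodes$name)
  # one JSON node per distinct taxid
  expect_equal(nrow(back$nodes), nrow(w$tree$nodes))
  validate_taxon_tree(back)
})

test_that("pruning retains exactly the matched nodes and their ancestors", {
  w <- make_world(seed = 73)
  species <- w$tree$nodes$taxid[w$tree$nodes$rank == "species"]

  empty <- prune_tree_to_results(w$tree, numeric(0))
  expect_equal(empty$nodes$taxid, w$tree$root)

  one <- prune_tree_to_results(w$tree, species[1])
  expect_equal(sort(one$nodes$taxid),
               oracle_ancestor_closure(w$tree, species[1]))
  expect_equal(nrow(one$nodes), 7L)  # kingdom..species single path

  some <- sample(species, 3)
  pruned <- prune_tree_to_results(w$tree, some)
  expect_equal(sort(pruned$nodes$taxid),
               oracle_ancestor_closure(w$tree, some))

  expect_error(prune_tree_to_results(w$tree, 424242),
               class = "spectax_taxonomy_error")
})
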