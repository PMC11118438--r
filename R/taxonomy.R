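# ranks kept in the tree, shallow to deep. "varietas" is the NCBI rank name
# for botanical varieties; "no rank" is reserved for the synthetic root.
RANK_WHITELIST <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "subgenus", "species", "subspecies", "varietas")

rank_depth <- function(rank) {
  d <- match(rank, RANK_WHITELIST)
  d[rank == "no rank"] <- 0L
  d
}

tree_children <- function(tree, taxid) {
  ch <- tree$nodes$taxid[!is.na(tree$nodes$parent) & tree$nodes$parent == taxid]
  sort(ch)
}

#' Build a rank-filtered taxonomic tree from lineage records
#'
#' Takes per-taxon lineage records (one ordered root-to-self lineage per
#' record) and assembles a single tree. Ranks outside the whitelist
#' (kingdom, phylum, class, order, family, genus, subgenus, species,
#' subspecies, varietas) are removed, with descendants re-attached to the
#' nearest kept ancestor. Duplicate taxids collapse to a single node; a
#' taxid appearing with conflicting names, ranks or parents is a consistency
#' error. If records span multiple kingdoms they are joined under a
#' synthetic root (taxid 1, rank `"no rank"`).
#'
#' @param lineages a data.frame with columns `record_taxid` (the taxon each
#'   record describes), `taxid`, `name`, `rank`, rows ordered shallow-to-deep
#'   within each record (e.g. a lineage table exported once from a taxonomy
#'   service, or [generate_taxonomy()] output).
#' @return An object of class `taxon_tree`: a node table (`taxid`, `name`,
#'   `rank`, `parent`, `n_direct`, `n_samples`) in deterministic depth-first
#'   order (children visited in ascending taxid order), plus the root taxid.
#' @export
build_taxon_tree <- function(lineages) {
  stopifnot(is.data.frame(lineages),
            all(c("record_taxid", "taxid", "name", "rank") %in% names(lineages)))
  if (nrow(lineages) == 0L) stop("no lineage records supplied")
  keep <- lineages$rank %in% RANK_WHITELIST
  lineages <- lineages[keep, , drop = FALSE]

  node_name <- character(); node_rank <- character(); node_parent <- numeric()
  seen <- new.env(parent = emptyenv())
  register <- function(taxid, name, rank, parent) {
    key <- as.character(taxid)
    prev <- seen[[key]]
    if (is.null(prev)) {
      seen[[key]] <- list(name = name, rank = rank, parent = parent)
    } else if (!identical(prev$name, name) || !identical(prev$rank, rank) ||
               !identical(prev$parent, parent)) {
      abort(sprintf("conflicting lineage for taxid %s: (%s/%s/parent %s) vs (%s/%s/parent %s)",
                    key, prev$name, prev$rank, prev$parent, name, rank, parent),
            "spectax_taxonomy_error")
    }
  }
  for (rec in split(lineages, lineages$record_taxid)) {
    rec <- rec[!duplicated(rec$taxid), , drop = FALSE]  # resubmitted records
    n <- nrow(rec)
    if (n == 0L) next
    d <- rank_depth(rec$rank)
    if (any(diff(d) <= 0)) {
      abort(sprintf("record %s: lineage ranks not strictly deepening",
                    rec$record_taxid[1L]),
            "spectax_taxonomy_error")
    }
    parent <- c(NA_real_, rec$taxid[-n])
    for (i in seq_len(n)) {
      register(rec$taxid[i], rec$name[i], rec$rank[i], parent[i])
    }
  }

  ids <- as.numeric(ls(seen))
  info <- lapply(as.character(ids), function(k) seen[[k]])
  nodes <- data.frame(
    taxid = ids,
    name = vapply(info, `[[`, "", "name"),
    rank = vapply(info, `[[`, "", "rank"),
    parent = vapply(info, `[[`, 0, "parent"),
    stringsAsFactors = FALSE
  )

  roots <- sort(nodes$taxid[is.na(nodes$parent)])
  if (length(roots) > 1L) {
    if (1 %in% nodes$taxid) {
      abort("cannot add synthetic root: taxid 1 already in use",
            "spectax_taxonomy_error")
    }
    nodes$parent[is.na(nodes$parent)] <- 1
    nodes <- rbind(data.frame(taxid = 1, name = "root", rank = "no rank",
                              parent = NA_real_, stringsAsFactors = FALSE),
                   nodes)
    root <- 1
  } else {
    root <- roots
  }

  tree <- structure(list(nodes = nodes, root = root), class = "taxon_tree")
  # rewrite node table in deterministic DFS order
  ordered <- numeric(0)
  walk <- function(taxid) {
    ordered[length(ordered) + 1L] <<- taxid
    for (ch in tree_children(tree, taxid)) walk(ch)
  }
  walk(root)
  nodes <- nodes[match(ordered, nodes$taxid), , drop = FALSE]
  nodes$n_direct <- 0L
  nodes$n_samples <- 0L
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, root = root), class = "taxon_tree")
}

#' @export
print.taxon_tree <- function(x, ...) {
  n_by_rank <- table(x$nodes$rank)
  cat(sprintf("<taxon_tree> %d nodes (root taxid %s): %s\n",
              nrow(x$nodes), format(x$root, scientific = FALSE),
              paste(sprintf("%s %d", names(n_by_rank), n_by_rank),
                    collapse = ", ")))
  invisible(x)
}

#' Attach per-node sample counts from the metadata table
#'
#' Counts, for every tree node, the non-blank reference files in its subtree:
#' a file whose taxid is an internal node (e.g. identified only to genus)
#' counts at that node and its ancestors, never at descendants. Blank/QC
#' files contribute nothing. After this call the conservation invariant
#' `n_samples(node) = n_direct(node) + sum(n_samples(children))` holds
#' everywhere.
#'
#' @param tree a [build_taxon_tree()] result.
#' @param metadata a metadata data.frame ([read_metadata_table()]).
#' @return The tree with `n_direct` and `n_samples` populated.
#' @export
attach_sample_counts <- function(tree, metadata) {
  stopifnot(inherits(tree, "taxon_tree"))
  nb <- metadata[!metadata$is_blank_or_qc, , drop = FALSE]
  pos <- match(nb$ncbi_taxid, tree$nodes$taxid)
  if (anyNA(pos)) {
    abort(paste0("non-blank file(s) with taxid not in the tree: ",
                 paste(nb$dataset_filename[is.na(pos)][1:min(5, sum(is.na(pos)))],
                       collapse = ", ")),
          "spectax_taxonomy_error")
  }
  tree$nodes$n_direct <- as.integer(tabulate(pos, nbins = nrow(tree$nodes)))
  tree$nodes$n_samples <- accumulate_counts(tree, tree$nodes$n_direct)
  tree
}

# bottom-up accumulation: node table is in DFS preorder, so the reverse
# order visits every child before its parent
accumulate_counts <- function(tree, direct) {
  total <- as.integer(direct)
  parent_pos <- match(tree$nodes$parent, tree$nodes$taxid)
  for (i in rev(seq_len(nrow(tree$nodes)))) {
    p <- parent_pos[i]
    if (!is.na(p)) total[p] <- total[p] + total[i]
  }
  total
}

#' Validate structural invariants of a taxon tree
#'
#' Checks taxid uniqueness, strict rank deepening on every parent-child
#' edge, and (when counts are attached) the count conservation invariant at
#' every node. Errors on the first violation; returns `TRUE` invisibly.
#'
#' @param tree a `taxon_tree`.
#' @return `TRUE`, invisibly.
#' @export
validate_taxon_tree <- function(tree) {
  n <- tree$nodes
  if (anyDuplicated(n$taxid)) {
    abort("duplicate taxids in tree", "spectax_taxonomy_error")
  }
  parent_pos <- match(n$parent, n$taxid)
  has_parent <- !is.na(n$parent)
  if (any(has_parent & is.na(parent_pos))) {
    abort("node with unknown parent taxid", "spectax_taxonomy_error")
  }
  pd <- rank_depth(n$rank[parent_pos[has_parent]])
  cd <- rank_depth(n$rank[has_parent])
  if (any(is.na(cd)) || any(cd <= pd)) {
    abort("rank ordering not strictly deepening on some edge",
          "spectax_taxonomy_error")
  }
  child_sum <- integer(nrow(n))
  for (i in seq_len(nrow(n))) {
    p <- parent_pos[i]
    if (!is.na(p)) child_sum[p] <- child_sum[p] + n$n_samples[i]
  }
  if (any(n$n_samples != n$n_direct + child_sum)) {
    abort("sample-count conservation violated", "spectax_taxonomy_error")
  }
  invisible(TRUE)
}

#' Serialize a taxon tree to Newick
#'
#' Node labels are taxids (internal nodes included), so the string is
#' parseable by standard phylogenetics tools. [tree_from_newick()] parses
#' the topology back into a `(taxid, parent)` edge table.
#'
#' @param tree a `taxon_tree`.
#' @return A Newick string terminated by `;`.
#' @export
tree_to_newick <- function(tree) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  rec <- function(taxid) {
    ch <- tree_children(tree, taxid)
    if (length(ch) == 0L) return(fmt(taxid))
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", fmt(taxid))
  }
  paste0(rec(tree$root), ";")
}

#' @rdname tree_to_newick
#' @param newick a Newick string with numeric labels on all nodes.
#' @return For `tree_from_newick`, a data.frame with columns `taxid`,
#'   `parent` (`NA` for the root), in depth-first order.
#' @export
tree_from_newick <- function(newick) {
  s <- gsub("[ \n\t]", "", newick)
  pos <- 1L
  peek <- function() substr(s, pos, pos)
  read_label <- function() {
    start <- pos
    while (pos <= nchar(s) && !peek() %in% c("(", ")", ",", ";")) {
      pos <<- pos + 1L
    }
    lab <- substr(s, start, pos - 1L)
    if (!nzchar(lab)) abort("unlabelled node in Newick input", "spectax_parse_error")
    as.numeric(lab)
  }
  rows <- list()
  rec <- function(parent) {
    kids <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        rec_id <- rec(NA)  # parent filled after label read
        kids[[length(kids) + 1L]] <- rec_id
        if (peek() == ",") { pos <<- pos + 1L } else break
      }
      if (peek() != ")") abort("unbalanced parentheses in Newick input",
                               "spectax_parse_error")
      pos <<- pos + 1L
    }
    me <- read_label()
    for (k in kids) {
      rows[[k]]$parent <<- me
    }
    rows[[length(rows) + 1L]] <<- list(taxid = me, parent = parent)
    length(rows)
  }
  rec(NA)
  if (peek() != ";") abort("Newick input must end with ';'", "spectax_parse_error")
  out <- data.frame(
    taxid = vapply(rows, function(r) r$taxid, 0),
    parent = vapply(rows, function(r) if (is.null(r$parent) || is.na(r$parent)) NA_real_ else r$parent, 0)
  )
  out
}

#' Serialize a taxon tree to JSON (and back)
#'
#' Each JSON node carries `taxid`, `name`, `rank`, `n_samples` and a
#' `children` array; a versioned header wraps the root node.
#' `tree_from_json(tree_to_json(t))` reproduces topology and annotations.
#'
#' @param tree a `taxon_tree`.
#' @param path optional file to write to.
#' @return The JSON string (invisibly when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  rec <- function(taxid) {
    i <- match(taxid, tree$nodes$taxid)
    list(taxid = tree$nodes$taxid[i],
         name = tree$nodes$name[i],
         rank = tree$nodes$rank[i],
         n_samples = tree$nodes$n_samples[i],
         children = lapply(tree_children(tree, taxid), rec))
  }
  doc <- list(format = "spectax-taxon-tree", version = 1L, tree = rec(tree$root))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "list")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @rdname tree_to_json
#' @param json a JSON string or path produced by `tree_to_json`.
#' @export
tree_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(doc$format, "spectax-taxon-tree")) {
    abort("not a spectax taxon-tree JSON document", "spectax_io_error")
  }
  rows <- list()
  rec <- function(node, parent) {
    rows[[length(rows) + 1L]] <<- data.frame(
      taxid = as.numeric(node$taxid), name = node$name, rank = node$rank,
      parent = parent, n_samples = as.integer(node$n_samples),
      stringsAsFactors = FALSE)
    for (ch in node$children) rec(ch, as.numeric(node$taxid))
  }
  rec(doc$tree, NA_real_)
  nodes <- do.call(rbind, rows)
  child_sum <- integer(nrow(nodes))
  parent_pos <- match(nodes$parent, nodes$taxid)
  for (i in seq_len(nrow(nodes))) {
    if (!is.na(parent_pos[i])) {
      child_sum[parent_pos[i]] <- child_sum[parent_pos[i]] + nodes$n_samples[i]
    }
  }
  nodes$n_direct <- nodes$n_samples - child_sum
  nodes <- nodes[, c("taxid", "name", "rank", "parent", "n_direct", "n_samples")]
  structure(list(nodes = nodes, root = nodes$taxid[is.na(nodes$parent)]),
            class = "taxon_tree")
}

#' Prune a tree to a set of matched taxa
#'
#' Retains exactly the matched nodes and all their ancestors (sample counts
#' are left untouched). An empty match set yields the root-only tree.
#'
#' @param tree a `taxon_tree`.
#' @param matched_taxids numeric vector of taxids present in the tree.
#' @return The pruned `taxon_tree`.
#' @export
prune_tree_to_results <- function(tree, matched_taxids) {
  matched_taxids <- unique(matched_taxids)
  unknown <- setdiff(matched_taxids, tree$nodes$taxid)
  if (length(unknown)) {
    abort(paste0("taxid(s) not in tree: ", paste(unknown, collapse = ", ")),
          "spectax_taxonomy_error")
  }
  keep <- new.env(parent = emptyenv())
  parent_of <- setNames(tree$nodes$parent, as.character(tree$nodes$taxid))
  for (t in c(tree$root, matched_taxids)) {
    while (!is.na(t) && is.null(keep[[as.character(t)]])) {
      keep[[as.character(t)]] <- TRUE
      t <- parent_of[[as.character(t)]]
    }
  }
  sel <- tree$nodes$taxid %in% as.numeric(ls(keep))
  structure(list(nodes = tree$nodes[sel, , drop = FALSE], root = tree$root),
            class = "taxon_tree")
}

#' Taxa present at a given rank, in tree traversal order
#'
#' @param tree a `taxon_tree`.
#' @param rank one of the whitelisted ranks.
#' @param min_samples only taxa with at least this many samples (default 1).
#' @return A data.frame with `taxid` and `name`, in depth-first tree order.
#' @export
taxa_at_rank <- function(tree, rank, min_samples = 1L) {
  if (!rank %in% RANK_WHITELIST) {
    abort(paste0("rank must be one of: ", paste(RANK_WHITELIST, collapse = ", ")),
          "spectax_parameter_error")
  }
  sel <- tree$nodes$rank == rank & tree$nodes$n_samples >= min_samples
  out <- tree$nodes[sel, c("taxid", "name")]
  rownames(out) <- NULL
  out
}
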