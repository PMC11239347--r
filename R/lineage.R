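# Germline-rooted lineage trees built from nested V-region mutation sets.
#
# A node is a genotype (a set of V mutations). Observed unique sequences
# become populated nodes at their mutation set; unpopulated ancestors are
# inferred at pairwise intersections of sibling sets where needed to keep
# the tree a containment hierarchy. The germline root carries the empty
# set.

.root_key <- "<germline>"
.set_key <- function(s) if (length(s) == 0L) .root_key else paste(s, collapse = ";")

# leading integer = mutation position; conflicting substitutions at the
# same position within one genotype are contradictory and rejected
.check_positions <- function(set, id) {
  pos <- regmatches(set, regexpr("^[0-9]+", set))
  pos <- pos[nzchar(pos)]
  if (anyDuplicated(pos))
    stop("conflicting mutation identifiers at one position in sequence ", id)
  invisible(NULL)
}

#' Build a lineage tree for one clone
#'
#' Constructs the germline-rooted mutation-containment tree of a clone.
#' Each unique sequence maps to a populated node at its V mutation set;
#' two unique sequences with identical sets share one node and pool their
#' tissue labels (one label per instance, i.e. per sequence-in-sample
#' occurrence). The parent of each node is the node with the largest
#' mutation set that is a strict subset of its own (ties broken
#' lexicographically on the set key); when two siblings share mutations
#' their parent lacks, an unpopulated ancestor is inferred at the pairwise
#' intersection. The result is invariant under permutation of the input
#' rows.
#'
#' @param members record frame of one clone's members; every member must
#'   carry `v_mutation_set` and (for labels) a `tissue` column.
#' @param clone_id optional clone identifier stored on the tree.
#' @return an object of class `lineage_tree`: a list with `clone_id`,
#'   `key` (node set keys, root first), `muts` (list of mutation sets),
#'   `parent` (parent index, `NA` for root), `populated` (logical),
#'   `labels` (list of character vectors, one entry per instance) and
#'   `n_seqs` (unique sequences per node).
#' @export
build_lineage <- function(members, clone_id = NULL) {
  if (nrow(members) == 0L) stop("clone has no members")
  if (is.null(members$v_mutation_set) ||
      any(vapply(members$v_mutation_set, is.null, logical(1))))
    stop("all members must carry v_mutation_set to build a lineage",
         if (!is.null(clone_id)) paste0(" (clone ", clone_id, ")") else "")
  has_tissue <- !is.null(members$tissue)

  # genotype per unique sequence; identical ids must agree on the set
  first <- !duplicated(members$sequence_id)
  geno <- members$v_mutation_set[first]
  ids <- members$sequence_id[first]
  for (i in seq_along(geno)) {
    geno[[i]] <- sort(unique(geno[[i]]))
    .check_positions(geno[[i]], ids[i])
  }
  key_of_seq <- vapply(geno, .set_key, character(1))
  names(key_of_seq) <- ids

  sets <- list()
  sets[[.root_key]] <- character(0)
  for (i in seq_along(geno)) sets[[key_of_seq[i]]] <- geno[[i]]

  parent_keys <- function(sets) {
    keys <- names(sets)
    lens <- lengths(sets)
    vapply(seq_along(sets), function(i) {
      if (lens[i] == 0L) return(NA_character_)
      cand <- which(lens < lens[i])
      cand <- cand[vapply(cand, function(j) all(sets[[j]] %in% sets[[i]]),
                          logical(1))]
      cl <- lens[cand]
      cand <- cand[cl == max(cl)]
      keys[cand[order(keys[cand])][1]]
    }, character(1))
  }

  repeat {
    par <- parent_keys(sets)
    added <- FALSE
    for (p in unique(par[!is.na(par)])) {
      kids <- which(!is.na(par) & par == p)
      if (length(kids) < 2L) next
      plen <- length(sets[[p]])
      for (a in seq_len(length(kids) - 1L)) {
        for (b in seq.int(a + 1L, length(kids))) {
          I <- intersect(sets[[kids[a]]], sets[[kids[b]]])
          if (length(I) > plen) {
            k <- .set_key(sort(I))
            if (!k %in% names(sets)) {
              sets[[k]] <- sort(I)
              added <- TRUE
            }
          }
        }
      }
    }
    if (!added) break
  }

  # canonical node order: root first, then by (set size, key)
  keys <- names(sets)
  ord <- order(lengths(sets), keys)
  ord <- c(which(keys == .root_key), setdiff(ord, which(keys == .root_key)))
  sets <- sets[ord]
  keys <- names(sets)
  par <- parent_keys(sets)
  parent <- match(par, keys)

  populated <- keys %in% key_of_seq
  labels <- vector("list", length(keys))
  n_seqs <- integer(length(keys))
  for (i in seq_along(keys)) {
    sid <- names(key_of_seq)[key_of_seq == keys[i]]
    n_seqs[i] <- length(sid)
    if (length(sid) && has_tissue) {
      rows <- members$sequence_id %in% sid
      labels[[i]] <- sort(members$tissue[rows])
    } else labels[[i]] <- character(0)
  }

  structure(list(clone_id = clone_id, key = keys, muts = unname(sets),
                 parent = parent, populated = populated, labels = labels,
                 n_seqs = n_seqs),
            class = "lineage_tree")
}

#' Number of populated nodes in a lineage
#'
#' Counts nodes occupied by at least one observed unique sequence; equals
#' the number of distinct mutation sets among the clone's unique
#' sequences.
#'
#' @param tree a `lineage_tree`.
#' @return integer count.
#' @export
populated_node_count <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  sum(tree$populated)
}

#' Lineage node table
#'
#' @param tree a `lineage_tree`.
#' @return data.frame with one row per node: id, parent, number of
#'   mutations, populated flag, unique-sequence count and label multiset.
#' @export
lineage_nodes <- function(tree) {
  data.frame(
    node_id = seq_along(tree$key),
    parent_id = tree$parent,
    n_mutations = lengths(tree$muts),
    populated = tree$populated,
    n_unique_seqs = tree$n_seqs,
    labels = vapply(tree$labels, paste, character(1), collapse = ","),
    mutations = tree$key,
    stringsAsFactors = FALSE)
}

#' Newick serialization of a lineage
#'
#' Writes the tree as a Newick string with unit branch lengths; node
#' comments carry the populated flag and the tissue-label multiset.
#'
#' @param tree a `lineage_tree`.
#' @return a single Newick string terminated by `;`.
#' @export
lineage_newick <- function(tree) {
  children <- split(seq_along(tree$parent), tree$parent)
  lab <- function(i) {
    tags <- sprintf("[&populated=%d,labels=%s]",
                    as.integer(tree$populated[i]),
                    paste(tree$labels[[i]], collapse = "|"))
    paste0("N", i, tags)
  }
  rec <- function(i) {
    kids <- children[[as.character(i)]]
    if (is.null(kids)) return(paste0(lab(i), ":1"))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
           lab(i), ":1")
  }
  root <- which(is.na(tree$parent))
  paste0(rec(root), ";")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree", if (!is.null(x$clone_id)) paste0("(clone ", x$clone_id, ")"),
      ": ", length(x$key), " nodes, ", sum(x$populated), " populated\n", sep = "")
  invisible(x)
}
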