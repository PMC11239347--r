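# Clumpiness: a 0-1 measure of how interleaved two tissue labels are
# within a clonal lineage.
#
# For every instance of one label at populated node u, its proximity score
# is 2^(-d), where d is the edge distance from u to the nearest populated
# node carrying the other label (d = 0 when u itself carries both). A path
# that passes through the germline root earns no credit: labels whose only
# connection is the root sit on different founder branches and are
# considered fully separated. Clumpiness is the mean proximity score over
# all instances of both labels: 0 when the labels occupy disjoint root
# clades, 1 when every populated node carries both.

.node_depths <- function(parent) {
  depth <- integer(length(parent))
  for (i in seq_along(parent)) {
    d <- 0L; j <- i
    while (!is.na(parent[j])) { j <- parent[j]; d <- d + 1L }
    depth[i] <- d
  }
  depth
}

.ancestor_chain <- function(parent, i) {
  out <- i
  while (!is.na(parent[i])) { i <- parent[i]; out <- c(out, i) }
  out
}

#' Tissue-label mixing within a lineage (clumpiness)
#'
#' Computes the clumpiness of two tissue labels in a lineage tree: 0 when
#' the labels are separated on different branches meeting only at the
#' germline root, 1 when they are fully mixed (every populated node
#' carries both). Symmetric in the two labels; instances of other labels
#' are ignored. Returns `NA` (undefined, distinguished from 0) when either
#' label does not occur among populated nodes.
#'
#' @param tree a `lineage_tree` whose nodes carry tissue-label multisets.
#' @param label_a,label_b the two tissue labels.
#' @return a fraction in `[0, 1]`, or `NA_real_` when undefined.
#' @export
clumpiness <- function(tree, label_a, label_b) {
  stopifnot(inherits(tree, "lineage_tree"))
  count_of <- function(lab) vapply(tree$labels, function(x) sum(x == lab),
                                   integer(1))
  ca <- count_of(label_a)
  cb <- count_of(label_b)
  if (sum(ca) == 0L || sum(cb) == 0L) return(NA_real_)

  parent <- tree$parent
  root <- which(is.na(parent))
  depth <- .node_depths(parent)
  chains <- lapply(seq_along(parent), function(i) .ancestor_chain(parent, i))

  dist_ok <- function(u, v) {
    # edge distance, or NA when the path runs through the germline root
    lca <- chains[[u]][match(TRUE, chains[[u]] %in% chains[[v]])]
    if (lca == root && u != v) return(NA_real_)
    depth[u] + depth[v] - 2L * depth[lca]
  }

  score_at <- function(u, other) {
    if (other[u] > 0L) return(1)
    cand <- which(other > 0L)
    d <- vapply(cand, function(v) dist_ok(u, v), numeric(1))
    d <- d[!is.na(d)]
    if (!length(d)) 0 else 2^(-min(d))
  }

  total <- 0
  for (u in which(ca > 0L)) total <- total + ca[u] * score_at(u, cb)
  for (u in which(cb > 0L)) total <- total + cb[u] * score_at(u, ca)
  total / (sum(ca) + sum(cb))
}

#' Per-individual median clumpiness
#'
#' Summarizes per-clone clumpiness values as a median per individual (and
#' label pair, when present). Individuals contributing 5 or fewer clones
#' with a defined value are dropped: only medians over strictly more than
#' `min_clones - 1` clones are reported.
#'
#' @param results data.frame with columns `patient_id`, `value` and
#'   optionally `label_pair`.
#' @param min_clones minimum number of contributing clones for a median to
#'   be retained, default 6 (i.e. strictly greater than 5).
#' @return data.frame with `patient_id`, optional `label_pair`,
#'   `n_clones`, `median_clumpiness`.
#' @export
median_clumpiness <- function(results, min_clones = 6L) {
  results <- results[!is.na(results$value), , drop = FALSE]
  by <- if ("label_pair" %in% names(results))
    list(patient_id = results$patient_id, label_pair = results$label_pair)
  else list(patient_id = results$patient_id)
  groups <- split(results$value, by, drop = TRUE)
  keys <- do.call(rbind, strsplit(names(groups), ".", fixed = TRUE))
  out <- data.frame(patient_id = keys[, 1], stringsAsFactors = FALSE)
  if (ncol(keys) > 1) out$label_pair <- keys[, 2]
  out$n_clones <- lengths(groups)
  out$median_clumpiness <- vapply(groups, median, numeric(1))
  out <- out[out$n_clones >= min_clones, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical tissue-pair label
#'
#' @param a,b tissue labels.
#' @return `"a|b"` with the two labels in sorted order.
#' @export
tissue_pair <- function(a, b) paste(sort(c(a, b)), collapse = "|")
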