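# Clonal inference: grouping rearrangements into clones and per-clone
# mutation summaries, detectability, trunk and size filters.

# pairwise CDR3 identity >= threshold, tolerant of float representation
.ident_join <- function(matches, len, threshold) {
  matches / len >= threshold - 1e-9
}

# single-linkage components among equal-length CDR3 strings
.link_cdr3 <- function(cdr3s, threshold) {
  u <- unique(cdr3s)
  n <- length(u)
  comp <- seq_len(n)
  if (n > 1L) {
    len <- nchar(u[1])
    m <- matrix(unlist(strsplit(u, "", fixed = TRUE), use.names = FALSE),
                nrow = len)
    find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (.ident_join(sum(m[, i] == m[, j]), len, threshold)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
  }
  comp[match(cdr3s, u)]
}

#' Group rearrangements into clones
#'
#' Partitions records into clones: within each (V gene, J gene, CDR3
#' length) bucket, records are clustered by single linkage, joining two
#' CDR3s when their amino-acid identity (matching positions divided by the
#' CDR3 length) is at least `threshold`. The default 0.85 means two 20-mer
#' CDR3s differing at 3 positions (85% identity) join one clone while 4
#' differences (80%) do not.
#'
#' The partition is independent of input order; clone ids are assigned
#' canonically by sorting clones on (v_gene, j_gene, cdr3_length, smallest
#' member CDR3, smallest member id). Records with an empty CDR3 are
#' excluded and tallied in attribute `rejected_empty_cdr3`.
#'
#' @param records canonical record frame (see [read_rearrangements()]).
#' @param threshold minimum CDR3 amino-acid identity fraction, default 0.85.
#' @return `records` with an integer `clone_id` column added.
#' @export
group_clones <- function(records, threshold = 0.85) {
  if (nrow(records) == 0L) stop("no records to group")
  empty <- is.na(records$cdr3_aa) | !nzchar(records$cdr3_aa)
  n_empty <- sum(empty)
  records <- records[!empty, , drop = FALSE]
  if (nrow(records) == 0L) stop("all records have empty CDR3")

  bucket <- paste(records$v_gene, records$j_gene, records$cdr3_length,
                  sep = "\r")
  comp <- integer(nrow(records))
  off <- 0L
  for (b in split(seq_len(nrow(records)), bucket)) {
    cc <- .link_cdr3(records$cdr3_aa[b], threshold)
    comp[b] <- off + cc
    off <- off + max(cc)
  }
  # canonical ids, invariant under input permutation
  key_min <- function(x) min(x)
  rep_cdr3 <- tapply(records$cdr3_aa, comp, key_min)
  rep_seq <- tapply(paste(records$sequence_id, records$sample_id), comp, key_min)
  rep_v <- tapply(records$v_gene, comp, key_min)
  rep_j <- tapply(records$j_gene, comp, key_min)
  rep_len <- tapply(records$cdr3_length, comp, function(x) x[1])
  ord <- order(rep_v, rep_j, rep_len, rep_cdr3, rep_seq)
  new_id <- integer(length(ord))
  new_id[ord] <- seq_along(ord)
  records$clone_id <- new_id[match(comp, as.integer(names(rep_cdr3)))]
  records <- records[order(records$clone_id), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "rejected_empty_cdr3") <- n_empty
  records
}

#' Per-sequence V-gene mutation fraction
#'
#' Mutation frequency of a sequence: total V-gene mutations divided by the
#' sequenced V-gene length. Vectorized.
#'
#' @param v_mutation_count non-negative integer vector.
#' @param v_sequenced_length positive integer vector (nt).
#' @return numeric vector in `[0, 1]`.
#' @export
mutation_fraction <- function(v_mutation_count, v_sequenced_length) {
  if (any(is.na(v_sequenced_length)) || any(v_sequenced_length <= 0))
    stop("v_sequenced_length must be positive")
  v_mutation_count / v_sequenced_length
}

# unique instances = distinct (sequence_id, sample_id) rows
.unique_instances <- function(members) {
  members[!duplicated(paste(members$sequence_id, members$sample_id)), ,
          drop = FALSE]
}

#' Average mutation fraction of a clone
#'
#' Unweighted mean of the per-sequence V mutation fraction over all unique
#' instances of the clone (distinct sequence-in-sample occurrences), not
#' weighted by copy number.
#'
#' @param members record frame of one clone's members.
#' @return scalar fraction.
#' @export
clone_mutation_fraction <- function(members) {
  if (nrow(members) == 0L) stop("clone has no members")
  inst <- .unique_instances(members)
  mean(mutation_fraction(inst$v_mutation_count, inst$v_sequenced_length))
}

#' Is a clone "mutated"?
#'
#' TRUE when the clone's average V-gene mutation frequency strictly
#' exceeds the cutoff (default 2%).
#'
#' @param members record frame of one clone's members.
#' @param cutoff strict lower bound on the average mutation fraction.
#' @return logical scalar.
#' @export
is_mutated_clone <- function(members, cutoff = 0.02) {
  clone_mutation_fraction(members) > cutoff
}

#' Is a clone detectable in a tissue?
#'
#' A clone is detectable in a tissue when it has at least one functional
#' (productive) sequence with copy number at least `min_copies` in that
#' tissue. Requires the record frame to carry a `tissue` column (see
#' [annotate_samples()]).
#'
#' @param members record frame of one clone's members, annotated with tissue.
#' @param tissue tissue label to test.
#' @param min_copies minimum copy number, default 2.
#' @return logical scalar.
#' @export
is_detectable <- function(members, tissue, min_copies = 2L) {
  if (is.null(members$tissue)) stop("members must carry a tissue column")
  any(members$tissue == tissue & members$productive &
        members$copy_number >= min_copies)
}

#' Clone sizes per patient, tissue and time bracket
#'
#' Clone size within a time bracket is the number of unique instances of
#' the clone summed over all samples in the bracket, where a unique
#' instance is one unique sequence observed in one sample (the same
#' sequence seen in two samples counts twice). Cells with zero instances
#' are omitted.
#'
#' @param assigned record frame with `clone_id` (from [group_clones()]).
#' @param meta metadata frame resolving every `sample_id`.
#' @return data.frame with `clone_id`, `patient_id`, `tissue`, `bracket`,
#'   `size`.
#' @export
clone_bracket_sizes <- function(assigned, meta) {
  a <- annotate_samples(assigned, meta)
  inst <- .unique_instances(a)
  dt <- data.table::as.data.table(
    inst[, c("clone_id", "patient_id", "tissue", "bracket")])
  out <- dt[, list(size = .N), by = c("clone_id", "patient_id", "tissue", "bracket")]
  data.table::setorder(out, clone_id, patient_id, tissue, bracket)
  as.data.frame(out)
}

#' Is a clone a trunk clone?
#'
#' A trunk clone has at least `min_shared` distinct mutations each present
#' in at least `prop` of its unique sequences, evidence of a shared
#' mutated ancestor.
#'
#' @param members record frame of one clone's members; every member must
#'   carry a V mutation set.
#' @param min_shared minimum number of shared mutations, default 5.
#' @param prop minimum fraction of unique sequences sharing each mutation,
#'   default 0.85.
#' @return logical scalar.
#' @export
is_trunk_clone <- function(members, min_shared = 5L, prop = 0.85) {
  seqs <- members[!duplicated(members$sequence_id), , drop = FALSE]
  missing <- vapply(seqs$v_mutation_set, is.null, logical(1))
  if (any(missing))
    stop("mutation sets missing for clone (sequence ",
         paste(head(seqs$sequence_id[missing], 3), collapse = ", "), ")")
  n <- nrow(seqs)
  counts <- table(unlist(seqs$v_mutation_set, use.names = FALSE))
  sum(counts / n >= prop - 1e-9) >= min_shared
}

#' Filter clones by unique-sequence count and dual-tissue sampling
#'
#' Retains clones with at least `k` unique sequences and at least one
#' unique sequence sampled in each of the two given tissues — the
#' eligibility rule applied before computing lineage-mixing statistics.
#'
#' @param assigned annotated record frame with `clone_id` and `tissue`.
#' @param k minimum number of unique sequences, default 3.
#' @param tissues character vector of the two tissues that must both be
#'   represented.
#' @return the subset of `assigned` belonging to retained clones.
#' @export
min_unique_sequences_filter <- function(assigned, k = 3L,
                                        tissues = c("blood", "ileum")) {
  if (is.null(assigned$tissue)) stop("records must carry a tissue column")
  stopifnot(length(tissues) == 2L, k >= 1L)
  keep <- vapply(split(seq_len(nrow(assigned)), assigned$clone_id),
    function(i) {
      m <- assigned[i, , drop = FALSE]
      length(unique(m$sequence_id)) >= k &&
        all(tissues %in% unique(m$tissue))
    }, logical(1))
  kept_ids <- as.integer(names(keep))[keep]
  assigned[assigned$clone_id %in% kept_ids, , drop = FALSE]
}

#' Summarize clones
#'
#' One row per clone: gene usage, CDR3 length, unique sequence and
#' instance counts, average V mutation fraction, mutated and trunk flags,
#' and (when tissue annotation is present) the tissues detected.
#'
#' @param assigned record frame with `clone_id`, optionally annotated.
#' @param mutated_cutoff cutoff for [is_mutated_clone()].
#' @return data.frame of per-clone summaries.
#' @export
clone_summary <- function(assigned, mutated_cutoff = 0.02) {
  have_sets <- all(!vapply(assigned$v_mutation_set, is.null, logical(1)))
  rows <- lapply(split(seq_len(nrow(assigned)), assigned$clone_id), function(i) {
    m <- assigned[i, , drop = FALSE]
    inst <- .unique_instances(m)
    data.frame(
      clone_id = m$clone_id[1], v_gene = m$v_gene[1], j_gene = m$j_gene[1],
      cdr3_length = m$cdr3_length[1],
      n_unique_seqs = length(unique(m$sequence_id)),
      n_instances = nrow(inst),
      avg_v_mutation_fraction = clone_mutation_fraction(m),
      is_mutated = is_mutated_clone(m, mutated_cutoff),
      is_trunk = if (have_sets) is_trunk_clone(m) else NA,
      tissues = if (is.null(m$tissue)) NA_character_
                else paste(sort(unique(m$tissue)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$clone_id), , drop = FALSE]
}
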