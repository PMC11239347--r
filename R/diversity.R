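# Diversity, evenness and cross-repertoire cosine similarity on
# clone-size distributions.

#' Hill-number diversity of a clone-size distribution
#'
#' The effective number of clones at order `q`, computed on clone-size
#' proportions \eqn{p_i}: \eqn{(\sum p_i^q)^{1/(1-q)}} for \eqn{q \ne 1},
#' with the continuous limit \eqn{\exp(-\sum p_i \ln p_i)} at `q = 1`.
#' Order 0 equals richness (the number of clones regardless of size);
#' higher orders weight large clones more. Scale-invariant and
#' non-increasing in `q`.
#'
#' @param sizes positive numeric vector of clone sizes.
#' @param q diversity order, a non-negative real.
#' @return a scalar `>= 1` for non-empty input.
#' @export
hill_diversity <- function(sizes, q) {
  if (length(sizes) == 0L) stop("empty repertoire slice")
  if (any(sizes <= 0)) stop("clone sizes must be positive")
  if (q < 0) stop("diversity order must be non-negative")
  p <- sizes / sum(sizes)
  if (q == 1) exp(-sum(p * log(p)))
  else if (q == 0) length(p)
  else sum(p^q)^(1 / (1 - q))
}

#' Evenness of a clone-size distribution
#'
#' Order-1 Hill diversity divided by richness; 1 when all clones are
#' equal-sized, approaching 0 as one clone dominates. Expresses clonality
#' without being affected by how many clones a sample contains.
#'
#' @param sizes positive numeric vector of clone sizes.
#' @return a fraction in `(0, 1]`.
#' @export
evenness <- function(sizes) {
  hill_diversity(sizes, 1) / length(sizes)
}

#' Cosine similarity of two repertoires
#'
#' Cosine of the two clone-size vectors taken over the union of clone
#' identifiers (a clone absent from one repertoire contributes size 0
#' there). 1 when relative clone sizes agree up to scale; 0 when the
#' repertoires share no clones. Clone identity must come from a single
#' clonal-grouping run over the pooled data of one patient; cosine across
#' patients is undefined.
#'
#' @param a,b named numeric vectors mapping clone id to size.
#' @return a fraction in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty repertoire slice")
  if (is.null(names(a)) || is.null(names(b)))
    stop("size vectors must be named by clone id")
  ids <- union(names(a), names(b))
  va <- setNames(numeric(length(ids)), ids); va[names(a)] <- a
  vb <- setNames(numeric(length(ids)), ids); vb[names(b)] <- b
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Build repertoire slices from bracketed clone sizes
#'
#' Converts the output of [clone_bracket_sizes()] into a list of named
#' size vectors, one per (patient, tissue, bracket) cell.
#'
#' @param bracket_sizes data.frame from [clone_bracket_sizes()].
#' @return named list of named numeric vectors; list names are
#'   `patient|tissue|bracket`.
#' @export
repertoire_slices <- function(bracket_sizes) {
  key <- paste(bracket_sizes$patient_id, bracket_sizes$tissue,
               bracket_sizes$bracket, sep = "|")
  lapply(split(bracket_sizes, key), function(d)
    setNames(as.numeric(d$size), as.character(d$clone_id)))
}

#' Drop slices with too few clones
#'
#' Retains repertoire slices whose richness is strictly greater than `k`
#' (default 5), the eligibility rule for per-bracket summaries.
#'
#' @param slices named list of named size vectors (see
#'   [repertoire_slices()]).
#' @param k strict lower bound on richness, default 5.
#' @return the filtered list.
#' @export
min_clone_filter <- function(slices, k = 5L) {
  stopifnot(k >= 0L)
  slices[vapply(slices, length, integer(1)) > k]
}
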