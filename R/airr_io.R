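# Reading, validation and normalization of annotated heavy-chain
# rearrangement tables and sample metadata.

#' @import data.table
#' @importFrom stats median pbinom pnorm rbinom rgeom rpois runif setNames
#' @importFrom utils head
NULL

# Recognized tissue labels and rejection grades
.bcr_tissues <- c("blood", "ileum", "colon", "native_colon", "duodenum")
.bcr_rejection <- c("none", "indeterminate", "mild", "moderate", "severe", "amr")
.bcr_quiescent <- c("none", "indeterminate")

# canonical field -> on-disk column, per dialect
.dialect_airr <- c(
  sequence_id = "sequence_id", sample_id = "sample_id",
  v_call = "v_call", j_call = "j_call", cdr3_aa = "junction_aa",
  productive = "productive", copy_number = "duplicate_count",
  v_mutation_count = "v_mutation_count",
  v_sequenced_length = "v_sequenced_length",
  v_mutation_set = "v_mutation_set")

.dialect_immunedb <- c(
  sequence_id = "seq_id", sample_id = "sample_id",
  v_call = "v_gene", j_call = "j_gene", cdr3_aa = "cdr3_aa",
  productive = "functional", copy_number = "copy_number",
  v_mutation_fraction = "v_mutation_fraction",
  v_sequenced_length = "v_length",
  v_mutation_set = "mutations")

#' Strip allele designators from a V/J gene call
#'
#' Collapses allele-level calls (e.g. `"IGHV1-2*02"`) to the gene level
#' (`"IGHV1-2"`); clone definitions in this package operate on genes, not
#' alleles.
#'
#' @param x character vector of gene calls.
#' @return character vector with everything from the first `*` removed.
#' @export
strip_allele <- function(x) sub("\\*.*$", "", x)

.parse_productive <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE", "1", "YES")] <- TRUE
  out[up %in% c("F", "FALSE", "0", "NO")] <- FALSE
  out
}

.parse_mutation_set <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) NULL
    else sort(unique(strsplit(trimws(s), ";", fixed = TRUE)[[1]]))
  })
}

#' Read an annotated rearrangement table
#'
#' Reads a tab-separated table of annotated heavy-chain rearrangements in
#' either the AIRR-C rearrangement dialect (columns `sequence_id`,
#' `sample_id`, `v_call`, `j_call`, `junction_aa`, `productive`,
#' `duplicate_count`, `v_mutation_count`, `v_sequenced_length`, optional
#' `v_mutation_set`) or an ImmuneDB-style dialect (`seq_id`, `sample_id`,
#' `v_gene`, `j_gene`, `cdr3_aa`, `functional`, `copy_number`,
#' `v_mutation_fraction`, `v_length`, optional `mutations`), and normalizes
#' it into the package's canonical record frame.
#'
#' Rows violating record invariants (copy number < 1, mutation count
#' exceeding V length, mutation-set cardinality disagreeing with the count,
#' unparseable flags, empty CDR3) are dropped and tallied in the
#' `"rejected"` attribute of the result, a named integer vector of reasons.
#' V and J calls are collapsed to gene level (allele suffix stripped) in
#' `v_gene`/`j_gene`; the raw calls are retained.
#'
#' @param path path to a TSV file.
#' @param dialect `"airr"` (default) or `"immunedb"`.
#' @return a `data.frame` with columns `sequence_id`, `sample_id`,
#'   `v_call`, `j_call`, `v_gene`, `j_gene`, `cdr3_aa`, `cdr3_length`,
#'   `productive` (logical), `copy_number`, `v_mutation_count`,
#'   `v_sequenced_length` (integers) and `v_mutation_set` (list column of
#'   character vectors, `NULL` where absent), plus attribute `rejected`.
#' @export
read_rearrangements <- function(path, dialect = c("airr", "immunedb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("rearrangement file not found: ", path)
  map <- if (dialect == "airr") .dialect_airr else .dialect_immunedb
  raw <- data.table::fread(path, sep = "\t", colClasses = "character",
                           na.strings = c("", "NA"), data.table = FALSE)
  mandatory <- map[setdiff(names(map), "v_mutation_set")]
  absent <- setdiff(unname(mandatory), names(raw))
  if (length(absent))
    stop("missing mandatory column(s) for dialect '", dialect, "': ",
         paste(absent, collapse = ", "))

  n <- nrow(raw)
  has_set <- map[["v_mutation_set"]] %in% names(raw)
  get <- function(field) {
    col <- map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, n)
  }

  rec <- data.frame(
    sequence_id = get("sequence_id"), sample_id = get("sample_id"),
    v_call = get("v_call"), j_call = get("j_call"),
    cdr3_aa = get("cdr3_aa"), stringsAsFactors = FALSE)
  rec$productive <- .parse_productive(get("productive"))
  rec$copy_number <- suppressWarnings(as.integer(get("copy_number")))
  rec$v_sequenced_length <- suppressWarnings(as.integer(get("v_sequenced_length")))
  if (dialect == "airr") {
    rec$v_mutation_count <- suppressWarnings(as.integer(get("v_mutation_count")))
  } else {
    frac <- suppressWarnings(as.numeric(get("v_mutation_fraction")))
    rec$v_mutation_count <- as.integer(round(frac * rec$v_sequenced_length))
  }
  rec$v_mutation_set <- if (has_set) .parse_mutation_set(get("v_mutation_set"))
                        else vector("list", n)

  reasons <- character(0)
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) reasons <<- c(reasons, rep(why, sum(cond & !dropped)))
    dropped <<- dropped | cond
    invisible(NULL)
  }
  dropped <- rep(FALSE, n)
  bad(is.na(rec$sequence_id) | is.na(rec$sample_id) | is.na(rec$v_call) |
        is.na(rec$j_call), "missing_identifier")
  bad(is.na(rec$cdr3_aa) | !nzchar(rec$cdr3_aa), "empty_cdr3")
  bad(is.na(rec$productive), "bad_productive_flag")
  bad(is.na(rec$copy_number) | rec$copy_number < 1L, "copy_number_lt_1")
  bad(is.na(rec$v_sequenced_length) | rec$v_sequenced_length < 1L,
      "bad_v_length")
  bad(is.na(rec$v_mutation_count) | rec$v_mutation_count < 0L,
      "bad_mutation_count")
  bad(rec$v_mutation_count > rec$v_sequenced_length, "mutations_exceed_length")
  card_ok <- vapply(seq_len(n), function(i) {
    s <- rec$v_mutation_set[[i]]
    is.null(s) || length(s) == rec$v_mutation_count[i]
  }, logical(1))
  bad(!card_ok, "mutation_set_cardinality")

  out <- rec[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  out$v_gene <- strip_allele(out$v_call)
  out$j_gene <- strip_allele(out$j_call)
  out$cdr3_length <- nchar(out$cdr3_aa)
  out <- out[, c("sequence_id", "sample_id", "v_call", "j_call", "v_gene",
                 "j_gene", "cdr3_aa", "cdr3_length", "productive",
                 "copy_number", "v_mutation_count", "v_sequenced_length",
                 "v_mutation_set")]
  tally <- if (length(reasons)) table(reasons) else table(character(0))
  attr(out, "rejected") <- setNames(as.integer(tally), names(tally))
  if (length(reasons))
    message(sum(dropped), "/", n, " rows rejected (",
            paste(names(tally), as.integer(tally), sep = "=", collapse = ", "),
            ")")
  out
}

#' Write a rearrangement table
#'
#' Inverse of [read_rearrangements()]: writes a canonical record frame back
#' to disk in the requested dialect. A write/read round trip reproduces all
#' canonical fields exactly.
#'
#' @param records canonical record frame (see [read_rearrangements()]).
#' @param path output TSV path.
#' @param dialect `"airr"` (default) or `"immunedb"`.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path, dialect = c("airr", "immunedb")) {
  dialect <- match.arg(dialect)
  set_str <- vapply(records$v_mutation_set, function(s)
    if (is.null(s)) "" else paste(s, collapse = ";"), character(1))
  if (dialect == "airr") {
    out <- data.frame(
      sequence_id = records$sequence_id, sample_id = records$sample_id,
      v_call = records$v_call, j_call = records$j_call,
      junction_aa = records$cdr3_aa,
      productive = ifelse(records$productive, "T", "F"),
      duplicate_count = records$copy_number,
      v_mutation_count = records$v_mutation_count,
      v_sequenced_length = records$v_sequenced_length,
      v_mutation_set = set_str, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      seq_id = records$sequence_id, sample_id = records$sample_id,
      v_gene = records$v_call, j_gene = records$j_call,
      cdr3_aa = records$cdr3_aa,
      functional = ifelse(records$productive, "T", "F"),
      copy_number = records$copy_number,
      v_mutation_fraction = records$v_mutation_count / records$v_sequenced_length,
      v_length = records$v_sequenced_length,
      mutations = set_str, stringsAsFactors = FALSE)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads per-sample metadata: `sample_id`, `patient_id`, `tissue`, `pod`
#' (post-operative day), `rejection_status`, and optionally `allograft`
#' (logical), `parent_gate_count` and `chimerism_pct`. Unknown tissue
#' labels or rejection grades are a hard error naming the offending value;
#' rows with an invalid POD or out-of-range chimerism are dropped with a
#' message. Duplicated sample ids are a hard error.
#'
#' @param path path to a TSV file.
#' @return a `data.frame` of validated sample metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", na.strings = c("", "NA"),
                           data.table = FALSE)
  need <- c("sample_id", "patient_id", "tissue", "pod", "rejection_status")
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("missing mandatory metadata column(s): ", paste(absent, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", "))
  unknown <- setdiff(unique(raw$tissue), .bcr_tissues)
  if (length(unknown))
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(unique(raw$rejection_status), .bcr_rejection)
  if (length(unknown))
    stop("unknown rejection grade(s): ", paste(unknown, collapse = ", "))

  raw$pod <- suppressWarnings(as.integer(raw$pod))
  keep <- !is.na(raw$pod) & raw$pod >= 0L
  if (!"parent_gate_count" %in% names(raw)) raw$parent_gate_count <- NA_integer_
  raw$parent_gate_count <- suppressWarnings(as.integer(raw$parent_gate_count))
  if (!"chimerism_pct" %in% names(raw)) raw$chimerism_pct <- NA_real_
  raw$chimerism_pct <- suppressWarnings(as.numeric(raw$chimerism_pct))
  keep <- keep & (is.na(raw$chimerism_pct) |
                    (raw$chimerism_pct >= 0 & raw$chimerism_pct <= 100))
  if (!"allograft" %in% names(raw)) raw$allograft <- NA
  raw$allograft <- as.logical(raw$allograft)
  if (any(!keep))
    message(sum(!keep), " metadata row(s) rejected (invalid pod or chimerism)")
  out <- raw[keep, c("sample_id", "patient_id", "tissue", "pod",
                     "rejection_status", "allograft", "parent_gate_count",
                     "chimerism_pct"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only quiescent samples
#'
#' Retains samples whose rejection grade is `none` or `indeterminate`;
#' samples with mild or greater acute cellular rejection, or
#' antibody-mediated rejection, are excluded from repertoire analyses.
#' Row order is preserved and the operation is idempotent.
#'
#' @param meta metadata frame from [read_metadata()].
#' @return the subset of quiescent rows.
#' @export
filter_quiescent <- function(meta) {
  if (any(is.na(meta$rejection_status)))
    stop("rejection_status must be populated")
  meta[meta$rejection_status %in% .bcr_quiescent, , drop = FALSE]
}

#' Attach sample metadata to records
#'
#' Joins `patient_id`, `tissue`, `pod` and the derived time bracket onto a
#' record frame by `sample_id`. Records whose sample is absent from the
#' metadata are a hard error (every instance must be traceable to a
#' sample).
#'
#' @param records canonical record frame.
#' @param meta metadata frame.
#' @return `records` with `patient_id`, `tissue`, `pod`, `bracket` added.
#' @export
annotate_samples <- function(records, meta) {
  idx <- match(records$sample_id, meta$sample_id)
  if (anyNA(idx))
    stop("sample_id not found in metadata: ",
         paste(unique(records$sample_id[is.na(idx)]), collapse = ", "))
  records$patient_id <- meta$patient_id[idx]
  records$tissue <- meta$tissue[idx]
  records$pod <- meta$pod[idx]
  records$bracket <- assign_bracket(records$pod)
  records
}
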