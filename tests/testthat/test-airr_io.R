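# IO: reading, validation, normalization, round trips.

write_airr_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

airr_rows <- function(n = 3) {
  data.frame(
    sequence_id = sprintf("s%d", seq_len(n)), sample_id = "S1",
    v_call = "IGHV1-2*02", j_call = "IGHJ4*02",
    junction_aa = "CARDYWGQGTLVTVSSW", productive = "T",
    duplicate_count = 2L, v_mutation_count = 3L, v_sequenced_length = 240L,
    v_mutation_set = "101A>G;150C>T;200G>A", stringsAsFactors = FALSE)
}

test_that("well-formed tables parse; invariant violations are dropped and tallied", {
  p <- write_airr_tsv(airr_rows(3))
  rec <- read_rearrangements(p)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(attr(rec, "rejected")), 0)
  expect_identical(rec$v_mutation_set[[1]], c("101A>G", "150C>T", "200G>A"))

  bad <- airr_rows(4)
  bad$duplicate_count[2] <- 0L                        # copy number < 1
  bad$v_mutation_count[3] <- 500L                     # exceeds v length
  bad$v_mutation_set[3] <- ""                         # (absent set is fine)
  bad$v_mutation_set[4] <- "101A>G"                   # cardinality mismatch
  p <- write_airr_tsv(bad)
  rec <- suppressMessages(read_rearrangements(p))
  expect_equal(nrow(rec), 1)
  tally <- attr(rec, "rejected")
  expect_equal(unname(tally["copy_number_lt_1"]), 1L)
  expect_equal(unname(tally["mutations_exceed_length"]), 1L)
  expect_equal(unname(tally["mutation_set_cardinality"]), 1L)
})

test_that("V/J calls are collapsed to gene level and parsing ignores column order", {
  rows <- airr_rows(2)
  rows$v_call <- c("IGHV1-2*02", "IGHV1-2*04")
  p1 <- write_airr_tsv(rows)
  p2 <- write_airr_tsv(rows[, rev(names(rows))])
  r1 <- read_rearrangements(p1)
  r2 <- read_rearrangements(p2)
  expect_equal(unique(r1$v_gene), "IGHV1-2")
  expect_equal(r1$j_gene[1], "IGHJ4")
  expect_identical(r1, r2)
})

test_that("missing mandatory columns are a named hard error", {
  rows <- airr_rows(1)
  rows$duplicate_count <- NULL
  p <- write_airr_tsv(rows)
  expect_error(read_rearrangements(p), "duplicate_count")
})

test_that("write/read round trip is field-exact in both dialects", {
  set.seed(42)
  rec <- make_records(random_cdr3(15, 5), seq_id = sprintf("q%d", 1:5),
                      mut_count = 2L,
                      muts = replicate(5, c("101A>G", "150C>T"), simplify = FALSE))
  for (d in c("airr", "immunedb")) {
    p <- tempfile(fileext = ".tsv")
    write_rearrangements(rec, p, d)
    back <- read_rearrangements(p, d)
    for (col in setdiff(names(rec), "v_mutation_set"))
      expect_equal(back[[col]], rec[[col]], info = paste(d, col))
    expect_identical(unclass(back$v_mutation_set),
                     lapply(rec$v_mutation_set, sort), info = d)
  }
})

test_that("metadata reading validates ids, tissues, pods", {
  m <- make_meta(c("S1", "S2"), tissue = c("blood", "ileum"), pod = c(0L, 45L))
  p <- write_airr_tsv(m)
  got <- read_metadata(p)
  expect_equal(nrow(got), 2)
  expect_equal(got$pod, c(0L, 45L))

  dup <- rbind(m, m[1, ])
  expect_error(read_metadata(write_airr_tsv(dup)), "duplicate sample_id")

  bad_tissue <- m; bad_tissue$tissue[1] <- "spleen"
  expect_error(read_metadata(write_airr_tsv(bad_tissue)), "spleen")

  neg <- m; neg$pod[2] <- -3L
  got <- suppressMessages(read_metadata(write_airr_tsv(neg)))
  expect_equal(got$sample_id, "S1")
})

test_that("quiescent filter keeps none/indeterminate, drops rejection, idempotent", {
  m <- make_meta(sprintf("S%d", 1:6),
                 rejection = c("none", "mild", "none", "indeterminate",
                               "severe", "amr"))
  q <- filter_quiescent(m)
  expect_equal(q$sample_id, c("S1", "S3", "S4"))
  expect_identical(filter_quiescent(q), q)
  expect_equal(nrow(filter_quiescent(make_meta("S1", rejection = "amr"))), 0)
})

test_that("annotate_samples joins and errors on unresolvable sample", {
  rec <- make_records(random_cdr3(14, 2), sample = c("S1", "S2"))
  meta <- make_meta(c("S1", "S2"), tissue = c("blood", "ileum"),
                    pod = c(30L, 400L))
  a <- annotate_samples(rec, meta)
  expect_equal(a$bracket, c("early", "late"))
  expect_equal(a$tissue, c("blood", "ileum"))
  expect_error(annotate_samples(rec, meta[1, ]), "S2")
})
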