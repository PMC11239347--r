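# Clonal grouping, filters and per-clone mutation summaries.

test_that("grouping honors the 85% CDR3 identity rule within V/J/length buckets", {
  base <- paste(rep("A", 20), collapse = "")
  three_off <- paste0(paste(rep("A", 17), collapse = ""), "CDE")  # 17/20 = 85%
  four_off <- paste0(paste(rep("A", 16), collapse = ""), "CDEF")  # 16/20 = 80%

  g <- group_clones(make_records(c(base, base)))
  expect_equal(length(unique(g$clone_id)), 1)

  g <- group_clones(make_records(c(base, three_off)))
  expect_equal(length(unique(g$clone_id)), 1)

  g <- group_clones(make_records(c(base, four_off)))
  expect_equal(length(unique(g$clone_id)), 2)

  # identical CDR3, different J gene -> separate clones
  g <- group_clones(make_records(c(base, base), j = c("IGHJ4*02", "IGHJ6*02")))
  expect_equal(length(unique(g$clone_id)), 2)
})

test_that("partition matches the brute-force single-linkage oracle and is order-invariant", {
  set.seed(101)
  for (trial in 1:30) {
    n <- sample(2:20, 1)
    len <- sample(c(10L, 13L, 20L), 1)
    seed_cdr3 <- random_cdr3(len)
    cdr3s <- vapply(seq_len(n), function(i)
      mutate_cdr3(seed_cdr3, sample(0:min(len, 8), 1)), character(1))
    rec <- make_records(cdr3s)
    g <- group_clones(rec)
    got <- g$clone_id[match(rec$sequence_id, g$sequence_id)]
    expect_equal(canon_partition(got), canon_partition(oracle_partition(cdr3s)),
                 info = paste("trial", trial))

    perm <- sample(n)
    g2 <- group_clones(rec[perm, ])
    got2 <- g2$clone_id[match(rec$sequence_id, g2$sequence_id)]
    expect_equal(got2, got, info = paste("permutation, trial", trial))
  }
})

test_that("grouping is a partition and raising the threshold only refines it", {
  set.seed(7)
  seed_cdr3 <- random_cdr3(15)
  cdr3s <- vapply(1:15, function(i) mutate_cdr3(seed_cdr3, sample(0:5, 1)),
                  character(1))
  rec <- make_records(cdr3s)
  lo <- group_clones(rec, 0.7)
  hi <- group_clones(rec, 0.9)
  expect_setequal(lo$sequence_id, rec$sequence_id)  # every record placed once
  expect_false(anyDuplicated(lo$sequence_id) > 0)
  # refinement: members of one hi-threshold clone share one lo-threshold clone
  lo_of <- lo$clone_id[match(hi$sequence_id, lo$sequence_id)]
  for (cl in split(lo_of, hi$clone_id))
    expect_length(unique(cl), 1)
})

test_that("mutation fractions and the mutated-clone call use printed boundaries", {
  expect_equal(mutation_fraction(6L, 300L), 0.02)
  expect_equal(mutation_fraction(0L, 300L), 0)
  expect_equal(mutation_fraction(300L, 300L), 1)
  expect_error(mutation_fraction(1L, 0L), "positive")

  rec <- make_records(random_cdr3(14, 2), mut_count = c(3L, 9L), v_len = 300L)
  expect_equal(clone_mutation_fraction(rec), 0.02)   # mean(0.01, 0.03)
  expect_false(is_mutated_clone(rec))                # 0.020 not > 0.02
  rec2 <- make_records(random_cdr3(14, 2), mut_count = c(12L, 30L),
                       v_len = 1000L)                # fractions 0.012, 0.030
  expect_true(is_mutated_clone(rec2))                # mean 0.021 > 0.02

  set.seed(1)
  counts <- sample(0:20, 10, replace = TRUE)
  rec <- make_records(random_cdr3(14, 10), mut_count = counts, v_len = 240L)
  expect_equal(clone_mutation_fraction(rec), sum(counts / 240) / 10)
})

test_that("detectability needs a productive sequence at copy number >= 2 in the tissue", {
  rec <- make_records(random_cdr3(14, 3), sample = c("A", "A", "B"),
                      copy = c(1L, 2L, 5L), productive = c(TRUE, TRUE, FALSE))
  rec$tissue <- c("ileum", "ileum", "blood")
  expect_true(is_detectable(rec, "ileum"))
  expect_false(is_detectable(rec, "blood"))           # copy 5 but unproductive
  rec$copy_number[2] <- 1L
  expect_false(is_detectable(rec, "ileum"))           # only copy-1 left
})

test_that("bracket sizes count unique (sequence, sample) instances", {
  meta <- make_meta(c("E1", "E2", "M1"), pod = c(30L, 60L, 120L))
  rec <- make_records(rep(random_cdr3(14), 4),
                      seq_id = c("u1", "u2", "u1", "u1"),
                      sample = c("E1", "E1", "E2", "M1"))
  g <- group_clones(rec)
  sz <- clone_bracket_sizes(g, meta)
  expect_equal(sz$size[sz$bracket == "early"], 3)   # u1@E1, u2@E1, u1@E2
  expect_equal(sz$size[sz$bracket == "mid"], 1)
  expect_equal(nrow(sz), 2)                          # zero-size cells omitted
  expect_error(clone_bracket_sizes(g, meta[1:2, ]), "M1")
})

test_that("trunk clones need >= 5 mutations shared by >= 85% of unique sequences", {
  shared5 <- sprintf("%d0A>G", 10:14)
  shared4 <- shared5[1:4]
  mk <- function(n_with, n_without, shared) {
    # each sequence also carries private mutations at positions of its own
    muts <- c(lapply(seq_len(n_with), function(i)
                c(shared, sprintf("%dC>T", 500 + i))),
              lapply(seq_len(n_without), function(i)
                sprintf("%dC>T", c(700 + i, 800 + i))))
    make_records(random_cdr3(14, n_with + n_without),
                 mut_count = lengths(muts), muts = muts)
  }
  expect_true(is_trunk_clone(mk(9, 1, shared5)))     # 5 shared by 90%
  expect_false(is_trunk_clone(mk(9, 1, shared4)))    # only 4 shared
  expect_false(is_trunk_clone(mk(8, 2, shared5)))    # 80% < 85%
  rec <- make_records(random_cdr3(14, 2))
  expect_error(is_trunk_clone(rec), "mutation sets missing")
})

test_that("lineage-eligibility filter needs k unique sequences in both tissues", {
  mk <- function(n, tissues) {
    rec <- make_records(rep(random_cdr3(14), n),
                        seq_id = sprintf("u%d", seq_len(n)),
                        sample = sprintf("s%d", seq_len(n)))
    rec$tissue <- tissues
    group_clones(rec)
  }
  both3 <- mk(3, c("blood", "ileum", "blood"))
  expect_equal(nrow(min_unique_sequences_filter(both3)), 3)
  expect_equal(nrow(min_unique_sequences_filter(mk(2, c("blood", "ileum")))), 0)
  expect_equal(nrow(min_unique_sequences_filter(mk(5, rep("blood", 5)))), 0)
})
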