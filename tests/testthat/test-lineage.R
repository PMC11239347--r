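# Germline-rooted mutation-containment lineage trees.

test_that("containment chains, inferred intersection ancestors, disjoint clades", {
  # {a} subset of {a,b}: a chain below the root
  tr <- build_lineage(lineage_members(list("a", c("a", "b")),
                                      list("blood", "blood")))
  expect_equal(length(tr$key), 3)               # root, {a}, {a,b}
  expect_equal(populated_node_count(tr), 2)
  expect_equal(tr$key[tr$parent[match("a;b", tr$key)]], "a")

  # {a,b} and {a,c}: unpopulated inferred ancestor at {a}
  tr <- build_lineage(lineage_members(list(c("a", "b"), c("a", "c")),
                                      list("blood", "blood")))
  expect_equal(length(tr$key), 4)
  i_a <- match("a", tr$key)
  expect_false(tr$populated[i_a])
  expect_equal(populated_node_count(tr), 2)
  expect_true(all(tr$parent[match(c("a;b", "a;c"), tr$key)] == i_a))

  # disjoint {a}, {b}: two populated children directly under the root
  tr <- build_lineage(lineage_members(list("a", "b"), list("blood", "blood")))
  expect_equal(length(tr$key), 3)
  expect_true(all(tr$parent[-1] == 1))
})

test_that("root-to-node paths are strictly increasing mutation chains", {
  set.seed(5)
  sim <- simulate_repertoire(sim_config(seed = 5, n_patients = 1, n_clones = 20))
  a <- annotate_samples(group_clones(sim$rearrangements), sim$metadata)
  for (i in split(seq_len(nrow(a)), a$clone_id)[1:10]) {
    tr <- build_lineage(a[i, , drop = FALSE])
    for (v in seq_along(tr$key)[-1]) {
      p <- tr$parent[v]
      expect_true(all(tr$muts[[p]] %in% tr$muts[[v]]))
      expect_lt(length(tr$muts[[p]]), length(tr$muts[[v]]))
    }
  }
})

test_that("rebuild from a permuted member list is isomorphic", {
  set.seed(9)
  sets <- list(c("a"), c("a", "b"), c("a", "c"), c("d"), c("d", "e", "f"),
               c("a", "b", "g"))
  members <- lineage_members(sets, replicate(6, "blood", simplify = FALSE))
  t1 <- build_lineage(members)
  t2 <- build_lineage(members[sample(nrow(members)), , drop = FALSE])
  expect_identical(t1$key, t2$key)
  expect_identical(t1$parent, t2$parent)
  expect_identical(t1$populated, t2$populated)
})

test_that("populated nodes = distinct mutation sets; sequences with equal sets share a node", {
  # two unique sequences with the same genotype pool their labels
  tr <- build_lineage(lineage_members(list("a", "a", c("a", "b")),
                                      list("blood", "ileum", "blood")))
  expect_equal(populated_node_count(tr), 2)
  i_a <- match("a", tr$key)
  expect_equal(sort(tr$labels[[i_a]]), c("blood", "ileum"))
  expect_equal(tr$n_seqs[i_a], 2)

  set.seed(31)
  sim <- simulate_repertoire(sim_config(seed = 31, n_patients = 1, n_clones = 15))
  a <- annotate_samples(group_clones(sim$rearrangements), sim$metadata)
  for (i in split(seq_len(nrow(a)), a$clone_id)) {
    m <- a[i, , drop = FALSE]
    uniq <- m[!duplicated(m$sequence_id), ]
    n_geno <- length(unique(vapply(uniq$v_mutation_set, paste,
                                   character(1), collapse = ";")))
    tr <- build_lineage(m)
    expect_equal(populated_node_count(tr), n_geno)
    expect_lte(populated_node_count(tr), length(unique(m$sequence_id)))
  }
})

test_that("conflicting substitutions at one V position are rejected", {
  bad <- lineage_members(list(c("100A>G", "100A>T")), list("blood"))
  expect_error(build_lineage(bad), "conflicting mutation")
})

test_that("newick serialization carries populated flags and labels", {
  tr <- build_lineage(lineage_members(list("a", c("a", "b")),
                                      list("blood", "ileum")))
  nwk <- lineage_newick(tr)
  expect_match(nwk, "^\\(.*\\)N1\\[&populated=0,labels=\\]:1;$")
  expect_match(nwk, "populated=1,labels=blood")
  nodes <- lineage_nodes(tr)
  expect_equal(nrow(nodes), 3)
  expect_equal(nodes$parent_id[1], NA_integer_)
})
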