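# Time brackets, sign test, rank-sum, chimerism AUC, gate and DSA rules.

test_that("bracket assignment partitions non-negative PODs at the printed edges", {
  expect_equal(assign_bracket(c(0L, 1L, 90L, 91L, 365L, 366L, 1000L)),
               c("pre", "early", "early", "mid", "mid", "late", "late"))
  pods <- 0:1000
  br <- assign_bracket(pods)
  expect_true(all(br %in% c("pre", "early", "mid", "late")))
  expect_equal(sum(br == "pre"), 1)
  expect_error(assign_bracket(-1L), "non-negative")
})

test_that("sign test: exact binomial, ties excluded, symmetric", {
  bal <- sign_test_clone_sizes(setNames(1:10, letters[1:10]),
                               setNames(c(2:6, 0:4), letters[1:10]))
  expect_equal(bal$n_plus, 5); expect_equal(bal$n_minus, 5)
  expect_equal(bal$p_value, 1)

  up <- sign_test_clone_sizes(setNames(rep(1, 10), letters[1:10]),
                              setNames(rep(2, 10), letters[1:10]))
  expect_equal(up$p_value, 2 / 1024)

  mix <- sign_test_clone_sizes(
    setNames(c(1, 1, 1, 2, 2, 2, 5, 5, 5, 5), letters[1:10]),
    setNames(c(2, 2, 2, 1, 1, 1, 5, 5, 5, 5), letters[1:10]))
  expect_equal(mix$n_plus, 3); expect_equal(mix$n_minus, 3)

  a <- sign_test_clone_sizes(setNames(1:8, letters[1:8]),
                             setNames(c(2, 2, 2, 2, 2, 2, 0, 0), letters[1:8]))
  b <- sign_test_clone_sizes(setNames(c(2, 2, 2, 2, 2, 2, 0, 0), letters[1:8]),
                             setNames(1:8, letters[1:8]))
  expect_equal(a$p_value, b$p_value)

  expect_warning(
    res <- sign_test_clone_sizes(c(x = 1), c(y = 1)),
    class = "bcrflow_no_informative_clones")
  expect_true(is.na(res$p_value))
})

test_that("rank-sum: exact small-sample values and tie handling", {
  expect_equal(rank_sum_compare(1:3, 4:6), 0.1)
  expect_equal(rank_sum_compare(5, 5), 1)
  expect_equal(rank_sum_compare(c(1, 2), c(1, 2)), 1)
  # exact path agrees with wilcox.test and with full enumeration
  set.seed(11)
  for (i in 1:15) {
    x <- sample(seq(0, 100, by = 0.5), sample(2:6, 1))
    y <- sample(setdiff(seq(0, 100, by = 0.5), x), sample(2:6, 1))
    p <- rank_sum_compare(x, y)
    expect_equal(p, wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(p, mwu_enumerate(x, y), tolerance = 1e-12)
  }
  # large samples fall back to the tie-corrected normal approximation
  set.seed(12)
  x <- rnorm(30); y <- rnorm(30) + 2
  expect_lt(rank_sum_compare(x, y), 0.001)
})

test_that("normalized chimerism AUC: flat line, two-point oracle, bounds", {
  flat <- data.frame(pod = c(10, 40, 100), percent = 50)
  expect_equal(chimerism_auc_normalized(flat), 50)
  two <- data.frame(pod = c(0, 10), percent = c(0, 100))
  expect_equal(chimerism_auc_normalized(two), 50)          # 500 / 10
  expect_warning(
    v <- chimerism_auc_normalized(data.frame(pod = 5, percent = 10)),
    class = "bcrflow_auc_undefined")
  expect_true(is.na(v))
  set.seed(4)
  for (i in 1:10) {
    s <- data.frame(pod = sort(sample(1:500, 6)), percent = runif(6, 20, 80))
    v <- chimerism_auc_normalized(s)
    expect_gte(v, min(s$percent)); expect_lte(v, max(s$percent))
  }
  # bracket restriction uses only in-bracket points
  s <- data.frame(pod = c(10, 50, 200, 300), percent = c(0, 100, 40, 40))
  expect_equal(chimerism_auc_normalized(s, "early"), 50)
  expect_equal(chimerism_auc_normalized(s, "mid"), 40)
})

test_that("parent-gate filter keeps >= 40 events and drops missing counts", {
  s <- data.frame(pod = 1:3, percent = 10,
                  parent_gate_count = c(40L, 39L, NA))
  out <- suppressWarnings(parent_gate_filter(s))
  expect_equal(out$parent_gate_count, 40L)
  expect_warning(parent_gate_filter(s), "missing parent gate")
})

test_that("DSA positivity uses the printed MFI increments", {
  expect_true(call_dsa_positive(4500, 2000, "serum"))      # delta 2500
  expect_false(call_dsa_positive(3999, 2000, "serum"))     # delta 1999
  expect_true(call_dsa_positive(4000, 2000, "serum"))      # delta 2000 inclusive
  expect_true(call_dsa_positive(600, 100, "supernatant"))  # delta 500
  expect_false(call_dsa_positive(599, 100, "supernatant"))
  expect_error(call_dsa_positive(-1, 0, "serum"), "non-negative")
})
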