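test_that("group means skip missing values and respect the usability rule", {
  p <- toy_pdui(matrix(c(0.2, 0.4, NA, 0.6, 0.5, 0.5), 1, 6))
  lab <- setNames(c("A", "A", "A", "B", "B", "B"), colnames(p))
  gm <- group_mean_pdui(p, lab, min_per_group = 2)
  expect_equal(unname(gm$means[1, "A"]), 0.3)   # {0.2, 0.4, NA} -> 0.3
  expect_true(gm$usable[1])
  gm3 <- group_mean_pdui(p, lab, min_per_group = 3)
  expect_false(gm3$usable[1])                   # only 2 non-missing in A
  # single-sample group mean equals that sample's value
  lab1 <- setNames(c("A", rep("B", 5)), colnames(p))
  gm1 <- group_mean_pdui(p, lab1, min_per_group = 1)
  expect_equal(unname(gm1$means[1, "A"]), 0.2)
  expect_error(group_mean_pdui(p, setNames(rep("A", 6), colnames(p))[-1]),
               "missing")
})

test_that("delta-PDUI is a signed antisymmetric group-mean difference", {
  p <- toy_pdui(matrix(c(0.7, 0.7, 0.5, 0.5), 1, 4))
  lab <- setNames(c("A", "A", "B", "B"), colnames(p))
  gm <- group_mean_pdui(p, lab, min_per_group = 2)
  expect_equal(unname(delta_pdui(gm, "A", "B")), 0.2)
  expect_equal(delta_pdui(gm, "A", "B"), -delta_pdui(gm, "B", "A"))
  expect_error(delta_pdui(gm, "A", "C"), "unknown group")
  # identical groups give exactly zero
  p0 <- toy_pdui(matrix(0.42, 3, 4))
  gm0 <- group_mean_pdui(p0, lab, min_per_group = 2)
  expect_equal(unname(delta_pdui(gm0, "A", "B")), rep(0, 3))
})

test_that("permutation p matches exhaustive enumeration on tiny instances", {
  set.seed(42)
  m <- matrix(runif(5 * 5), 5, 5)
  p <- toy_pdui(m)
  lab <- setNames(c("A", "A", "A", "B", "B"), colnames(p))
  pt <- permutation_pvalues(p, lab, method = "exhaustive", min_per_group = 2)
  oracle <- vapply(seq_len(nrow(m)), function(i)
    enumerate_perm_p(m[i, ], lab, "A"), numeric(1))
  expect_equal(unname(pt$p), oracle)
})

test_that("degenerate and null events get honest permutation p-values", {
  m <- rbind(rep(0.5, 8), runif(8))
  p <- toy_pdui(m)
  lab <- setNames(rep(c("A", "B"), each = 4), colnames(p))
  pt <- quiet(permutation_pvalues(p, lab, B = 200, seed = 1, min_per_group = 2))
  expect_equal(unname(pt$p[1]), 1)       # constant event: delta 0, p = 1
  expect_true(all(pt$p > 0 & pt$p <= 1))
  expect_warning(permutation_pvalues(p, lab, B = 50, seed = 1, min_per_group = 2),
                 "coarse")
  expect_error(permutation_pvalues(p, lab, B = 0, seed = 1), "B must be")
})

test_that("BH adjustment reproduces the hand-computed step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("the calling rule applies inclusive delta and exclusive p cutoffs", {
  d <- setNames(c(0.10, 0.09, -0.30, 0.50), paste0("E", 1:4, "|chr1|", 1:4))
  p <- c(0.04, 0.001, 0.01, 0.05)
  res <- call_differential(d, p)
  expect_true(res$called[1])             # |delta| = 0.1 is inclusive
  expect_false(res$called[2])            # effect too small despite tiny p
  expect_true(res$called[3])
  expect_false(res$called[4])            # p = 0.05 is exclusive
  expect_equal(res$direction, c("shortened", "none", "lengthened", "none"))
  expect_error(call_differential(d, p[1:2]), "lengths")
})

test_that("calling is monotone in both thresholds", {
  set.seed(7)
  d <- setNames(runif(200, -0.4, 0.4), sprintf("E%03d|chr1|%d", 1:200, 1:200))
  p <- runif(200)^2
  base <- call_differential(d, p, 0.1, 0.05)
  looser <- call_differential(d, p, 0.05, 0.2)
  expect_true(all(looser$called[base$called]))
})

test_that("one-vs-rest contrasts localize a subgroup-specific event", {
  set.seed(3)
  n <- 30
  sub <- rep(c("TA", "TS", "TN"), each = n / 3)
  m <- matrix(rbeta(20 * n, 10, 10), 20, n)
  m[1, sub == "TA"] <- rbeta(n / 3, 16, 4)   # elevated only in TA
  p <- toy_pdui(m)
  names(sub) <- colnames(p)
  res <- quiet(one_vs_rest_differential(p, sub, B = 200, seed = 1,
                                        min_per_group = 2))
  expect_named(res, c("TA", "TS", "TN"))
  expect_true(res$TA$called[1])
  expect_true(abs(res$TA$delta_pdui[1]) > abs(res$TS$delta_pdui[1]))
  expect_error(one_vs_rest_differential(p, setNames(rep(c("TA", "TS"), n / 2),
                                                    colnames(p))),
               "missing subgroup")
})

test_that("gradient events require strict monotonicity and range", {
  m <- rbind(c(0.2, 0.4, 0.6), c(0.2, 0.5, 0.4), c(0.30, 0.35, 0.38),
             c(0.8, 0.6, 0.3))
  rownames(m) <- sprintf("E%d|chr1|%d", 1:4, 1:4)
  colnames(m) <- c("TA", "TS", "TN")
  g <- gradient_events(m, delta_threshold = 0.1)
  expect_setequal(g$event_id, rownames(m)[c(1, 4)])
  expect_equal(g$direction[g$event_id == rownames(m)[1]], "increasing")
  expect_equal(g$direction[g$event_id == rownames(m)[4]], "decreasing")
  # row 2 is non-monotone; row 3 monotone but range 0.08 < 0.1
})

test_that("T-cell subgroup assignment uses summed class mass and tie priority", {
  pops <- names(tcell_population_classes())
  prop <- matrix(0, 2, 8, dimnames = list(c("s1", "s2"), pops))
  prop["s1", ] <- c(0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.05, 0.05)  # activation 0.6
  prop["s2", ] <- c(0.4, 0, 0, 0.4, 0, 0, 0.1, 0.1)            # exact TA/TS tie
  lab <- assign_tcell_subgroup(prop)
  expect_equal(unname(lab), c("TA", "TA"))
  expect_error(assign_tcell_subgroup(prop[, -1]), "sum to 1")
  colnames(prop)[1] <- "unknown_pop"
  expect_error(assign_tcell_subgroup(prop), "class map")
})
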