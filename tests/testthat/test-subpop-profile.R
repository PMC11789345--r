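test_that("planted partition is recovered exactly and deterministically", {
  blobs <- make_blobs(n_per = 60)
  lab <- cluster_subpopulation(blobs$x, seed = 4)
  tab <- table(lab, blobs$truth)
  expect_equal(length(unique(lab)), 2L)
  # one-to-one correspondence with the planted blobs (ARI = 1)
  expect_equal(sum(apply(tab, 1, max)), nrow(blobs$x))
  expect_identical(lab, cluster_subpopulation(blobs$x, seed = 4))
  expect_error(cluster_subpopulation(blobs$x[1:2, ]),
               class = "fiberfa_value_error")
  expect_warning(cluster_subpopulation(blobs$x[1:5, ], n_neighbors = 15),
                 "clamped")
})

test_that("sigup discovery flags a planted marker and honors thresholds", {
  set.seed(21)
  n <- 200
  x <- matrix(rnorm(2 * n * 30), 2 * n, 30,
              dimnames = list(NULL, sprintf("g%02d", 1:30)))
  lab <- rep(c("a", "b"), each = n)
  x[lab == "a", "g01"] <- x[lab == "a", "g01"] + 4   # 4-fold in log2 units
  sig <- find_sigups(x, lab)
  expect_true("g01" %in% sig$sets$a)
  expect_false("g01" %in% sig$sets$b)
  expect_equal(find_sigups(x, lab, min_lfc = Inf)$sets$a, character())
  expect_error(find_sigups(x, rep("a", 2 * n)),
               class = "fiberfa_value_error")
})

test_that("sigup discovery is calibrated under label permutation", {
  set.seed(22)
  n <- 150
  x <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(NULL, sprintf("g%02d", 1:30)))
  lab <- rep(c("a", "b"), length.out = n)
  flagged <- replicate(200, {
    sig <- find_sigups(x, sample(lab), min_lfc = 0)
    (length(sig$sets$a) + length(sig$sets$b)) / (2 * ncol(x))
  })
  expect_lte(mean(flagged), 0.05)
})

test_that("cluster naming follows the sigup grammar", {
  sizes <- c(A = 300, B = 200, C = 150, D = 120, E = 100)
  sigups <- list(A = c("Ckm", "Pygm"), B = "Ckm", C = "Myh4",
                 D = character(), E = character())
  ann <- name_clusters(sigups, sizes)
  expect_equal(ann$cluster, c("A", "B", "C", "D", "E"))  # descending size
  # A and B share the name gene Ckm: indexed by descending size
  expect_equal(ann$name[ann$cluster == "A"], "Ckm+(1)")
  expect_equal(ann$name[ann$cluster == "B"], "Ckm+(2)")
  expect_equal(ann$name[ann$cluster == "C"], "Myh4+")    # unique sigup
  expect_equal(ann$name[ann$cluster == "D"], "Unknown(1)")
  expect_equal(ann$name[ann$cluster == "E"], "Unknown(2)")
  expect_false(anyDuplicated(ann$name) > 0)
  # identical sigup sets always share a base name and get indexed
  ann2 <- name_clusters(list(X = "Ckm", Y = "Ckm"), c(X = 10, Y = 50))
  expect_equal(ann2$name, c("Ckm+(1)", "Ckm+(2)"))
  expect_equal(ann2$cluster, c("Y", "X"))
  # single unknown stays unindexed
  ann3 <- name_clusters(list(Z = character()), c(Z = 5))
  expect_equal(ann3$name, "Unknown")
  # naming is a pure function: repeated calls agree
  expect_identical(ann, name_clusters(sigups, sizes))
})

test_that("condition proportions tally fractions that sum to one", {
  lab <- c("x", "x", "y", "y", "y", "y")
  cond <- c("A", "A", "A", "B", "B", "B")
  pt <- condition_proportions(lab, cond)
  expect_equal(pt$fractions["A", ], c(x = 2 / 3, y = 1 / 3))
  expect_equal(pt$fractions["B", ], c(x = 0, y = 1))
  expect_equal(unname(rowSums(pt$fractions)), c(1, 1))
  expect_equal(pt$counts["A", "x"], 2)
  # single cluster: every row is exactly 1
  pt1 <- condition_proportions(rep("only", 4), c("A", "A", "B", "B"))
  expect_true(all(pt1$fractions == 1))
  # empty condition level is dropped with a warning
  expect_warning(
    pt2 <- condition_proportions(lab, factor(cond, levels = c("A", "B", "C"))),
    "zero cells")
  expect_equal(rownames(pt2$fractions), c("A", "B"))
})

test_that("combining clusters sums fractions and validates names", {
  pt <- condition_proportions(c("x", "y", "z", "x", "x", "z"),
                              rep(c("A", "B"), each = 3))
  all_names <- colnames(pt$fractions)
  expect_equal(unname(combine_clusters(pt, all_names)), c(1, 1))
  expect_equal(unname(combine_clusters(pt, character())), c(0, 0))
  expect_equal(combine_clusters(pt, c("x", "z")),
               c(A = 2 / 3, B = 1))
  # additive over disjoint name sets
  expect_equal(combine_clusters(pt, c("x", "z")),
               combine_clusters(pt, "x") + combine_clusters(pt, "z"))
  expect_error(combine_clusters(pt, "nope"), class = "fiberfa_lookup_error")
})

test_that("marker comparison is calibrated under the null and powered", {
  set.seed(30)
  n <- 200
  cond <- rep(c("Ctrl", "P", "P_PG"), each = n)
  null_flags <- replicate(200, {
    x <- matrix(rnorm(3 * n * 2), 3 * n, 2,
                dimnames = list(NULL, c("Fbxo32", "Trim63")))
    res <- compare_marker_expression(x, conditions = cond)
    any(res$p_adj < 0.05)
  })
  expect_lt(mean(null_flags), 0.12)   # family-level false alarms are rare
  # a planted 2-fold (1 log2 unit) shift is detected with high power
  hits <- replicate(50, {
    x <- matrix(rnorm(3 * n * 2), 3 * n, 2,
                dimnames = list(NULL, c("Fbxo32", "Trim63")))
    x[cond == "P_PG", "Fbxo32"] <- x[cond == "P_PG", "Fbxo32"] + 1
    res <- compare_marker_expression(x, conditions = cond)
    any(res$p_adj < 0.05 & res$gene == "Fbxo32")
  })
  expect_gt(mean(hits), 0.8)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(compare_marker_expression(x, genes = "Fbxo32",
                                         conditions = rep(c("A", "B"), 5)),
               class = "fiberfa_lookup_error")
})
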