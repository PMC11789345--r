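test_that("generator produces aligned counts and truth, deterministically", {
  cfg <- sim_config(n_cells_per_condition = 100, seed = 7)
  sim <- generate_fiber_counts(cfg)
  expect_equal(length(sim$counts$cells), 300)
  expect_equal(sim$truth$cell, sim$counts$cells)
  expect_equal(sim$truth$condition, sim$counts$condition)
  expect_true(all(sim$counts$counts >= 0))
  expect_true(all(sim$counts$counts == round(sim$counts$counts)))
  # recorded class tallies agree with the truth table
  cc <- attr(sim$truth, "class_counts")
  expect_equal(unclass(cc),
               unclass(table(condition = sim$truth$condition,
                             class = sim$truth$true_class)))
  # truth class consistent with program intensities
  elev <- 2^cfg$program_mean_lfc
  expect_true(all(sim$truth$intensity_fast[sim$truth$true_class == "fast"] == elev))
  expect_true(all(sim$truth$intensity_slow[sim$truth$true_class == "fast"] == 1))
  expect_true(all(sim$truth$intensity_fast[sim$truth$true_class == "negative"] == 1))
  # byte-identical rerun
  sim2 <- generate_fiber_counts(sim_config(n_cells_per_condition = 100, seed = 7))
  expect_identical(sim, sim2)
  # and a different seed actually changes the draw
  sim3 <- generate_fiber_counts(sim_config(n_cells_per_condition = 100, seed = 8))
  expect_false(identical(sim$counts$counts, sim3$counts$counts))
})

test_that("zero cells per condition gives an empty matrix with intact panel", {
  sim <- generate_fiber_counts(sim_config(n_cells_per_condition = 0))
  expect_equal(nrow(sim$counts$counts), 0)
  expect_equal(sim$counts$genes,
               unlist(default_gene_panel(), use.names = FALSE))
  expect_equal(nrow(sim$truth), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_mix = c(fast = -0.1, slow = 0.5,
                                        hybrid = 0.3, negative = 0.3)),
               class = "fiberfa_config_error")
  expect_error(sim_config(gene_panel = list()),
               class = "fiberfa_config_error")
  expect_error(sim_config(slow_depletion = 0), class = "fiberfa_config_error")
  expect_error(sim_config(outlier_frac = 1.2), class = "fiberfa_config_error")
  expect_error(sim_config(gene_panel = list(fast = c("Myh1", "Myh1"))),
               class = "fiberfa_config_error")
})

test_that("slow depletion halves the slow-class probability before renormalization", {
  cfg <- sim_config(n_cells_per_condition = 2000, slow_depletion = 0.5,
                    seed = 21)
  sim <- generate_fiber_counts(cfg)
  frac <- tapply(sim$truth$true_class == "slow", sim$truth$condition, mean)
  # construction: Ctrl slow prob 0.2; depleted 0.1 / 0.9 after renormalizing
  p_dep <- 0.1 / 0.9
  se <- sqrt(0.2 * 0.8 / 2000) + sqrt(p_dep * (1 - p_dep) / 2000)
  expect_lt(abs(frac[["Ctrl"]] - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  expect_lt(abs(frac[["P_PG"]] - p_dep), 3 * sqrt(p_dep * (1 - p_dep) / 2000))
  expect_lt(abs(frac[["P_PG"]] / frac[["Ctrl"]] - p_dep / 0.2), 0.12)
})

test_that("program elevation and planted outlier rate match the design", {
  cfg <- sim_config(seed = 31)
  sim <- generate_fiber_counts(cfg)
  fastg <- cfg$gene_panel$fast
  mfast <- mean(sim$counts$counts[sim$truth$true_class == "fast", fastg])
  mneg <- mean(sim$counts$counts[sim$truth$true_class == "negative", fastg])
  expect_lt(abs(log2(mfast / mneg) - cfg$program_mean_lfc), 0.3)
  n <- nrow(sim$truth)
  expect_lt(abs(mean(sim$truth$qc_outlier) - cfg$outlier_frac),
            1.96 * sqrt(0.1 * 0.9 / n))
})

test_that("GO annotation designer realizes overlaps exactly", {
  ann <- generate_go_annotations(n_terms = 10, seed = 3)
  # Myh7b shares 6 of Myh7's 10 terms and has 10 in total: J = 6/14
  expect_equal(jaccard(ann$Myh7, ann$Myh7b), 6 / 14)
  expect_equal(jaccard(ann$Myh7, ann$Myh11), 5 / 15)
  expect_equal(jaccard(ann$Myh1, ann$Myh3), 4 / 16)
  # distractors are disjoint from every seed
  for (d in c("Ckm", "Fbxo32"))
    for (s in c("Myh1", "Myh2", "Myh4", "Myh7"))
      expect_equal(jaccard(ann[[d]], ann[[s]]), 0)
  expect_identical(ann, generate_go_annotations(n_terms = 10, seed = 3))
  expect_error(generate_go_annotations(
    similar = data.frame(gene = "x", seed = "Myh7", overlap = 1.5)),
    class = "fiberfa_config_error")
})
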