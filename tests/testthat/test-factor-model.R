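# Each operation is checked against an oracle that does not share code
# with the implementation: closed-form partials for KMO, a principal-axis
# iteration for minres, a grid search for the rotation, the direct matrix
# formula for scores.

test_that("KMO matches the closed-form partial-correlation oracle", {
  R <- matrix(c(1, .6, .3,
                .6, 1, .2,
                .3, .2, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  k <- kmo(R)
  # oracle: for p = 3 the partial of (i, j) given the third variable has
  # the textbook regression-residual form
  pr <- function(rab, rac, rbc)
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  q <- c(pr(.6, .3, .2), pr(.3, .6, .2), pr(.2, .6, .3))
  r <- c(.6, .3, .2)
  oracle <- sum(2 * r^2) / (sum(2 * r^2) + sum(2 * q^2))
  expect_lt(abs(k$overall - oracle), 1e-10)
  expect_true(all(k$msa >= 0 & k$msa <= 1))
})

test_that("an independent variable has the smallest MSA; singularity errors", {
  # two near-perfectly correlated variables plus one independent: the
  # independent variable has zero shared variance, so its MSA is 0
  R <- matrix(c(1, .999, 0,
                .999, 1, 0,
                0, 0, 1), 3, 3,
              dimnames = list(c("v1", "v2", "v3"), c("v1", "v2", "v3")))
  k <- kmo(R)
  expect_equal(unname(which.min(k$msa)), 3L)
  expect_equal(unname(k$msa[3]), 0)
  # exactly collinear variables make the correlation matrix singular
  set.seed(8)
  v <- rnorm(50)
  xs <- cbind(a = v, b = v, c = rnorm(50))
  expect_error(kmo(xs), class = "fiberfa_value_error")
  expect_silent(kmo(xs, ridge = 1e-6))
  expect_error(kmo(cbind(a = rep(1, 10), b = rnorm(10))),
               class = "fiberfa_value_error")
})

test_that("parallel analysis retains 0 on noise, 1 on rank-1 structure", {
  set.seed(13)
  noise <- matrix(rnorm(500 * 7), 500, 7)
  pa <- parallel_analysis(noise, seed = 99)
  expect_equal(pa$m_retained, 0L)
  expect_equal(nrow(pa$eigen_table), 7)
  # one factor exactly replicated across all variables
  f <- rnorm(200)
  rank1 <- matrix(f, 200, 6) * rep(runif(6, .5, 2), each = 200)
  expect_equal(parallel_analysis(rank1, seed = 1)$m_retained, 1L)
  expect_error(parallel_analysis(noise, n_reps = 0),
               class = "fiberfa_value_error")
  # deterministic given seed
  expect_identical(parallel_analysis(noise, seed = 7),
                   parallel_analysis(noise, seed = 7))
})

test_that("minres recovers a noiseless one-factor model exactly", {
  set.seed(4)
  f <- rnorm(100)
  x <- outer(f, runif(6, 0.5, 2))    # rank-1, no unique variance
  colnames(x) <- paste0("v", 1:6)
  fit <- extract_factors(x, 1)
  expect_lt(max(abs(fit$communalities - 1)), 1e-6)
  expect_lt(max(fit$uniquenesses), 1e-6)
  expect_error(extract_factors(x, 0), class = "fiberfa_value_error")
  expect_error(extract_factors(x, 6), class = "fiberfa_value_error")
})

test_that("minres objective is at least as good as the principal-axis oracle", {
  # fixed correlation matrix from a two-factor population model
  L0 <- rbind(c(.8, 0), c(.7, .1), c(.75, 0),
              c(0, .7), c(.1, .65), c(0, .6), c(.2, .2))
  R <- tcrossprod(L0)
  diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:7), paste0("v", 1:7))
  fit <- extract_factors(R, 2)
  L_pa <- principal_axis_oracle(R, 2)
  expect_lte(fit$objective, offdiag_rss(R, L_pa) + 1e-10)
  expect_true(all(fit$communalities >= 0 & fit$communalities <= 1))
})

test_that("quartimin rotation: fixed point, grid-search optimum, invariants", {
  # perfect simple structure is already optimal: criterion 0, loadings
  # unchanged up to column permutation and sign
  L_simple <- rbind(c(.8, 0), c(.7, 0), c(.6, 0),
                    c(0, .7), c(0, .8), c(0, .5), c(0, .6))
  rot <- rotate_quartimin(L_simple)
  expect_lt(rot$criterion, 1e-10)
  recov <- abs(rot$loadings)
  perm_match <- min(max(abs(recov - L_simple)),
                    max(abs(recov - L_simple[, 2:1])))
  expect_lt(perm_match, 1e-5)

  # random loadings: optimum matches the two-angle grid-search oracle
  set.seed(9)
  A <- matrix(rnorm(14, 0, 0.5), 7, 2)
  rot2 <- rotate_quartimin(A)
  expect_lt(abs(rot2$criterion - grid_quartimin_oracle(A)), 1e-4)

  # algebraic invariants: model fit and communalities preserved
  fit_before <- tcrossprod(A)
  fit_after <- rot2$loadings %*% rot2$Phi %*% t(rot2$loadings)
  expect_lt(max(abs(fit_before - fit_after)), 1e-8)
  expect_lt(max(abs(diag(fit_before) - diag(fit_after))), 1e-8)
  expect_equal(diag(rot2$Phi), c(1, 1), tolerance = 1e-10)
  expect_error(rotate_quartimin(A[, 1, drop = FALSE]),
               class = "fiberfa_value_error")
})

test_that("regression scores equal the direct matrix formula and recover truth", {
  set.seed(15)
  n <- 20
  Phi <- matrix(c(1, .3, .3, 1), 2, 2)
  L <- rbind(c(.8, .1), c(.7, 0), c(.75, .05),
             c(0, .8), c(.1, .7), c(.05, .6), c(.3, .3))
  rownames(L) <- paste0("v", 1:7)
  x <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("v", 1:7)))
  F1 <- score_factors(x, L, Phi)
  # direct formula, written out independently
  Z <- scale(x)
  W <- solve(cor(x)) %*% (L %*% Phi)
  expect_lt(max(abs(F1 - Z %*% W)), 1e-10)

  # near-noiseless two-factor model (tiny uniquenesses, data drawn from
  # the standardized model): scores track the true factors
  set.seed(16)
  Ln <- rbind(c(.99, 0), c(.98, .05), c(.97, 0),
              c(0, .99), c(.05, .98), c(0, .97), c(.6, .6))
  rownames(Ln) <- paste0("v", 1:7)
  h2 <- diag(Ln %*% Phi %*% t(Ln))
  Ftrue <- matrix(rnorm(600 * 2), 600, 2) %*% chol(Phi)
  xx <- Ftrue %*% t(Ln) +
    matrix(rnorm(600 * 7), 600, 7) %*% diag(sqrt(pmax(1 - h2, 1e-4)))
  colnames(xx) <- paste0("v", 1:7)
  Fs <- score_factors(xx, Ln, Phi)
  expect_gt(cor(Fs[, 1], Ftrue[, 1]), 0.99)
  expect_gt(cor(Fs[, 2], Ftrue[, 2]), 0.99)
  expect_error(score_factors(cbind(x, vc = 1), L, Phi),
               class = "fiberfa_value_error")
})

test_that("factor-to-fiber mapping is permutation invariant and guards ambiguity", {
  L <- rbind(Myh1 = c(.8, 0), Myh2 = c(.75, .1), Myh4 = c(.7, 0),
             Myh7 = c(0, .8), Myh7b = c(.1, .7),
             Myh11 = c(0, 0), Myh3 = c(0, 0))
  m1 <- map_factors_to_fiber_types(L, c("Myh1", "Myh2", "Myh4"), "Myh7")
  expect_equal(m1$fast, 1L)
  expect_equal(m1$slow, 2L)
  m2 <- map_factors_to_fiber_types(L[, 2:1], c("Myh1", "Myh2", "Myh4"), "Myh7")
  expect_equal(m2$fast, 2L)
  expect_equal(m2$slow, 1L)
  # all-zero slow seed rows cannot be mapped
  L0 <- L; L0["Myh7", ] <- 0
  expect_error(map_factors_to_fiber_types(L0, c("Myh1", "Myh2", "Myh4"), "Myh7"),
               class = "fiberfa_mapping_error")
  # both programs winning the same factor is ambiguous
  La <- rbind(Myh1 = c(.8, 0), Myh7 = c(.7, .1))
  expect_error(map_factors_to_fiber_types(La, "Myh1", "Myh7"),
               class = "fiberfa_mapping_error")
})

test_that("full fit on synthetic data recovers the program-loading pattern", {
  pr <- default_processed()
  fa <- fit_fiber_factors(pr$expr, fa_panel, seed = 5)
  expect_equal(fa$m, 2L)
  expect_gt(fa$kmo, 0.5)
  # fast seeds load on the fast factor, slow genes on the slow factor
  expect_gt(mean(fa$loadings[c("Myh1", "Myh2", "Myh4"), "F_fast"]), 0.6)
  expect_lt(max(abs(fa$loadings[c("Myh1", "Myh2", "Myh4"), "F_slow"])), 0.3)
  expect_gt(mean(fa$loadings[c("Myh7", "Myh7b"), "F_slow"]), 0.5)
  expect_lt(max(abs(fa$loadings[c("Myh7", "Myh7b"), "F_fast"])), 0.3)
  # communalities are rotation invariants of the model
  expect_lt(max(abs(diag(fa$loadings %*% fa$Phi %*% t(fa$loadings)) -
                      fa$communalities)), 1e-6)
  expect_true(all(abs(fa$loadings) <= 1 + 1e-6))
  expect_true(all(fa$uniquenesses >= -1e-6 & fa$uniquenesses <= 1))
})
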