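# Shared fixtures and independent oracles.

# Sum of squared off-diagonal residuals of R - L L'.
offdiag_rss <- function(R, L) {
  resid <- R - tcrossprod(L)
  diag(resid) <- 0
  sum(resid^2)
}

# Principal-axis iteration: the classical EFA algorithm, independent of the
# package's minres optimizer.
principal_axis_oracle <- function(R, m, max_iter = 500) {
  h2 <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, ncol(R)))
  for (i in seq_len(max_iter)) {
    Rs <- R
    diag(Rs) <- h2
    e <- eigen(Rs, symmetric = TRUE)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < 1e-10) break
    h2 <- h2_new
  }
  L
}

# Brute-force quartimin oracle for 2 factors: grid search over the two
# oblique rotation angles (coarse pass, then 1e-3-resolution refinement
# around the coarse optimum).
grid_quartimin_oracle <- function(A, coarse = 0.01, fine = 1e-3) {
  crit <- function(a, b) {
    Tm <- cbind(c(cos(a), sin(a)), c(cos(b), sin(b)))
    if (abs(det(Tm)) < 1e-6) return(Inf)
    quartimin_criterion(A %*% t(solve(Tm)))
  }
  grid <- seq(-pi / 2, pi / 2, by = coarse)
  vals <- outer(grid, grid, Vectorize(crit))
  i <- which(vals == min(vals), arr.ind = TRUE)[1L, ]
  fa <- seq(grid[i[1L]] - 1.5 * coarse, grid[i[1L]] + 1.5 * coarse, by = fine)
  fb <- seq(grid[i[2L]] - 1.5 * coarse, grid[i[2L]] + 1.5 * coarse, by = fine)
  min(outer(fa, fb, Vectorize(crit)))
}

# Small fiber_counts with controllable totals/mito for QC boundary tests.
make_qc_counts <- function(totals, mito_frac, condition = NULL) {
  genes <- c("g1", "g2", "mt-x")
  counts <- t(vapply(seq_along(totals), function(i) {
    m <- round(totals[i] * mito_frac[i])
    rest <- totals[i] - m
    c(ceiling(rest / 2), floor(rest / 2), m)
  }, numeric(3)))
  rownames(counts) <- sprintf("c%d", seq_along(totals))
  colnames(counts) <- genes
  fiber_counts(counts, condition = condition)
}

# Two well-separated gaussian blobs for clustering tests.
make_blobs <- function(n_per = 60, p = 10, sep = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = sep), n_per, p))
  rownames(x) <- sprintf("b%03d", seq_len(2 * n_per))
  colnames(x) <- sprintf("g%02d", seq_len(p))
  list(x = x, truth = rep(1:2, each = n_per))
}

# Default synthetic dataset processed through QC + normalization, cached
# per session so several test files can share it.
default_processed <- local({
  cache <- NULL
  function(seed = 101) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    sim <- generate_fiber_counts(sim_config(seed = seed))
    qc <- qc_filter(sim$counts)
    expr <- normalize_log_rpm(qc$counts)
    cache <<- list(seed = seed, sim = sim, qc = qc, expr = expr,
                   truth = sim$truth[match(rownames(expr$values),
                                           sim$truth$cell), ])
    cache
  }
})

fa_panel <- c("Myh1", "Myh2", "Myh4", "Myh7", "Myh7b", "Myh11", "Myh3")

truth_to_label <- c(fast = "fast", slow = "slow",
                    hybrid = "double_positive",
                    negative = "double_negative")

# One slow-depletion recovery run: simulate, run the full pipeline, return
# TRUE when the combined slow-typical fraction is lower in the depleted
# condition than in the control.
depletion_direction_recovered <- function(seed, n_per_condition = 300) {
  sim <- generate_fiber_counts(
    sim_config(n_cells_per_condition = n_per_condition, seed = seed))
  ann <- generate_go_annotations(seed = seed)
  res <- suppressWarnings(run_fiber_pipeline(
    sim$counts, ann, config = list(n_factors = 2, pa_reps = 30),
    seed = seed))
  comb <- res$combined
  isTRUE(unname(comb["P_PG"] < comb["Ctrl"]))
}
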