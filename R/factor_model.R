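# Exploratory factor analysis on the z-scored expression of the marker
# panel: KMO sampling adequacy, Horn's parallel analysis for the factor
# count, minres extraction, quartimin (oblimin gamma = 0) rotation by
# gradient projection, and regression (Thurstone) factor scores. The whole
# stack is implemented here; tests check each piece against independent
# oracles (pairwise-regression partials, grid-searched rotations, direct
# matrix formulas).

# Accept either a cells x variables data matrix (z-scored internally) or a
# ready-made correlation matrix (square, symmetric, unit diagonal).
as_corr <- function(x, ridge = 0) {
  x <- as_expr_matrix(x)
  if (nrow(x) == ncol(x) && max(abs(x - t(x))) < 1e-12 &&
      max(abs(diag(x) - 1)) < 1e-12) {
    R <- x
  } else {
    sds <- apply(x, 2, sd)
    if (any(sds == 0))
      fib_stop("fiberfa_value_error", "variable '%s' is constant",
               colnames(x)[which(sds == 0)[1L]])
    R <- cor(x)
  }
  if (ridge > 0) {
    R <- R + diag(ridge, ncol(R))
    R <- stats::cov2cor(R)
  }
  R
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO and per-variable MSA from the anti-image partial
#' correlations: `KMO = sum(r_ij^2) / (sum(r_ij^2) + sum(q_ij^2))` over
#' off-diagonal pairs, where `q` are the partial correlations given all
#' other variables.
#'
#' @param x data matrix (cells x variables) or correlation matrix.
#' @param ridge ridge added to the correlation matrix before inversion;
#'   with the default 0, a singular matrix is an error.
#' @return list with `overall` and per-variable `msa` (both in `[0, 1]`).
#' @export
kmo <- function(x, ridge = 0) {
  R <- as_corr(x, ridge)
  if (ncol(R) < 2L)
    fib_stop("fiberfa_value_error", "KMO needs at least two variables")
  S <- tryCatch(solve(R), error = function(e)
    fib_stop("fiberfa_value_error",
             "correlation matrix is singular; retry with ridge > 0"))
  d <- 1 / sqrt(diag(S))
  Q <- -S * outer(d, d)       # anti-image partial correlations
  diag(Q) <- 0
  r2 <- R^2; diag(r2) <- 0
  q2 <- Q^2
  den <- rowSums(r2) + rowSums(q2)
  # a variable sharing no variance at all has adequacy 0, not 0/0
  msa <- ifelse(den == 0, 0, rowSums(r2) / den)
  names(msa) <- colnames(R)
  overall <- if (sum(r2) + sum(q2) == 0) 0 else
    sum(r2) / (sum(r2) + sum(q2))
  list(overall = overall, msa = msa)
}

#' Horn's parallel analysis for the number of factors
#'
#' Compares the observed correlation-matrix eigenvalues with a quantile of
#' eigenvalues from `n_reps` same-shape standard-normal datasets; the
#' retained count is the number of leading observed eigenvalues above the
#' null quantile (stopping at the first failure). Deterministic given
#' `seed`.
#'
#' @param x data matrix, cells x variables (at least 3 cells).
#' @param n_reps number of null replicates (default 100).
#' @param quantile null quantile compared against (default 0.95).
#' @param seed RNG seed for the null datasets.
#' @return list with `m_retained` and `eigen_table`
#'   (k, lambda_obs, lambda_null).
#' @export
parallel_analysis <- function(x, n_reps = 100, quantile = 0.95, seed = 1L) {
  x <- as_expr_matrix(x)
  if (n_reps < 1) fib_stop("fiberfa_value_error", "n_reps must be >= 1")
  if (nrow(x) < 3L) fib_stop("fiberfa_value_error", "need at least 3 cells")
  p <- ncol(x)
  obs <- eigen(as_corr(x), symmetric = TRUE, only.values = TRUE)$values
  null_eigs <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      z <- matrix(rnorm(nrow(x) * p), nrow(x), p)
      eigen(cor(z), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  thresh <- apply(null_eigs, 1, function(v)
    stats::quantile(v, probs = quantile, names = FALSE))
  above <- obs > thresh
  m <- match(FALSE, above, nomatch = p + 1L) - 1L
  list(m_retained = m,
       eigen_table = data.frame(k = seq_len(p), lambda_obs = obs,
                                lambda_null = thresh))
}

#' Minimum-residual (minres) factor extraction
#'
#' Finds uniquenesses minimizing the sum of squared off-diagonal residuals
#' of `R - Lambda Lambda' - diag(u^2)`; loadings come from the leading
#' eigenvectors of the reduced correlation matrix. Communalities are
#' clipped to `[0, 1]`.
#'
#' @param x data matrix or correlation matrix.
#' @param m number of factors, `1 <= m <` number of variables.
#' @param method `"minres"` (default) or `"pa"` (iterated principal axis).
#' @param max_iter iteration cap for the optimizer.
#' @return list with unrotated `loadings`, `communalities`, `uniquenesses`
#'   and the residual sum of squares `objective`.
#' @export
extract_factors <- function(x, m, method = c("minres", "pa"),
                            max_iter = 1000L) {
  method <- match.arg(method)
  R <- as_corr(x)
  p <- ncol(R)
  if (m < 1) fib_stop("fiberfa_value_error", "m must be >= 1")
  if (m >= p)
    fib_stop("fiberfa_value_error",
             "m = %d factors requires more than %d variables", m, p)
  loadings_from_psi <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(m)], 0)
    e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(lam), m)
  }
  offdiag_rss <- function(L) {
    resid <- R - tcrossprod(L)
    diag(resid) <- 0
    sum(resid^2)
  }
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  smc <- pmin(pmax(smc, 0.05), 0.95)
  if (method == "minres") {
    fit <- optim(1 - smc, function(psi) offdiag_rss(loadings_from_psi(psi)),
                 method = "L-BFGS-B", lower = 1e-7, upper = 1,
                 control = list(maxit = max_iter, factr = 1e4))
    # a line-search abort at a numerically zero residual is convergence
    if (fit$convergence != 0 && fit$value > 1e-8)
      fib_stop("fiberfa_convergence_error",
               "minres did not converge (code %d, residual %.3e): %s",
               fit$convergence, fit$value, fit$message)
    L <- loadings_from_psi(fit$par)
  } else {
    h2 <- smc
    for (i in seq_len(max_iter)) {
      L <- loadings_from_psi(1 - h2)
      h2_new <- pmin(rowSums(L^2), 1)
      if (max(abs(h2_new - h2)) < 1e-9) break
      h2 <- h2_new
    }
  }
  h2 <- pmin(pmax(rowSums(L^2), 0), 1)
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("F", seq_len(m))
  list(loadings = L, communalities = h2, uniquenesses = 1 - h2,
       objective = offdiag_rss(L))
}

#' Quartimin criterion of a loading matrix
#'
#' `Q = sum_i sum_{k != l} lambda_ik^2 lambda_il^2`: the within-variable
#' cross-products of squared loadings that oblique quartimin rotation
#' minimizes.
#'
#' @param L loading matrix (variables x factors).
#' @return scalar criterion value.
#' @export
quartimin_criterion <- function(L) {
  L2 <- L^2
  N <- matrix(1, ncol(L), ncol(L)) - diag(ncol(L))
  sum(L2 * (L2 %*% N))
}

# One gradient-projection run (Jennrich's oblique GPA) from a start Tmat.
# Internal objective is quartimin_criterion / 4, paired with its exact
# gradient, the standard scaling for the GPA step test.
gpa_oblq <- function(A, Tmat, max_iter, tol) {
  vg <- function(L) {
    L2 <- L^2
    N <- matrix(1, ncol(L), ncol(L)) - diag(ncol(L))
    list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
  }
  Ti <- Tmat
  L <- A %*% t(solve(Ti))
  V <- vg(L)
  G <- -t(t(L) %*% V$Gq %*% solve(Ti))
  al <- 1
  s <- Inf
  for (iter in seq_len(max_iter)) {
    Gp <- G - Ti %*% diag(colSums(Ti * G), ncol(Ti))
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    improved <- FALSE
    for (i in 0:25) {
      X <- Ti - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Lt <- A %*% t(solve(Tt))
      Vt <- vg(Lt)
      if (Vt$f < V$f - 0.5 * s^2 * al) {
        improved <- TRUE
        break
      }
      al <- al / 2
    }
    # criterion differences below float precision: a stall this close to
    # stationarity is convergence
    if (!improved) break
    Ti <- Tt; L <- Lt; V <- Vt
    G <- -t(t(L) %*% V$Gq %*% solve(Ti))
  }
  list(loadings = L, Th = Ti, f = V$f, converged = s < max(tol, 1e-5))
}

#' Oblique quartimin rotation by gradient projection
#'
#' Minimizes the quartimin criterion over oblique rotations
#' `Lambda = A (T')^{-1}` with unit-column `T`; the factor correlation is
#' `Phi = T'T`. Several random restarts (seeded, deterministic) guard
#' against local minima; the model fit `Lambda Phi Lambda'` equals the
#' unrotated `A A'` exactly.
#'
#' @param loadings unrotated loading matrix with at least 2 factors.
#' @param n_restarts random restarts in addition to the identity start.
#' @param seed seed for the restart rotations.
#' @param max_iter,tol gradient-projection iteration cap and gradient
#'   tolerance.
#' @return list with rotated `loadings`, factor correlation `Phi`,
#'   rotation matrix `Th` and `criterion`.
#' @export
rotate_quartimin <- function(loadings, n_restarts = 10L, seed = 1L,
                             max_iter = 1000L, tol = 1e-6) {
  A <- as.matrix(loadings)
  m <- ncol(A)
  if (m < 2L)
    fib_stop("fiberfa_value_error", "rotation needs at least 2 factors")
  starts <- c(list(diag(m)), with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      Q <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
      Q %*% diag(1 / sqrt(colSums(Q^2)), m)
    })
  }))
  best <- NULL
  for (Tmat in starts) {
    fit <- gpa_oblq(A, Tmat, max_iter, tol)
    if (!fit$converged) next
    if (is.null(best) || fit$f < best$f) best <- fit
  }
  if (is.null(best))
    fib_stop("fiberfa_convergence_error",
             "quartimin rotation did not converge from any start")
  L <- best$loadings
  dimnames(L) <- dimnames(A)
  Phi <- crossprod(best$Th)
  dimnames(Phi) <- list(colnames(A), colnames(A))
  list(loadings = L, Phi = Phi, Th = best$Th,
       criterion = quartimin_criterion(L))
}

#' Factor scores
#'
#' Regression (Thurstone) scores `F = Z R^{-1} (Lambda Phi)` by default;
#' Bartlett weighted-least-squares scores are available. Variables are
#' z-scored internally; one score column per factor, in factor order.
#'
#' @param x data matrix, cells x panel variables (same variable set the
#'   model was fitted on).
#' @param loadings rotated pattern matrix.
#' @param Phi factor correlation matrix (identity for unrotated models).
#' @param method `"regression"` (default) or `"bartlett"`.
#' @param ridge optional ridge for a singular correlation matrix.
#' @return matrix of factor scores, cells x factors.
#' @export
score_factors <- function(x, loadings, Phi = diag(ncol(loadings)),
                          method = c("regression", "bartlett"), ridge = 0) {
  method <- match.arg(method)
  x <- as_expr_matrix(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    fib_stop("fiberfa_value_error", "variable '%s' is constant",
             colnames(x)[which(sds == 0)[1L]])
  Z <- scale(x)
  L <- as.matrix(loadings)
  if (!is.null(rownames(L)) && !is.null(colnames(Z)))
    Z <- Z[, rownames(L), drop = FALSE]
  if (method == "regression") {
    R <- as_corr(x[, if (is.null(rownames(L))) seq_len(ncol(x)) else
                     rownames(L), drop = FALSE], ridge)
    W <- tryCatch(solve(R, L %*% Phi), error = function(e)
      fib_stop("fiberfa_value_error",
               "correlation matrix is singular; retry with ridge > 0"))
  } else {
    h2 <- pmin(diag(L %*% Phi %*% t(L)), 0.999)
    Uinv <- diag(1 / (1 - h2))
    W <- Uinv %*% L %*% solve(t(L) %*% Uinv %*% L)
  }
  F <- Z %*% W
  colnames(F) <- colnames(L)
  rownames(F) <- rownames(x)
  F
}

#' Map extracted factors to fast and slow fiber types
#'
#' The factor with the largest mean absolute loading over the fast seed
#' genes is labelled "fast", likewise "slow"; an ambiguous mapping (both
#' programs winning the same factor) is an error. Signs record whether the
#' factor loads positively or negatively on its seeds.
#'
#' @param loadings rotated loading matrix with gene rownames.
#' @param seeds_fast,seeds_slow seed gene ids present in the rownames.
#' @return list with `fast`, `slow` (column indices) and `sign_fast`,
#'   `sign_slow`.
#' @export
map_factors_to_fiber_types <- function(loadings, seeds_fast, seeds_slow) {
  L <- as.matrix(loadings)
  for (s in c(seeds_fast, seeds_slow))
    if (!s %in% rownames(L))
      fib_stop("fiberfa_lookup_error", "seed gene '%s' is not in the panel", s)
  mean_fast <- colMeans(L[seeds_fast, , drop = FALSE])
  mean_slow <- colMeans(L[seeds_slow, , drop = FALSE])
  if (max(abs(mean_fast)) < 1e-8 || max(abs(mean_slow)) < 1e-8)
    fib_stop("fiberfa_mapping_error",
             "a seed set has no loading on any factor")
  kf <- which.max(abs(mean_fast))
  ks <- which.max(abs(mean_slow))
  if (kf == ks)
    fib_stop("fiberfa_mapping_error",
             "fast and slow seeds map to the same factor (%d)", kf)
  list(fast = kf, slow = ks,
       sign_fast = sign(mean_fast[kf]), sign_slow = sign(mean_slow[ks]))
}

#' Fit the full fiber-type factor model
#'
#' Z-scores the panel expression, checks sampling adequacy, selects the
#' factor count by parallel analysis (unless given), extracts by minres,
#' applies quartimin rotation, maps factors to fiber types and computes
#' factor scores. Output factors are ordered fast first and sign-aligned
#' so seed genes load positively.
#'
#' @param expr a `fiber_expr` or matrix (cells x genes).
#' @param panel panel gene ids (subset of columns of `expr`).
#' @param seeds_fast,seeds_slow fast / slow seed genes within the panel.
#' @param n_factors `"auto"` (parallel analysis) or an integer.
#' @param pa_reps,pa_quantile parallel-analysis replicates and quantile.
#' @param score_method passed to [score_factors()].
#' @param seed RNG seed for parallel analysis and rotation restarts.
#' @return object of class `fiber_fa`: loadings, Phi, communalities,
#'   uniquenesses, kmo/msa, eigen table, retained `m`, scores (columns
#'   `F_fast`, `F_slow`) and the factor mapping.
#' @export
fit_fiber_factors <- function(expr, panel,
                              seeds_fast = c("Myh1", "Myh2", "Myh4"),
                              seeds_slow = "Myh7",
                              n_factors = "auto", pa_reps = 100,
                              pa_quantile = 0.95,
                              score_method = "regression", seed = 1L) {
  x <- as_expr_matrix(expr)
  missing <- setdiff(panel, colnames(x))
  if (length(missing))
    fib_stop("fiberfa_lookup_error", "panel gene '%s' is absent from expr",
             missing[1L])
  xp <- x[, panel, drop = FALSE]
  adequacy <- kmo(xp)
  pa <- parallel_analysis(xp, n_reps = pa_reps, quantile = pa_quantile,
                          seed = seed)
  m <- if (identical(n_factors, "auto")) pa$m_retained else as.integer(n_factors)
  if (m < 2L)
    fib_stop("fiberfa_value_error",
             "retained %d factor(s); fiber typing needs 2 (set n_factors)", m)
  ext <- extract_factors(xp, m)
  rot <- rotate_quartimin(ext$loadings, seed = seed)
  map <- map_factors_to_fiber_types(rot$loadings, seeds_fast, seeds_slow)
  ord <- c(map$fast, map$slow, setdiff(seq_len(m), c(map$fast, map$slow)))
  sgn <- rep(1, m)
  sgn[map$fast] <- map$sign_fast
  sgn[map$slow] <- map$sign_slow
  L <- sweep(rot$loadings, 2, sgn, `*`)[, ord, drop = FALSE]
  Phi <- diag(sgn) %*% rot$Phi %*% diag(sgn)
  Phi <- Phi[ord, ord, drop = FALSE]
  fac_names <- c("F_fast", "F_slow",
                 if (m > 2) paste0("F", seq_len(m - 2) + 2L))
  colnames(L) <- fac_names
  dimnames(Phi) <- list(fac_names, fac_names)
  scores <- score_factors(xp, L, Phi, method = score_method)
  structure(list(loadings = L, Phi = Phi,
                 communalities = ext$communalities,
                 uniquenesses = ext$uniquenesses,
                 kmo = adequacy$overall, msa = adequacy$msa,
                 eigen_table = pa$eigen_table, m = m,
                 rotation_criterion = rot$criterion,
                 scores = scores,
                 mapping = list(fast = 1L, slow = 2L),
                 panel = panel, seeds_fast = seeds_fast,
                 seeds_slow = seeds_slow, seed = seed),
            class = "fiber_fa")
}

#' @export
print.fiber_fa <- function(x, ...) {
  cat(sprintf("<fiber_fa> %d factors on %d-gene panel, %d cells\n",
              x$m, length(x$panel), nrow(x$scores)))
  cat(sprintf("  KMO = %.3f, quartimin criterion = %.4g\n",
              x$kmo, x$rotation_criterion))
  print(round(x$loadings, 3))
  invisible(x)
}
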