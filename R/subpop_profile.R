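# Subpopulation profiling: graph clustering within the fast and slow
# fiber classes, significantly upregulated genes ("sigups") per cluster,
# grammar-based cluster naming, condition-stratified proportions, combined
# cluster fractions and the atrophy-marker condition check.

#' Cluster a subpopulation by kNN graph + modularity communities
#'
#' Principal components of the subpopulation's expression (up to `n_pcs`)
#' feed a k-nearest-neighbour graph whose communities are found by
#' modularity (Louvain) optimization. Deterministic given `seed`.
#'
#' @param expr a `fiber_expr` or matrix (cells x genes) for the
#'   subpopulation only.
#' @param n_neighbors neighbours per cell; clamped (with a warning) to one
#'   less than the cell count when the subpopulation is small.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed for the community search.
#' @param n_pcs maximum number of principal components (default 30).
#' @return integer cluster labels named by cell, numbered 1..k by
#'   descending cluster size.
#' @export
cluster_subpopulation <- function(expr, n_neighbors = 15L, resolution = 1.0,
                                  seed = 1L, n_pcs = 30L) {
  x <- as_expr_matrix(expr)
  n <- nrow(x)
  if (n < 3L)
    fib_stop("fiberfa_value_error", "clustering needs at least 3 cells")
  if (n_neighbors > n - 1L) {
    fib_warn("n_neighbors = %d clamped to %d for %d cells",
             n_neighbors, n - 1L, n)
    n_neighbors <- n - 1L
  }
  keep <- apply(x, 2, sd) > 0
  pcs <- min(n_pcs, n - 1L, sum(keep))
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = pcs)$x
  D <- as.matrix(dist(pc))
  diag(D) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(n_neighbors)]
    cbind(i, nb)
  }))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comm <- with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  lab <- igraph::membership(comm)
  # renumber by descending size, ties by first appearance
  sizes <- table(lab)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  lab <- match(as.integer(lab), as.integer(names(sizes))[ord])
  names(lab) <- rownames(x)
  lab
}

#' Find significantly upregulated genes (sigups) per cluster
#'
#' One-vs-rest Wilcoxon rank-sum test per gene (alternative "greater"),
#' Benjamini-Hochberg adjusted within each cluster; a cluster's sigups are
#' the genes with adjusted p below `alpha` and log2 fold-change (mean
#' difference on the log2 expression scale) at least `min_lfc`.
#'
#' @param expr a `fiber_expr` or matrix (cells x genes).
#' @param labels cluster labels aligned with rows of `expr` (at least 2
#'   clusters).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_lfc log2 fold-change floor (default 1).
#' @return object of class `fiber_sigups`: `sets` (named list of gene
#'   vectors per cluster) and `stats` (cluster, gene, lfc, p, p_adj).
#' @export
find_sigups <- function(expr, labels, alpha = 0.05, min_lfc = 1.0) {
  x <- as_expr_matrix(expr)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    fib_stop("fiberfa_value_error", "labels length != number of cells")
  cl <- sort(unique(labels))
  if (length(cl) < 2L)
    fib_stop("fiberfa_value_error", "sigup discovery needs >= 2 clusters")
  stats_list <- lapply(cl, function(k) {
    inside <- labels == k
    lfc <- colMeans(x[inside, , drop = FALSE]) -
      colMeans(x[!inside, , drop = FALSE])
    p <- vapply(seq_len(ncol(x)), function(j) {
      xi <- x[inside, j]
      xo <- x[!inside, j]
      if (sd(c(xi, xo)) == 0) return(1)
      suppressWarnings(wilcox.test(xi, xo, alternative = "greater",
                                   exact = FALSE)$p.value)
    }, numeric(1))
    data.frame(cluster = k, gene = colnames(x), lfc = unname(lfc),
               p = p, p_adj = p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, stats_list)
  sets <- lapply(setNames(cl, cl), function(k) {
    s <- stats[stats$cluster == k & stats$p_adj < alpha &
                 stats$lfc >= min_lfc, ]
    s$gene[order(-s$lfc)]
  })
  structure(list(sets = sets, stats = stats), class = "fiber_sigups")
}

#' Name clusters from their sigups
#'
#' Grammar: a cluster with sigups is named after the sigup with the
#' largest fold-change, as `"G+"`; clusters sharing a name (in particular
#' identical sigup sets) are indexed `"G+(1)", "G+(2)"` by descending
#' size; clusters without sigups are `"Unknown"`, indexed likewise.
#'
#' @param sigups a `fiber_sigups`, or a named list of sigup gene vectors
#'   (already ordered by fold-change).
#' @param sizes named integer vector of cluster sizes (same cluster ids).
#' @return data.frame (cluster, name, size, sigups) with unique names, in
#'   descending size order.
#' @export
name_clusters <- function(sigups, sizes) {
  sets <- if (inherits(sigups, "fiber_sigups")) sigups$sets else sigups
  if (!setequal(names(sets), names(sizes)))
    fib_stop("fiberfa_value_error", "sigups and sizes must cover the same clusters")
  cl <- names(sets)[order(-as.numeric(sizes[names(sets)]), names(sets))]
  base <- vapply(cl, function(k)
    if (length(sets[[k]])) paste0(sets[[k]][1L], "+") else "Unknown",
    character(1))
  name <- base
  for (b in unique(base)) {
    idx <- which(base == b)  # already in descending size order
    if (length(idx) > 1L)
      name[idx] <- sprintf("%s(%d)", b, seq_along(idx))
  }
  data.frame(cluster = cl, name = unname(name),
             size = as.integer(sizes[cl]),
             sigups = vapply(sets[cl], paste, character(1), collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally label proportions per condition
#'
#' @param labels per-cell labels (cluster names or class labels).
#' @param conditions per-cell condition labels, same length.
#' @return object of class `fiber_proportions` with `counts` and
#'   `fractions` matrices (condition rows x label columns); conditions
#'   with zero cells are dropped with a warning. Each retained row of
#'   `fractions` sums to 1.
#' @export
condition_proportions <- function(labels, conditions) {
  labels <- as.character(labels)
  if (!is.factor(conditions)) conditions <- factor(as.character(conditions))
  if (length(labels) != length(conditions))
    fib_stop("fiberfa_value_error", "labels and conditions differ in length")
  if (anyNA(conditions))
    fib_stop("fiberfa_value_error", "every cell needs a condition")
  counts <- table(condition = conditions, label = labels)
  counts <- unclass(counts)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    fib_warn("dropping condition(s) with zero cells: %s",
             paste(rownames(counts)[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  fractions <- counts / rowSums(counts)
  structure(list(counts = counts, fractions = fractions),
            class = "fiber_proportions")
}

#' @export
print.fiber_proportions <- function(x, ...) {
  cat("<fiber_proportions>\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Combine named clusters into one per-condition fraction
#'
#' @param table a `fiber_proportions`.
#' @param names cluster names to combine; each must be a column of the
#'   table. An empty set gives 0 per condition.
#' @return named numeric vector: per condition, the summed fraction.
#' @export
combine_clusters <- function(table, names) {
  if (!inherits(table, "fiber_proportions"))
    fib_stop("fiberfa_value_error", "table must be a fiber_proportions")
  missing <- setdiff(names, colnames(table$fractions))
  if (length(missing))
    fib_stop("fiberfa_lookup_error", "unknown cluster name '%s'", missing[1L])
  if (!length(names))
    return(setNames(rep(0, nrow(table$fractions)),
                    rownames(table$fractions)))
  rowSums(table$fractions[, names, drop = FALSE])
}

#' Compare marker expression across conditions
#'
#' For each gene and condition pair: two-sided Wilcoxon rank-sum statistic,
#' BH-adjusted p (across the whole table) and the mean log2-expression
#' difference. Intended for the muscle-atrophy markers Fbxo32 (atrogin-1)
#' and Trim63 (murf-1).
#'
#' @param expr a `fiber_expr` (with conditions) or matrix.
#' @param genes genes to test; absence is an error naming the gene.
#' @param conditions per-cell conditions (taken from `expr` when omitted).
#' @return data.frame (gene, cond_a, cond_b, statistic, p, p_adj,
#'   mean_diff).
#' @export
compare_marker_expression <- function(expr, genes = c("Fbxo32", "Trim63"),
                                      conditions = NULL) {
  x <- as_expr_matrix(expr)
  conditions <- expr_conditions(expr, conditions)
  missing <- setdiff(genes, colnames(x))
  if (length(missing))
    fib_stop("fiberfa_lookup_error", "gene '%s' is not in the matrix",
             missing[1L])
  conds <- unique(conditions)
  pairs <- if (length(conds) < 2L) NULL else utils::combn(conds, 2L)
  if (is.null(pairs))
    fib_stop("fiberfa_value_error", "need at least two conditions")
  rows <- list()
  for (g in genes) {
    for (j in seq_len(ncol(pairs))) {
      a <- x[conditions == pairs[1L, j], g]
      b <- x[conditions == pairs[2L, j], g]
      wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, cond_a = pairs[1L, j], cond_b = pairs[2L, j],
                   statistic = unname(wt$statistic), p = wt$p.value,
                   mean_diff = mean(a) - mean(b), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("gene", "cond_a", "cond_b", "statistic", "p", "p_adj",
          "mean_diff")]
}
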