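# End-to-end orchestration: QC -> log2(RPM+1) -> marker panel -> factor
# model -> four-class fiber typing -> per-subpopulation clustering, sigup
# naming and condition-stratified proportions.

pipeline_defaults <- function() {
  list(count_cutoff = 5000, mito_cutoff = 0.10, count_filter = "ge_removes",
       seeds_fast = c("Myh1", "Myh2", "Myh4"), seeds_slow = "Myh7",
       similar_top_k = 3L, n_factors = "auto", pa_reps = 100,
       pa_quantile = 0.95, score_method = "regression",
       tau_fast = NULL, tau_slow = NULL,
       n_neighbors = 15L, resolution = 1.0,
       sigup_alpha = 0.05, sigup_min_lfc = 1.0,
       combine_names = NULL, atrophy_genes = c("Fbxo32", "Trim63"))
}

#' Run the full fiber-typing pipeline
#'
#' @param counts a [fiber_counts()] with condition labels.
#' @param annotations gene-to-GO-term table (named list), e.g. from
#'   [read_gaf()] or [generate_go_annotations()].
#' @param config named list overriding [pipeline defaults][run_fiber_pipeline]:
#'   QC cutoffs (`count_cutoff`, `mito_cutoff`, `count_filter`), panel
#'   construction (`seeds_fast`, `seeds_slow`, `similar_top_k`), factor
#'   model (`n_factors`, `pa_reps`, `pa_quantile`, `score_method`),
#'   classification (`tau_fast`/`tau_slow` for manual thresholds),
#'   profiling (`n_neighbors`, `resolution`, `sigup_alpha`,
#'   `sigup_min_lfc`, `combine_names`, `atrophy_genes`).
#' @param seed seed for every stochastic stage (parallel analysis,
#'   rotation restarts, community detection).
#' @return object of class `fiber_pipeline` with all stage results, the
#'   output tables written by [write_report()], and a run report
#'   (seeds, configuration echo, thresholds used, per-stage tallies).
#' @export
run_fiber_pipeline <- function(counts, annotations, config = list(),
                               seed = 1L) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  stages <- list()

  qc <- qc_filter(counts, count_cutoff = cfg$count_cutoff,
                  mito_cutoff = cfg$mito_cutoff,
                  count_filter = cfg$count_filter)
  stages$qc <- list(cells_in = length(counts$cells),
                    cells_kept = length(qc$counts$cells),
                    genes = length(counts$genes))
  expr <- normalize_log_rpm(qc$counts)

  seeds <- c(cfg$seeds_fast, cfg$seeds_slow)
  ranking <- rank_similar_genes(seeds, annotations)
  panel <- select_feature_panel(seeds, ranking, top_k = cfg$similar_top_k)
  absent <- setdiff(panel, expr$genes)
  if (length(absent)) {
    fib_warn("dropping panel gene(s) absent from the matrix: %s",
             paste(absent, collapse = ", "))
    panel <- setdiff(panel, absent)
  }
  stages$panel <- list(n_seeds = length(seeds), n_panel = length(panel))

  fa <- fit_fiber_factors(expr, panel, seeds_fast = cfg$seeds_fast,
                          seeds_slow = cfg$seeds_slow,
                          n_factors = cfg$n_factors, pa_reps = cfg$pa_reps,
                          pa_quantile = cfg$pa_quantile,
                          score_method = cfg$score_method, seed = seed)
  stages$factors <- list(m = fa$m, kmo = fa$kmo)

  thresholds <- if (!is.null(cfg$tau_fast) && !is.null(cfg$tau_slow))
    fiber_thresholds(cfg$tau_fast, cfg$tau_slow, provenance = "manual")
  else propose_thresholds(fa$scores)
  classes <- classify_cells(fa$scores, thresholds)
  stages$classify <- as.list(table(classes$label))

  merged <- as.character(classes$label)
  names(merged) <- names(classes$label)
  subpops <- list()
  cluster_rows <- list()
  sigup_rows <- list()
  for (sp in c("fast", "slow")) {
    cells <- names(classes$label)[classes$label == sp]
    if (length(cells) < 3L) {
      fib_warn("subpopulation '%s' has %d cell(s); skipping clustering",
               sp, length(cells))
      next
    }
    sub_expr <- expr$values[cells, , drop = FALSE]
    lab <- cluster_subpopulation(sub_expr, n_neighbors = cfg$n_neighbors,
                                 resolution = cfg$resolution, seed = seed)
    sizes <- table(lab)
    if (length(sizes) >= 2L) {
      sig <- find_sigups(sub_expr, lab, alpha = cfg$sigup_alpha,
                         min_lfc = cfg$sigup_min_lfc)
      sets <- sig$sets
      sig_stats <- sig$stats
    } else {
      sets <- setNames(list(character()), names(sizes))
      sig_stats <- NULL
    }
    ann <- name_clusters(sets, sizes)
    display <- setNames(paste0(sp, ":", ann$name), ann$cluster)
    merged[cells] <- display[as.character(lab)]
    subpops[[sp]] <- list(labels = lab, annotation = ann, sigups = sets)
    cluster_rows[[sp]] <- data.frame(cell = cells, subpopulation = sp,
                                     cluster = as.integer(lab),
                                     name = unname(display[as.character(lab)]),
                                     stringsAsFactors = FALSE)
    if (!is.null(sig_stats)) {
      keep <- mapply(function(cl, g) g %in% sets[[cl]],
                     sig_stats$cluster, sig_stats$gene)
      s <- sig_stats[keep, , drop = FALSE]
      if (nrow(s))
        sigup_rows[[sp]] <- data.frame(
          cluster = unname(display[as.character(s$cluster)]), gene = s$gene,
          lfc = s$lfc, p_adj = s$p_adj, stringsAsFactors = FALSE)
    }
  }
  empty_sig <- data.frame(cluster = character(), gene = character(),
                          lfc = numeric(), p_adj = numeric())
  cluster_table <- if (length(cluster_rows))
    do.call(rbind, c(cluster_rows, list(make.row.names = FALSE)))
  else data.frame(cell = character(), subpopulation = character(),
                  cluster = integer(), name = character())
  sigup_table <- if (length(sigup_rows))
    do.call(rbind, c(sigup_rows, list(make.row.names = FALSE)))
  else empty_sig

  proportions <- condition_proportions(merged, expr$condition)
  class_proportions <- condition_proportions(as.character(classes$label),
                                             expr$condition)
  combine_names <- cfg$combine_names
  if (is.null(combine_names) && !is.null(subpops$slow))
    combine_names <- paste0("slow:", subpops$slow$annotation$name)
  combined <- if (is.null(combine_names)) NULL
              else combine_clusters(proportions, combine_names)

  markers <- NULL
  mk <- intersect(cfg$atrophy_genes, expr$genes)
  if (length(mk) && length(unique(expr$condition)) >= 2L)
    markers <- compare_marker_expression(expr, genes = mk)

  prop_long <- as.data.frame(as.table(proportions$counts),
                             stringsAsFactors = FALSE)
  names(prop_long) <- c("condition", "cluster", "count")
  prop_long$fraction <- as.vector(proportions$fractions)

  report <- list(seed = seed, config = cfg, stages = stages)
  structure(list(qc = qc$qc, expr = expr, ranking = ranking, panel = panel,
                 factors = fa, classes = classes, subpops = subpops,
                 merged_labels = merged, proportions = proportions,
                 class_proportions = class_proportions,
                 combined = combined, combine_names = combine_names,
                 markers = markers, cluster_table = cluster_table,
                 sigup_table = sigup_table, proportion_table = prop_long,
                 report = report),
            class = "fiber_pipeline")
}

#' @export
print.fiber_pipeline <- function(x, ...) {
  cat("<fiber_pipeline>\n")
  cat(sprintf("  QC: %d / %d cells kept\n", x$report$stages$qc$cells_kept,
              x$report$stages$qc$cells_in))
  cat(sprintf("  panel (%d genes): %s\n", length(x$panel),
              paste(x$panel, collapse = ", ")))
  cat(sprintf("  factors: m = %d, KMO = %.3f\n", x$factors$m, x$factors$kmo))
  cat(sprintf("  thresholds: tau_fast = %.3f, tau_slow = %.3f (%s)\n",
              x$classes$thresholds$tau_fast, x$classes$thresholds$tau_slow,
              x$classes$thresholds$provenance))
  cat("  classes:\n")
  print(table(x$classes$label))
  if (!is.null(x$combined)) {
    cat(sprintf("  combined slow-typical fraction (%s):\n",
                paste(x$combine_names, collapse = " + ")))
    print(round(x$combined, 4))
  }
  invisible(x)
}
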