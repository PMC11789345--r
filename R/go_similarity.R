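# Marker-panel construction: seed markers plus genes similar to them by
# Jaccard index over GO annotation sets.

#' Jaccard index of two sets
#'
#' @param set_a,set_b non-empty vectors treated as sets.
#' @return `|A intersect B| / |A union B|`, in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  if (!length(set_a) || !length(set_b))
    fib_stop("fiberfa_value_error", "jaccard is undefined for empty sets")
  a <- unique(set_a)
  b <- unique(set_b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Rank genes by GO-annotation similarity to a seed set
#'
#' Every non-seed gene in the annotation table is scored by the aggregate
#' (max or mean) of its pairwise Jaccard indices against the seeds, then
#' sorted by descending score with lexicographic tie-break, giving a total
#' order stable across runs.
#'
#' @param seeds seed gene ids; each must appear in `table`.
#' @param table named list mapping gene ids to GO term sets (e.g. from
#'   [read_gaf()] or [generate_go_annotations()]).
#' @param aggregate `"max"` (default: similar to any seed counts) or
#'   `"mean"`.
#' @return data.frame (gene, score), seeds excluded, sorted as described.
#' @export
rank_similar_genes <- function(seeds, table, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  missing <- setdiff(seeds, names(table))
  if (length(missing))
    fib_stop("fiberfa_lookup_error",
             "seed gene '%s' is absent from the annotation table", missing[1L])
  others <- setdiff(names(table), seeds)
  agg <- if (aggregate == "max") max else mean
  score <- vapply(others, function(g)
    agg(vapply(seeds, function(s) jaccard(table[[g]], table[[s]]),
               numeric(1))), numeric(1))
  ord <- order(-score, others)
  data.frame(gene = others[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Select the factor-analysis feature panel
#'
#' The panel is the seed genes followed by similar genes taken from the
#' ranking, either the top `top_k` or all genes with score at least
#' `min_score` (exactly one of the two must be given).
#'
#' @param seeds seed gene ids.
#' @param ranking data.frame from [rank_similar_genes()].
#' @param top_k number of top-ranked similar genes to add.
#' @param min_score minimum similarity score for inclusion.
#' @return character vector: seeds then selected genes, duplicate-free.
#' @export
select_feature_panel <- function(seeds, ranking, top_k = NULL,
                                 min_score = NULL) {
  if (is.null(top_k) == is.null(min_score))
    fib_stop("fiberfa_config_error",
             "give exactly one of top_k / min_score")
  if (!is.null(top_k)) {
    if (top_k > nrow(ranking)) {
      fib_warn("top_k = %d exceeds the %d available genes; truncating",
               top_k, nrow(ranking))
      top_k <- nrow(ranking)
    }
    picked <- head(ranking$gene, top_k)
  } else {
    picked <- ranking$gene[ranking$score >= min_score]
  }
  unique(c(seeds, picked))
}
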