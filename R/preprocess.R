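# Quality filtering and normalization.
#
# The QC rule removes cells with >= 5000 total counts or a mitochondrial
# count share >= 10% (both boundaries inclusive on the removal side), plus
# zero-total cells; retained counts are converted to log2(RPM + 1), where
# RPM scales each cell's counts to a library of 10^6.

#' Quality-control filter on total counts and mitochondrial fraction
#'
#' @param counts a [fiber_counts()]; its `mito_mask` defines mitochondrial
#'   genes.
#' @param count_cutoff total-count cutoff (default 5000).
#' @param mito_cutoff mitochondrial-fraction cutoff (default 0.10).
#' @param count_filter `"ge_removes"` (default) removes cells at or above
#'   `count_cutoff`; `"lt_removes"` removes cells below it, for reanalyses
#'   that prefer a lower bound.
#' @return list with `counts` (filtered, gene axis unchanged) and `qc`, a
#'   per-cell data.frame (cell, total, mito_frac, kept, reason).
#' @export
qc_filter <- function(counts, count_cutoff = 5000, mito_cutoff = 0.10,
                      count_filter = c("ge_removes", "lt_removes")) {
  if (!inherits(counts, "fiber_counts"))
    fib_stop("fiberfa_value_error", "counts must be a fiber_counts")
  count_filter <- match.arg(count_filter)
  total <- rowSums(counts$counts)
  mito <- if (any(counts$mito_mask))
    rowSums(counts$counts[, counts$mito_mask, drop = FALSE]) else
    rep(0, length(total))
  mito_frac <- ifelse(total > 0, mito / total, 0)
  bad_count <- if (count_filter == "ge_removes") total >= count_cutoff
               else total < count_cutoff
  bad_mito <- mito_frac >= mito_cutoff
  zero <- total == 0
  kept <- !(bad_count | bad_mito | zero)
  reason <- rep("", length(total))
  reason[bad_mito] <- "mito_fraction"
  reason[bad_count] <- "count_cutoff"     # count rule reported first
  reason[zero] <- "zero_total"
  qc <- data.frame(cell = counts$cells, total = total,
                   mito_frac = mito_frac, kept = kept, reason = reason,
                   stringsAsFactors = FALSE)
  if (length(kept) && !any(kept))
    fib_stop("fiberfa_value_error",
             "QC removed every cell; review count_cutoff/mito_cutoff")
  filtered <- fiber_counts(counts$counts[kept, , drop = FALSE],
                           cells = counts$cells[kept], genes = counts$genes,
                           condition = if (is.null(counts$condition)) NULL
                                       else counts$condition[kept],
                           mito_mask = counts$mito_mask)
  list(counts = filtered, qc = qc)
}

#' Convert counts to log2(RPM + 1)
#'
#' `RPM = counts / per-cell total * 10^6`; the per-cell total runs over all
#' genes present after QC (library-size concept), before any panel
#' subsetting. Zero counts map to 0 exactly, and the transform is invariant
#' to per-cell scaling of counts.
#'
#' @param counts a [fiber_counts()] with every cell total positive.
#' @return a `fiber_expr` carrying the transformed matrix and the per-cell
#'   condition labels.
#' @export
normalize_log_rpm <- function(counts) {
  if (!inherits(counts, "fiber_counts"))
    fib_stop("fiberfa_value_error", "counts must be a fiber_counts")
  total <- rowSums(counts$counts)
  if (any(total == 0))
    fib_stop("fiberfa_contract_error",
             "zero-total cell '%s' reached normalization; run qc_filter first",
             counts$cells[which(total == 0)[1L]])
  v <- log2(counts$counts / total * 1e6 + 1)
  new_fiber_expr(v, condition = counts$condition)
}
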