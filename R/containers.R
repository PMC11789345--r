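# Core containers. Cells are rows, genes are columns throughout: the
# row-per-observation orientation used for all downstream statistics,
# regardless of the genes-by-cells convention of on-disk Matrix Market files.

#' Construct a count-matrix container
#'
#' Holds an integer gene-by-cell count matrix (stored cells x genes), the
#' mitochondrial gene mask used by quality control, and a per-cell condition
#' label.
#'
#' @param counts integer matrix, cells in rows, genes in columns. Dimnames
#'   are taken as cell/gene identifiers when `cells`/`genes` are missing.
#' @param cells,genes character vectors of unique identifiers.
#' @param condition per-cell condition labels (factor or character).
#' @param mito_mask logical per gene; defaults to a case-insensitive
#'   `"mt-"` prefix match on gene identifiers (mouse convention).
#' @return An object of class `fiber_counts`.
#' @export
fiber_counts <- function(counts, cells = rownames(counts),
                         genes = colnames(counts), condition = NULL,
                         mito_mask = NULL) {
  counts <- as.matrix(counts)
  if (is.null(cells) || is.null(genes))
    fib_stop("fiberfa_format_error", "cell and gene identifiers are required")
  cells <- as.character(cells)
  genes <- as.character(genes)
  if (nrow(counts) != length(cells) || ncol(counts) != length(genes))
    fib_stop("fiberfa_format_error",
             "count matrix is %d x %d but %d cells / %d genes were given",
             nrow(counts), ncol(counts), length(cells), length(genes))
  if (anyDuplicated(cells))
    fib_stop("fiberfa_format_error", "duplicate cell id: '%s'",
             cells[duplicated(cells)][1L])
  if (anyDuplicated(genes))
    fib_stop("fiberfa_format_error", "duplicate gene id: '%s'",
             genes[duplicated(genes)][1L])
  if (length(counts) && !is_count_like(counts)) {
    bad <- which(counts < 0 | abs(counts - round(counts)) >= 1e-8,
                 arr.ind = TRUE)[1L, , drop = TRUE]
    fib_stop("fiberfa_format_error",
             "non-integer or negative count at cell '%s', gene '%s'",
             cells[bad[1L]], genes[bad[2L]])
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  dimnames(counts) <- list(cells, genes)
  if (is.null(mito_mask)) mito_mask <- grepl("^mt-", genes, ignore.case = TRUE)
  if (length(mito_mask) != length(genes))
    fib_stop("fiberfa_format_error", "mito_mask length != number of genes")
  if (!is.null(condition)) {
    if (length(condition) != length(cells))
      fib_stop("fiberfa_format_error", "condition length != number of cells")
    condition <- as.character(condition)
  }
  structure(list(counts = counts, cells = cells, genes = genes,
                 condition = condition, mito_mask = as.logical(mito_mask)),
            class = "fiber_counts")
}

#' @export
print.fiber_counts <- function(x, ...) {
  cat(sprintf("<fiber_counts> %d cells x %d genes (%d mitochondrial)\n",
              length(x$cells), length(x$genes), sum(x$mito_mask)))
  if (!is.null(x$condition)) {
    tab <- table(x$condition)
    cat("  conditions:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.fiber_counts <- function(x) dim(x$counts)

new_fiber_expr <- function(values, condition = NULL) {
  structure(list(values = values, cells = rownames(values),
                 genes = colnames(values), condition = condition),
            class = "fiber_expr")
}

#' @export
print.fiber_expr <- function(x, ...) {
  cat(sprintf("<fiber_expr> log2(RPM + 1), %d cells x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.fiber_expr <- function(x) dim(x$values)

# Coerce a fiber_expr / matrix argument to a plain cells x genes matrix.
as_expr_matrix <- function(x) {
  if (inherits(x, "fiber_expr")) return(x$values)
  if (is.matrix(x)) return(x)
  fib_stop("fiberfa_value_error", "expected a fiber_expr or a matrix")
}

expr_conditions <- function(x, conditions = NULL) {
  if (!is.null(conditions)) return(as.character(conditions))
  if (inherits(x, "fiber_expr") && !is.null(x$condition))
    return(as.character(x$condition))
  fib_stop("fiberfa_value_error", "per-cell condition labels are required")
}
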