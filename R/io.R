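# Readers and writers for the standard formats the pipeline touches, the
# TOML configuration reader, and the machine-readable run report.

#' Read a Matrix Market triplet count matrix with sidecar TSVs
#'
#' On-disk layout follows the community convention: the MTX file is genes x
#' cells with 1-based indices; `features.tsv` and `barcodes.tsv` carry one
#' gene / cell id per line; `meta.tsv` is a two-column table (cell,
#' condition). Internally the matrix is re-oriented cells x genes.
#'
#' @param mtx_path,features_path,barcodes_path paths to the matrix and id
#'   files.
#' @param meta_path optional path to the per-cell metadata TSV with columns
#'   `cell` and `condition`. Condition labels are taken only from here,
#'   never parsed out of barcodes.
#' @param mito_genes optional explicit character vector of mitochondrial
#'   gene ids; default is the case-insensitive `"mt-"` prefix rule.
#' @return a [fiber_counts()].
#' @export
read_mtx_triplet <- function(mtx_path, features_path, barcodes_path,
                             meta_path = NULL, mito_genes = NULL) {
  for (p in c(mtx_path, features_path, barcodes_path, meta_path))
    if (!file.exists(p))
      fib_stop("fiberfa_io_error", "file not found: '%s'", p)
  m <- tryCatch(Matrix::readMM(mtx_path), error = function(e)
    fib_stop("fiberfa_format_error", "cannot parse MTX '%s': %s",
             mtx_path, conditionMessage(e)))
  genes <- readLines(features_path)
  cells <- readLines(barcodes_path)
  genes <- sub("\t.*$", "", genes)  # tolerate extra feature columns
  cells <- sub("\t.*$", "", cells)
  if (nrow(m) != length(genes))
    fib_stop("fiberfa_format_error",
             "MTX header declares %d genes but features.tsv has %d lines",
             nrow(m), length(genes))
  if (ncol(m) != length(cells))
    fib_stop("fiberfa_format_error",
             "MTX header declares %d cells but barcodes.tsv has %d lines",
             ncol(m), length(cells))
  mat <- t(as.matrix(m))  # internal orientation: cells x genes
  condition <- NULL
  if (!is.null(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    if (!all(c("cell", "condition") %in% names(meta)))
      fib_stop("fiberfa_format_error",
               "meta.tsv must have columns 'cell' and 'condition'")
    idx <- match(cells, meta$cell)
    if (anyNA(idx))
      fib_stop("fiberfa_format_error", "meta.tsv is missing cell '%s'",
               cells[which(is.na(idx))[1L]])
    condition <- meta$condition[idx]
  }
  mito_mask <- if (is.null(mito_genes)) NULL else genes %in% mito_genes
  fiber_counts(mat, cells = cells, genes = genes, condition = condition,
               mito_mask = mito_mask)
}

#' Read GO annotations from a GAF 2.2 file or a two-column TSV
#'
#' GAF lines use the gene symbol (column 3) and GO id (column 5); comment
#' lines starting with `!` are skipped. A plain two-column file is read as
#' (gene, GO id) pairs. Duplicate (gene, term) pairs collapse.
#'
#' @param path input file.
#' @return named list mapping gene symbol to a character vector of GO ids.
#' @export
read_gaf <- function(path) {
  if (!file.exists(path))
    fib_stop("fiberfa_io_error", "file not found: '%s'", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  if (!any(keep)) {
    fib_warn("'%s' contains no annotation records", path)
    return(list())
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  nf <- lengths(fields)
  pairs <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) == 2L) return(c(f[1L], f[2L]))
    if (length(f) >= 15L) return(c(f[3L], f[5L]))
    fib_stop("fiberfa_format_error",
             "line %d of '%s' has %d columns (expected 2 or >= 15)",
             lineno[i], path, length(f))
  }, character(2))
  genes <- pairs[1L, ]
  terms <- pairs[2L, ]
  ok <- nzchar(genes) & nzchar(terms)
  gf <- factor(genes[ok], levels = unique(genes[ok]))
  lapply(split(terms[ok], gf), unique)
}

#' Write a GO annotation table as a minimal GAF 2.2 file
#'
#' @param annotations named list of GO id vectors, as from
#'   [generate_go_annotations()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gaf <- function(annotations, path) {
  rows <- unlist(lapply(names(annotations), function(g) {
    vapply(annotations[[g]], function(tm)
      paste(c("FIB", g, g, "", tm, "FIB:ref", "IEA", "", "P", "", "",
              "protein", "taxon:10090", "20260101", "FIB", "", ""),
            collapse = "\t"), character(1))
  }), use.names = FALSE)
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

# ---- minimal TOML subset --------------------------------------------------
# Supports [section] / [a.b] headers, key = value with strings, numbers,
# booleans and flat arrays, and '#' comments. Written in-package because no
# TOML parser is available among the installed R packages.

toml_scalar <- function(tok) {
  tok <- trimws(tok)
  if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
  if (grepl("^'.*'$", tok)) return(gsub("^'|'$", "", tok))
  if (tok %in% c("true", "false")) return(tok == "true")
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num)) return(num)
  fib_stop("fiberfa_format_error", "cannot parse TOML value '%s'", tok)
}

#' Read a configuration file in a TOML subset
#'
#' Handles `[section]` (and dotted `[a.b]`) tables, scalar and flat-array
#' values, and `#` comments — the subset the pipeline's configuration uses.
#'
#' @param path TOML file path.
#' @return nested named list.
#' @export
read_toml_config <- function(path) {
  if (!file.exists(path))
    fib_stop("fiberfa_io_error", "file not found: '%s'", path)
  out <- list()
  section <- character()
  for (raw in readLines(path)) {
    line <- sub('#(?=(?:[^"]*"[^"]*")*[^"]*$).*', "", raw, perl = TRUE)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- strsplit(gsub("^\\[|\\]$", "", line), ".", fixed = TRUE)[[1L]]
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0)
      fib_stop("fiberfa_format_error", "TOML line without '=': '%s'", raw)
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      inner <- trimws(gsub("^\\[|\\]$", "", val))
      if (!nzchar(inner)) list()
      else {
        toks <- strsplit(inner, ",(?=(?:[^\"]*\"[^\"]*\")*[^\"]*$)",
                         perl = TRUE)[[1L]]
        vals <- lapply(toks, toml_scalar)
        if (length(unique(vapply(vals, class, character(1)))) == 1L)
          unlist(vals) else vals
      }
    } else toml_scalar(val)
    out <- assign_nested(out, c(section, key), parsed)
  }
  out
}

assign_nested <- function(lst, path, value) {
  if (length(path) == 1L) {
    lst[[path]] <- value
    return(lst)
  }
  head_key <- path[[1L]]
  if (is.null(lst[[head_key]])) lst[[head_key]] <- list()
  lst[[head_key]] <- assign_nested(lst[[head_key]], path[-1L], value)
  lst
}

# ---- run report -----------------------------------------------------------

#' Write pipeline results and the machine-readable run report
#'
#' Writes `loadings.tsv`, `scores.tsv`, `classes.tsv`, `clusters.tsv`,
#' `sigups.tsv`, `proportions.tsv` and `report.json` (seeds, configuration
#' echo, thresholds actually used, per-stage tallies, package version) to
#' `out_dir`, creating it if needed. A rerun with the same configuration
#' and seed is byte-identical.
#'
#' @param results a `fiber_pipeline` object from [run_fiber_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the file manifest (named character vector of paths).
#' @export
write_report <- function(results, out_dir) {
  if (!inherits(results, "fiber_pipeline"))
    fib_stop("fiberfa_value_error", "results must be a fiber_pipeline object")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    fib_stop("fiberfa_io_error", "cannot create output directory '%s'", out_dir)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  fa <- results$factors
  loadings <- data.frame(gene = rownames(fa$loadings),
                         round(fa$loadings, 10),
                         h2 = round(fa$communalities, 10),
                         u2 = round(fa$uniquenesses, 10),
                         msa = round(fa$msa[rownames(fa$loadings)], 10))
  scores <- data.frame(cell = rownames(fa$scores), round(fa$scores, 10))
  classes <- data.frame(cell = names(results$classes$label),
                        round(fa$scores, 10),
                        label = as.character(results$classes$label))
  clusters <- results$cluster_table
  sigups <- results$sigup_table
  prop <- results$proportion_table
  manifest <- c(loadings = tsv(loadings, "loadings.tsv"),
                scores = tsv(scores, "scores.tsv"),
                classes = tsv(classes, "classes.tsv"),
                clusters = tsv(clusters, "clusters.tsv"),
                sigups = tsv(sigups, "sigups.tsv"),
                proportions = tsv(prop, "proportions.tsv"))
  report <- list(package_version = as.character(packageVersion("fiberfa")),
                 seed = results$report$seed,
                 config = results$report$config,
                 thresholds = list(tau_fast = results$classes$thresholds$tau_fast,
                                   tau_slow = results$classes$thresholds$tau_slow,
                                   provenance = results$classes$thresholds$provenance),
                 stages = results$report$stages)
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- c(manifest, report = rp)
  invisible(manifest)
}
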