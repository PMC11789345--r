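# Synthetic fixed-cell scRNA-seq generator with ground truth.
#
# Emulates the statistical structure the downstream analysis assumes: two
# myosin expression programs (fast / slow twitch), hybrid cells carrying
# both, non-myofiber cells carrying neither, dedicated mitochondrial genes
# whose per-cell share drives the QC rule, log-normal library sizes, and a
# configurable depletion of the slow class in diseased conditions.

#' Default gene panel for the synthetic generator
#'
#' Genes are grouped by role: `fast` and `slow` program genes, `neutral`
#' myosins (annotated near the seeds but not part of either program),
#' muscle `atrophy` markers with no condition effect, mitochondrial genes
#' (`mt-` prefix) and moderately expressed `filler` housekeeping genes.
#'
#' @param n_filler number of filler genes.
#' @return named list of character vectors, one per role.
#' @export
default_gene_panel <- function(n_filler = 60L) {
  list(fast    = c("Myh1", "Myh2", "Myh4", "Ckm", "Pygm", "Ttn", "Mybph"),
       slow    = c("Myh7", "Myh7b"),
       neutral = c("Myh11", "Myh3"),
       atrophy = c("Fbxo32", "Trim63"),
       mito    = paste0("mt-", c("Nd1", "Nd2", "Co1", "Cytb", "Atp6")),
       filler  = sprintf("Flr%03d", seq_len(n_filler)))
}

#' Simulation configuration
#'
#' @param n_cells_per_condition cells generated per condition. The default
#'   (667 x 3 conditions, about 2000 cells) gives comfortable power for
#'   factor-model and classifier recovery checks.
#' @param conditions ordered condition labels; analogues of a control and
#'   two disease severities.
#' @param class_mix named probabilities over the four true classes
#'   `fast`, `slow`, `hybrid`, `negative`; either one vector shared by all
#'   conditions or a list with one vector per condition. Renormalized to
#'   sum to 1.
#' @param slow_depletion multiplicative factor in (0, 1] applied to the
#'   slow-class probability in `depleted_conditions` (before
#'   renormalization); models the loss of slow-typical fibers.
#' @param depleted_conditions conditions whose slow class is depleted.
#' @param gene_panel list of gene roles as in [default_gene_panel()].
#' @param program_mean_lfc log2 elevation of program genes in cells of
#'   their class (default 4). Elevation multiplies the gene's expected
#'   count directly (no library renormalization), so the fast/negative
#'   mean-count ratio of program genes equals `2^program_mean_lfc` by
#'   construction; cells expressing a program carry correspondingly more
#'   RNA.
#' @param nb_dispersion negative-binomial dispersion; per-gene count
#'   variance is `mu + nb_dispersion * mu^2` (default 0.5).
#' @param mito_frac_mean,mito_frac_sd mean/sd of the per-cell mitochondrial
#'   fraction (normal, truncated to `[0.002, 0.07]` for non-outliers, so
#'   count noise cannot push a regular cell over the 10% QC line).
#' @param libsize_meanlog,libsize_sdlog log-normal parameters of the
#'   expected non-mitochondrial total of a program-negative cell.
#' @param outlier_frac fraction of cells planted as QC outliers (expected
#'   total above the 5000-count cutoff, or mitochondrial fraction above
#'   10%), so the filtering rule is exercised.
#' @param program_baseline,background_weight relative expression weight of
#'   a program gene at rest (scalar, or named vector with `fast` and
#'   `slow` entries) and of a non-program (neutral, atrophy, filler)
#'   gene. The defaults put a resting program gene at a few counts per
#'   cell; the slow program rests a little higher, which keeps its
#'   two-gene factor well conditioned.
#' @param seed master seed; all randomness flows from it through a per-cell
#'   counter-based substream.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_condition = 667L,
                       conditions = c("Ctrl", "P", "P_PG"),
                       class_mix = c(fast = 0.5, slow = 0.2,
                                     hybrid = 0.1, negative = 0.2),
                       slow_depletion = 0.5,
                       depleted_conditions = "P_PG",
                       gene_panel = default_gene_panel(),
                       program_mean_lfc = 4,
                       nb_dispersion = 0.5,
                       mito_frac_mean = 0.04,
                       mito_frac_sd = 0.01,
                       libsize_meanlog = log(1100),
                       libsize_sdlog = 0.3,
                       outlier_frac = 0.1,
                       program_baseline = c(fast = 1, slow = 3),
                       background_weight = 4,
                       seed = 1L) {
  if (!is.numeric(n_cells_per_condition) || n_cells_per_condition < 0)
    fib_stop("fiberfa_config_error", "n_cells_per_condition must be >= 0")
  conditions <- as.character(conditions)
  if (!length(conditions) || anyDuplicated(conditions))
    fib_stop("fiberfa_config_error", "conditions must be unique and non-empty")
  classes <- c("fast", "slow", "hybrid", "negative")
  if (!is.list(class_mix)) {
    class_mix <- rep(list(class_mix), length(conditions))
    names(class_mix) <- conditions
  }
  if (!setequal(names(class_mix), conditions))
    fib_stop("fiberfa_config_error", "class_mix must cover every condition")
  class_mix <- lapply(class_mix[conditions], function(p) {
    if (!all(classes %in% names(p)))
      fib_stop("fiberfa_config_error",
               "class_mix needs probabilities for %s",
               paste(classes, collapse = ", "))
    p <- p[classes]
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1) || sum(p) <= 0)
      fib_stop("fiberfa_config_error",
               "class_mix probabilities must lie in [0, 1] and sum > 0")
    p / sum(p)
  })
  if (!is.numeric(slow_depletion) || slow_depletion <= 0 || slow_depletion > 1)
    fib_stop("fiberfa_config_error", "slow_depletion must lie in (0, 1]")
  if (!all(depleted_conditions %in% conditions))
    fib_stop("fiberfa_config_error",
             "depleted_conditions must be a subset of conditions")
  genes <- unlist(gene_panel, use.names = FALSE)
  if (!length(genes))
    fib_stop("fiberfa_config_error", "gene_panel is empty")
  if (anyDuplicated(genes))
    fib_stop("fiberfa_config_error", "gene_panel ids must be unique ('%s')",
             genes[duplicated(genes)][1L])
  for (nm in c("program_mean_lfc", "nb_dispersion", "mito_frac_mean",
               "mito_frac_sd", "libsize_meanlog", "libsize_sdlog",
               "outlier_frac", "background_weight"))
    stopifnot_scalar_number(get(nm), nm)
  if (length(program_baseline) == 1L && is.null(names(program_baseline)))
    program_baseline <- c(fast = unname(program_baseline),
                          slow = unname(program_baseline))
  if (!all(c("fast", "slow") %in% names(program_baseline)) ||
      any(!is.finite(program_baseline)) || any(program_baseline <= 0))
    fib_stop("fiberfa_config_error",
             "program_baseline needs positive 'fast' and 'slow' entries")
  if (outlier_frac < 0 || outlier_frac > 1)
    fib_stop("fiberfa_config_error", "outlier_frac must lie in [0, 1]")
  if (nb_dispersion < 0)
    fib_stop("fiberfa_config_error", "nb_dispersion must be >= 0")
  structure(list(n_cells_per_condition = as.integer(n_cells_per_condition),
                 conditions = conditions, class_mix = class_mix,
                 slow_depletion = slow_depletion,
                 depleted_conditions = depleted_conditions,
                 gene_panel = gene_panel,
                 program_mean_lfc = program_mean_lfc,
                 nb_dispersion = nb_dispersion,
                 mito_frac_mean = mito_frac_mean,
                 mito_frac_sd = mito_frac_sd,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 outlier_frac = outlier_frac,
                 program_baseline = program_baseline,
                 background_weight = background_weight,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Effective per-condition class probabilities after slow depletion.
effective_class_mix <- function(config) {
  lapply(setNames(config$conditions, config$conditions), function(cond) {
    p <- config$class_mix[[cond]]
    if (cond %in% config$depleted_conditions)
      p["slow"] <- p["slow"] * config$slow_depletion
    p / sum(p)
  })
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion == 0) return(stats::rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Generate a synthetic fiber-type count matrix with ground truth
#'
#' Each cell draws a true class from its condition's class mix; program
#' genes of that class are elevated `2^program_mean_lfc`-fold over their
#' resting weight; hybrid cells carry both programs, negative cells
#' neither. Counts are gamma-Poisson (negative binomial) around
#' library-size-scaled means, with the mitochondrial share of each cell's
#' library set by a truncated-normal fraction. A configurable fraction of
#' cells is planted as QC outliers. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [fiber_counts()]) and `truth`, a
#'   data.frame with one row per cell: condition, true class, true program
#'   intensities and the planted QC-outlier flag.
#' @export
generate_fiber_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    fib_stop("fiberfa_config_error", "config must be a sim_config")
  panel <- config$gene_panel
  genes <- unlist(panel, use.names = FALSE)
  roles <- rep(names(panel), lengths(panel))
  is_mito <- roles == "mito"
  n_mito <- sum(is_mito)
  pb <- config$program_baseline
  base_w <- ifelse(roles == "fast", pb[["fast"]],
                   ifelse(roles == "slow", pb[["slow"]],
                          config$background_weight))
  base_w[is_mito] <- 0
  base_sum <- sum(base_w)
  elev <- 2^config$program_mean_lfc
  mix <- effective_class_mix(config)
  n_per <- config$n_cells_per_condition
  n_total <- n_per * length(config$conditions)

  counts <- matrix(0, nrow = n_total, ncol = length(genes))
  condition <- rep(config$conditions, each = n_per)
  cls <- character(n_total)
  outlier <- logical(n_total)

  for (i in seq_len(n_total)) {
    with_seed(cell_seed(config$seed, i), {
      p <- mix[[condition[i]]]
      cls[i] <- sample(names(p), 1L, prob = p)
      L <- rlnorm(1, config$libsize_meanlog, config$libsize_sdlog)
      f <- min(max(rnorm(1, config$mito_frac_mean, config$mito_frac_sd),
                   0.002), 0.08)
      if (runif(1) < config$outlier_frac) {
        outlier[i] <- TRUE
        if (runif(1) < 0.5) L <- 7000 * (1 + 0.3 * rexp(1))
        else f <- runif(1, 0.15, 0.30)
      }
      w <- base_w
      if (cls[i] %in% c("fast", "hybrid")) w[roles == "fast"] <- w[roles == "fast"] * elev
      if (cls[i] %in% c("slow", "hybrid")) w[roles == "slow"] <- w[roles == "slow"] * elev
      # program elevation scales expected counts directly (mean-count
      # ratio between classes is exact); the mitochondrial block is then
      # sized so the cell's expected mito fraction is exactly f
      mu <- L * w / base_sum
      mu[is_mito] <- f / (1 - f) * sum(mu) / n_mito
      counts[i, ] <- rnbinom_mu(length(mu), mu, config$nb_dispersion)
    })
  }

  cells <- sprintf("cell%05d", seq_len(n_total))
  rownames(counts) <- cells
  colnames(counts) <- genes
  fc <- fiber_counts(counts, cells = cells, genes = genes,
                     condition = condition, mito_mask = is_mito)
  truth <- data.frame(cell = cells, condition = condition, true_class = cls,
                      intensity_fast = ifelse(cls %in% c("fast", "hybrid"), elev, 1),
                      intensity_slow = ifelse(cls %in% c("slow", "hybrid"), elev, 1),
                      qc_outlier = outlier, stringsAsFactors = FALSE)
  if (n_total == 0) truth <- truth[0, ]
  attr(truth, "class_counts") <-
    if (n_total) table(condition = condition, class = cls) else NULL
  list(counts = fc, truth = truth)
}

#' Generate a designed GO annotation fixture
#'
#' Builds a gene-to-GO-term table in which seed genes receive disjoint term
#' blocks, designated "similar" genes share an exactly realized fraction of
#' one seed's terms, and distractor genes receive terms disjoint from every
#' seed, so all pairwise Jaccard indices are known by construction.
#'
#' @param seed_genes marker genes that anchor the design.
#' @param similar data.frame with columns `gene`, `seed`, `overlap`
#'   (fraction of the seed's terms shared, in `[0, 1]`).
#' @param distractors genes annotated disjointly from all seeds.
#' @param n_terms terms per gene.
#' @param seed RNG seed (controls which of the seed's terms are shared).
#' @return named list mapping each gene to its character vector of GO ids.
#' @export
generate_go_annotations <- function(seed_genes = c("Myh1", "Myh2", "Myh4", "Myh7"),
                                    similar = data.frame(
                                      gene = c("Myh7b", "Myh11", "Myh3"),
                                      seed = c("Myh7", "Myh7", "Myh1"),
                                      overlap = c(0.6, 0.5, 0.4)),
                                    distractors = c("Ckm", "Pygm", "Ttn",
                                                    "Mybph", "Fbxo32", "Trim63"),
                                    n_terms = 10L, seed = 1L) {
  if (!nrow(similar) == 0 &&
      (any(similar$overlap < 0) || any(similar$overlap > 1)))
    fib_stop("fiberfa_config_error", "overlap fractions must lie in [0, 1]")
  if (!all(similar$seed %in% seed_genes))
    fib_stop("fiberfa_config_error", "similar$seed must name seed genes")
  next_id <- 0L
  fresh <- function(k) {
    ids <- sprintf("GO:%07d", next_id + seq_len(k))
    next_id <<- next_id + k
    ids
  }
  ann <- list()
  for (g in seed_genes) ann[[g]] <- fresh(n_terms)
  with_seed(seed, {
    for (i in seq_len(nrow(similar))) {
      s <- round(similar$overlap[i] * n_terms)
      shared <- if (s > 0) sample(ann[[similar$seed[i]]], s) else character()
      ann[[similar$gene[i]]] <- c(shared, fresh(n_terms - s))
    }
  })
  for (g in distractors) ann[[g]] <- fresh(n_terms)
  ann
}

#' Write a synthetic dataset to disk in community single-cell layout
#'
#' Writes `matrix.mtx` (genes x cells, 1-based Matrix Market triplets),
#' `features.tsv`, `barcodes.tsv`, `meta.tsv` (cell, condition) and, when
#' truth is supplied, `truth.tsv`.
#'
#' @param sim result of [generate_fiber_counts()], or a [fiber_counts()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  fc <- if (inherits(sim, "fiber_counts")) sim else sim$counts
  truth <- if (inherits(sim, "fiber_counts")) NULL else sim$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mtx = file.path(dir, "matrix.mtx"),
             features = file.path(dir, "features.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"),
             meta = file.path(dir, "meta.tsv"))
  m <- Matrix::Matrix(t(fc$counts), sparse = TRUE)  # genes x cells on disk
  Matrix::writeMM(m, paths[["mtx"]])
  writeLines(fc$genes, paths[["features"]])
  writeLines(fc$cells, paths[["barcodes"]])
  meta <- data.frame(cell = fc$cells,
                     condition = if (is.null(fc$condition)) NA else fc$condition)
  write.table(meta, paths[["meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.tsv"))
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
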