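# Four-way fiber classification from the two factor scores. The original
# analysis set the thresholds manually from score histograms; the automatic
# valley proposal is a convenience default, and manual values always take
# precedence in the pipeline.

#' Threshold set for fiber classification
#'
#' @param tau_fast,tau_slow finite thresholds on the fast / slow factor
#'   scores.
#' @param provenance `"manual"` or `"auto"`, recorded for the run report.
#' @return object of class `fiber_thresholds`.
#' @export
fiber_thresholds <- function(tau_fast, tau_slow,
                             provenance = c("manual", "auto")) {
  provenance <- match.arg(provenance)
  stopifnot_scalar_number(tau_fast, "tau_fast")
  stopifnot_scalar_number(tau_slow, "tau_slow")
  structure(list(tau_fast = tau_fast, tau_slow = tau_slow,
                 provenance = provenance), class = "fiber_thresholds")
}

#' @export
print.fiber_thresholds <- function(x, ...) {
  cat(sprintf("<fiber_thresholds> tau_fast = %.4f, tau_slow = %.4f (%s)\n",
              x$tau_fast, x$tau_slow, x$provenance))
  invisible(x)
}

# Valley of a kernel density estimate between its two largest modes; NULL
# when the density is effectively unimodal (no valley dipping well below
# both flanking modes, which rules out sampling wiggles on one hump).
density_valley <- function(x, min_depth = 0.8) {
  d <- density(x)
  y <- d$y
  n <- length(y)
  peaks <- which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  if (length(peaks) < 2L) return(NULL)
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  seg <- seq(top2[1L], top2[2L])
  valley <- seg[which.min(y[seg])]
  if (y[valley] > min_depth * min(y[top2])) return(NULL)
  d$x[valley]
}

#' Propose classification thresholds from score histograms
#'
#' Per factor, the threshold is placed at the minimum of a kernel density
#' estimate between the two largest modes. If the density is unimodal the
#' midpoint between two 1-D k-means centers is used instead, with a
#' warning.
#'
#' @param scores matrix of factor scores with columns `F_fast`, `F_slow`
#'   (at least 20 cells), or a `fiber_fa` object.
#' @return a [fiber_thresholds()] with provenance `"auto"`.
#' @export
propose_thresholds <- function(scores) {
  if (inherits(scores, "fiber_fa")) scores <- scores$scores
  if (nrow(scores) < 20L)
    fib_stop("fiberfa_value_error",
             "fewer than 20 cells; set thresholds manually")
  tau <- vapply(c("F_fast", "F_slow"), function(col) {
    x <- scores[, col]
    v <- density_valley(x)
    if (is.null(v)) {
      fib_warn("score distribution of %s looks unimodal; using 1-D k-means midpoint",
               col)
      km <- with_seed(0L, kmeans(x, centers = 2L, nstart = 5L))
      v <- mean(km$centers)
    }
    v
  }, numeric(1))
  fiber_thresholds(tau[["F_fast"]], tau[["F_slow"]], provenance = "auto")
}

#' Classify cells into the four fiber classes
#'
#' A cell at or above a threshold is positive for that program (boundary
#' inclusive): positive for fast only is `fast`, slow only `slow`, both
#' `double_positive`, neither `double_negative`.
#'
#' @param scores score matrix with columns `F_fast`, `F_slow` and cell
#'   rownames, or a `fiber_fa`.
#' @param thresholds a [fiber_thresholds()].
#' @return list with `label` (named factor over the four classes, every
#'   cell exactly one label) and the `thresholds` used.
#' @export
classify_cells <- function(scores, thresholds) {
  if (inherits(scores, "fiber_fa")) scores <- scores$scores
  if (!inherits(thresholds, "fiber_thresholds"))
    fib_stop("fiberfa_value_error", "thresholds must be a fiber_thresholds")
  f <- scores[, "F_fast"]
  s <- scores[, "F_slow"]
  if (anyNA(f) || anyNA(s))
    fib_stop("fiberfa_value_error", "missing score for cell '%s'",
             rownames(scores)[which(is.na(f) | is.na(s))[1L]])
  fast_pos <- f >= thresholds$tau_fast
  slow_pos <- s >= thresholds$tau_slow
  lab <- ifelse(fast_pos & slow_pos, "double_positive",
         ifelse(fast_pos, "fast",
         ifelse(slow_pos, "slow", "double_negative")))
  label <- factor(lab, levels = c("double_negative", "fast", "slow",
                                  "double_positive"))
  names(label) <- rownames(scores)
  list(label = label, thresholds = thresholds)
}
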