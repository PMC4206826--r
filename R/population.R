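#' Cosine similarity between two response vectors
#'
#' `dot(u, v) / (|u| * |v|)`, the cosine of the angle between two
#' N-cell population response vectors. Zero-norm vectors have no defined
#' direction and raise an error rather than silently returning a value
#' that would bias averaged similarities; callers may drop all-zero
#' repetitions explicitly.
#'
#' @param u,v Equal-length numeric vectors with positive norm.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

#' Pattern similarity across three stimulus repetitions
#'
#' The three pairwise cosine similarities between the population response
#' vectors of the first/second, second/third and first/third repetitions,
#' and their arithmetic mean (the pattern-similarity statistic of a test
#' time point).
#'
#' @param v1,v2,v3 Equal-length response vectors (same cell order).
#' @return A list of class `"similarity_result"`: `pair_cosines` (named
#'   `c12`, `c23`, `c13`) and `mean_cosine`.
#' @examples
#' pattern_similarity(c(1, 2, 2), c(2, 1, 2), c(2, 2, 1))$mean_cosine  # 8/9
#' @export
pattern_similarity <- function(v1, v2, v3) {
  pc <- c(c12 = cosine_similarity(v1, v2),
          c23 = cosine_similarity(v2, v3),
          c13 = cosine_similarity(v1, v3))
  structure(list(pair_cosines = pc, mean_cosine = mean(pc)),
            class = "similarity_result")
}

#' Cronbach's alpha reliability with Feldt confidence interval
#'
#' Internal-consistency reliability of responses across stimulus
#' repetitions: `alpha = k/(k-1) * (1 - sum(var_item) / var_total)`, with
#' the repetitions as items (rows) and the cells as subjects (columns);
#' item variances and the total-score variance are sample variances across
#' cells. Binary occurrence matrices (0/1) are accepted, which is the
#' default use: reliability of transient *occurrence* across three
#' repetitions. The 95% confidence interval is Feldt's F-based interval
#' with `n_cells - 1` and `(n_cells - 1) * (k - 1)` degrees of freedom.
#'
#' @param scores Numeric matrix, repetitions (items) x cells (subjects).
#' @param conf_level Confidence level for the interval.
#' @return A list of class `"reliability_result"`: `alpha`, `ci95`
#'   (`low`, `high`), `k`, `n`.
#' @export
cronbach_alpha <- function(scores, conf_level = 0.95) {
  scores <- as.matrix(scores)
  k <- nrow(scores); n <- ncol(scores)
  if (k < 2) stop("need at least 2 repetitions (items)")
  if (n < 2) stop("need at least 2 cells (subjects)")
  total <- colSums(scores)
  vt <- stats::var(total)
  if (vt == 0) stop("total-score variance is zero; alpha undefined")
  vi <- apply(scores, 1, stats::var)
  alpha <- k / (k - 1) * (1 - sum(vi) / vt)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  gamma <- 1 - conf_level
  low <- 1 - (1 - alpha) * stats::qf(1 - gamma / 2, df1, df2)
  high <- 1 - (1 - alpha) * stats::qf(gamma / 2, df1, df2)
  structure(list(alpha = alpha, ci95 = c(low = low, high = high),
                 k = k, n = n, conf_level = conf_level),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<cronbach_alpha: %.3f [%.3f, %.3f], %d items x %d subjects>\n",
              x$alpha, x$ci95["low"], x$ci95["high"], x$k, x$n))
  invisible(x)
}

#' Responder distribution summary
#'
#' Histogram of per-cell response values and the fraction of cells
#' strictly above a responder threshold (default dF/F 0.2).
#'
#' @param values Finite numeric response values (may be empty).
#' @param threshold Responder criterion.
#' @param bin_edges Strictly increasing histogram edges (half-open bins,
#'   last bin closed); values outside the edges are not binned but counted
#'   in `n_out_of_range`.
#' @return A list: `counts`, `bin_edges`, `fraction_above`,
#'   `fraction_defined`, `n`, `n_out_of_range`.
#' @export
responder_distribution <- function(values, threshold = 0.2,
                                   bin_edges = seq(0, 1, by = 0.1)) {
  if (any(diff(bin_edges) <= 0)) stop("'bin_edges' must be increasing")
  if (length(values) && !all(is.finite(values)))
    stop("'values' must be finite")
  nb <- length(bin_edges) - 1L
  counts <- integer(nb)
  inb <- 0L
  if (length(values)) {
    # half-open bins [e_i, e_{i+1}), last bin closed
    bin <- findInterval(values, bin_edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb
    counts <- tabulate(bin[ok], nbins = nb)
    inb <- sum(ok)
  }
  structure(list(counts = counts, bin_edges = bin_edges,
                 fraction_above = if (length(values))
                   mean(values > threshold) else NA_real_,
                 fraction_defined = length(values) > 0,
                 n = length(values),
                 n_out_of_range = length(values) - inb,
                 threshold = threshold),
            class = "responder_distribution")
}

#' Two-sample Kolmogorov--Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two
#' empirical CDFs; the p-value uses the asymptotic Kolmogorov distribution
#' with the effective sample size `n * m / (n + m)` (adequate for the
#' 50--80-cell samples this package targets).
#'
#' @param x,y Non-empty numeric samples.
#' @return A list with `D`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(v) mean(x <= v), 0)
  fy <- vapply(pooled, function(v) mean(y <= v), 0)
  D <- max(abs(fx - fy))
  ne <- n * m / (n + m)
  lambda <- sqrt(ne) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(D = D, p = min(1, max(0, p)), n_x = n, n_y = m)
}

#' Correlate dopaminergic-evoked calcium with sensory response gain
#'
#' Pearson correlation (with two-sided p) between each cell's summed
#' dF/F response to dopaminergic (VTA) stimulation and its change in
#' sensory-evoked dF/F from before to 2 hr after conditioning, within one
#' animal.
#'
#' @param vta_summed_dff Per-cell summed dF/F under VTA stimulation.
#' @param delta_dff Per-cell `dF/F(2hr) - dF/F(before)`, same cells.
#' @return A list with `r`, `p`, `n`.
#' @export
correlate_response_gain <- function(vta_summed_dff, delta_dff) {
  if (length(vta_summed_dff) != length(delta_dff))
    stop("inputs must be paired per cell")
  if (length(vta_summed_dff) < 3) stop("need >= 3 paired cells")
  if (stats::sd(vta_summed_dff) == 0 || stats::sd(delta_dff) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(vta_summed_dff, delta_dff, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(delta_dff))
}
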