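#' Ryan's stepwise multiple-comparison procedure
#'
#' All pairwise comparisons of k level means with span-dependent nominal
#' levels and stepwise closure. Means are ranked; a pair spanning `r`
#' ordered means is tested with a two-sided t statistic
#' `t = |m_i - m_j| / sqrt(ms_error * (1/n_i + 1/n_j))` on `df_error`
#' degrees of freedom at the nominal level
#' `alpha_r = 2 * alpha / (k * (r - 1))` (which reduces to `alpha` for
#' `k = 2`). Closure: a pair is tested only if every enclosing span has
#' already been rejected; pairs inside a retained span are declared
#' non-significant without testing, so no isolated rejection can occur
#' inside a non-rejected span.
#'
#' @param level_means Named numeric vector of level means.
#' @param n_per_level Observations per level (scalar or per-level vector).
#' @param ms_error Error mean square from the ANOVA (`> 0`).
#' @param df_error Error degrees of freedom.
#' @param alpha Familywise significance level.
#' @return A `data.frame` of class `"ryan_posthoc"`, one row per pair:
#'   `level_i`, `level_j`, `diff`, `t`, `span_r`, `nominal_level`, `p`,
#'   `tested`, `significant`.
#' @export
ryan_posthoc <- function(level_means, n_per_level, ms_error, df_error,
                         alpha = 0.05) {
  k <- length(level_means)
  if (k < 2) stop("need >= 2 levels")
  if (!is.numeric(ms_error) || ms_error <= 0) stop("'ms_error' must be > 0")
  if (df_error < 1) stop("'df_error' must be >= 1")
  if (length(n_per_level) == 1) n_per_level <- rep(n_per_level, k)
  if (is.null(names(level_means)))
    names(level_means) <- paste0("L", seq_len(k))
  ord <- order(level_means)
  m <- level_means[ord]
  n <- n_per_level[ord]
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  res <- data.frame(
    i = pairs[, 1], j = pairs[, 2],
    level_i = names(m)[pairs[, 1]], level_j = names(m)[pairs[, 2]],
    diff = m[pairs[, 2]] - m[pairs[, 1]],
    span_r = pairs[, 2] - pairs[, 1] + 1L, stringsAsFactors = FALSE)
  res$t <- abs(res$diff) / sqrt(ms_error * (1 / n[res$i] + 1 / n[res$j]))
  res$nominal_level <- if (k == 2) alpha else
    2 * alpha / (k * (res$span_r - 1))
  res$p <- 2 * stats::pt(res$t, df_error, lower.tail = FALSE)
  res <- res[order(-res$span_r, res$i), ]
  res$tested <- FALSE
  res$significant <- FALSE
  for (q in seq_len(nrow(res))) {
    i <- res$i[q]; j <- res$j[q]
    enclosing <- res$i <= i & res$j >= j & !(res$i == i & res$j == j)
    if (any(enclosing & !res$significant)) next
    res$tested[q] <- TRUE
    res$significant[q] <- res$p[q] < res$nominal_level[q]
  }
  rownames(res) <- NULL
  res$i <- NULL; res$j <- NULL
  class(res) <- c("ryan_posthoc", "data.frame")
  res
}

#' Paired t tests with Holm's step-down adjustment
#'
#' Two-sided paired t tests for a list of condition comparisons, with
#' Holm's sequentially rejective adjustment (monotonicity enforced by
#' [stats::p.adjust()]). Identical paired arrays (all differences zero)
#' yield `t = 0, p = 1` rather than an error.
#'
#' @param condition_arrays Named list of numeric vectors, one per
#'   condition, pairing subjects by position.
#' @param comparisons List of length-2 character vectors naming the
#'   condition pairs to compare. Defaults to all pairs against the first
#'   condition.
#' @return A `data.frame`: `condition_a`, `condition_b`, `mean_diff`, `t`,
#'   `df`, `p_raw`, `p_holm`.
#' @export
paired_t_holm <- function(condition_arrays, comparisons = NULL) {
  if (is.null(names(condition_arrays)))
    names(condition_arrays) <- paste0("cond", seq_along(condition_arrays))
  if (is.null(comparisons))
    comparisons <- lapply(names(condition_arrays)[-1],
                          function(b) c(names(condition_arrays)[1], b))
  rows <- lapply(comparisons, function(cmp) {
    x <- condition_arrays[[cmp[1]]]
    y <- condition_arrays[[cmp[2]]]
    if (is.null(x) || is.null(y)) stop("unknown condition in comparison")
    if (length(x) != length(y)) stop("mismatched pair lengths for ",
                                     cmp[1], " vs ", cmp[2])
    if (length(x) < 2) stop("each comparison needs >= 2 pairs")
    d <- y - x
    n <- length(d)
    s <- stats::sd(d)
    if (s == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      t <- mean(d) / (s / sqrt(n))
    }
    p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
    data.frame(condition_a = cmp[1], condition_b = cmp[2],
               mean_diff = mean(d), t = t, df = n - 1, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out
}
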