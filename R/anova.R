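#' Mixed (split-plot) two-way repeated-measures ANOVA
#'
#' Classical balanced split-plot decomposition for designs with one
#' between-subjects factor (conditioning paradigm: separate groups of
#' animals) and one within-subjects factor (test time point, measured
#' repeatedly on every animal). The between factor is tested against the
#' subjects-within-groups stratum; the within factor and the interaction
#' against the subjects-within-groups x time residual. For the canonical
#' 4-paradigm x 8-animal x 4-time design the degrees of freedom are
#' (3, 28) for the paradigm, (3, 84) for time and (9, 84) for the
#' interaction. No sphericity correction is applied by default;
#' Greenhouse--Geisser adjustment of the within-factor p-values is
#' available as an option.
#'
#' @param data Long-format `data.frame`.
#' @param dv,subject,between,within Column names of the dependent
#'   variable, subject (animal) id, between factor and within factor.
#' @param gg_correction Apply the Greenhouse--Geisser epsilon to the
#'   within and interaction tests.
#' @return A `data.frame` of class `"anova_table"` with one row per
#'   stratum (`between`, `subjects_within_groups`, `within`,
#'   `interaction`, `residual`, `total`): `ss`, `df`, `ms`, `F`, `p`, and
#'   a `zero_ss` flag marking effects whose F was guarded to 0 because
#'   both the effect and error sums of squares vanished.
#' @export
mixed_anova <- function(data, dv = "value", subject = "animal",
                        between = "paradigm", within = "time_point",
                        gg_correction = FALSE) {
  need <- c(dv, subject, between, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- data[[dv]]
  subj <- interaction(data[[between]], data[[subject]], drop = TRUE)
  g <- factor(data[[between]])
  w <- factor(data[[within]])
  a <- nlevels(g); b <- nlevels(w)
  if (a < 2 || b < 2) stop("need >= 2 levels per factor")
  # balance check: every subject in one group, every cell exactly once
  tab <- table(subj, w)
  if (any(tab != 1))
    stop("design must be balanced and complete (one value per subject x ",
         "time cell)")
  n_per_group <- table(g) / b
  if (length(unique(n_per_group)) != 1)
    stop("design must be balanced: equal subjects per group")
  n <- as.integer(n_per_group[1])
  grand <- mean(y)
  m_g <- tapply(y, g, mean)
  m_w <- tapply(y, w, mean)
  m_gw <- tapply(y, list(g, w), mean)
  m_s <- tapply(y, subj, mean)
  ss_total <- sum((y - grand)^2)
  ss_between_subj <- b * sum((m_s - grand)^2)
  ss_a <- n * b * sum((m_g - grand)^2)
  ss_subj <- ss_between_subj - ss_a
  ss_b <- a * n * sum((m_w - grand)^2)
  ss_ab <- n * sum((m_gw - outer(m_g - grand, m_w - grand, `+`) - grand)^2)
  ss_res <- ss_total - ss_a - ss_subj - ss_b - ss_ab
  df_a <- a - 1L; df_subj <- a * (n - 1L)
  df_b <- b - 1L; df_ab <- df_a * df_b; df_res <- df_subj * df_b
  ms <- c(ss_a / df_a, ss_subj / df_subj, ss_b / df_b, ss_ab / df_ab,
          ss_res / df_res)
  guard_f <- function(ss_eff, ms_eff, ms_err, tol = 1e-12) {
    if (ms_err > tol) return(ms_eff / ms_err)
    if (ss_eff <= tol) return(0)
    Inf
  }
  f_a <- guard_f(ss_a, ms[1], ms[2])
  f_b <- guard_f(ss_b, ms[3], ms[5])
  f_ab <- guard_f(ss_ab, ms[4], ms[5])
  eps <- 1
  if (gg_correction) eps <- gg_epsilon(data, dv, subject, between, within)
  p_a <- stats::pf(f_a, df_a, df_subj, lower.tail = FALSE)
  p_b <- stats::pf(f_b, eps * df_b, eps * df_res, lower.tail = FALSE)
  p_ab <- stats::pf(f_ab, eps * df_ab, eps * df_res, lower.tail = FALSE)
  out <- data.frame(
    effect = c("between", "subjects_within_groups", "within", "interaction",
               "residual", "total"),
    ss = c(ss_a, ss_subj, ss_b, ss_ab, ss_res, ss_total),
    df = c(df_a, df_subj, df_b, df_ab, df_res, a * b * n - 1L),
    ms = c(ms, NA),
    F = c(f_a, NA, f_b, f_ab, NA, NA),
    df_den = c(df_subj, NA, df_res, df_res, NA, NA),
    p = c(p_a, NA, p_b, p_ab, NA, NA),
    zero_ss = c(ss_a <= 1e-12, NA, ss_b <= 1e-12, ss_ab <= 1e-12, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "gg_epsilon") <- eps
  class(out) <- c("anova_table", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the pooled within-subject covariance
gg_epsilon <- function(data, dv, subject, between, within) {
  wide <- stats::reshape(
    data[, c(dv, subject, between, within)], timevar = within,
    idvar = c(subject, between), direction = "wide")
  m <- as.matrix(wide[, -(1:2), drop = FALSE])
  S <- stats::cov(m)
  b <- ncol(S)
  dbar <- mean(diag(S)); mbar <- mean(S)
  num <- (b * (dbar - mbar))^2
  den <- (b - 1) * (sum(S^2) - 2 * b * sum(rowMeans(S)^2) + b^2 * mbar^2)
  max(1 / (b - 1), min(1, num / den))
}

#' One-way between-groups ANOVA
#'
#' Standard between/within decomposition with `k - 1` and `N - k` degrees
#' of freedom; the error mean square and degrees of freedom feed
#' [ryan_posthoc()].
#'
#' @param groups List of numeric vectors, one per group (each with at
#'   least two observations).
#' @return A list: `F`, `df` (`c(df_num, df_den)`), `p`, `ms_between`,
#'   `ms_error`, `group_means`, `n_per_group`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs >= 2 observations")
  k <- length(groups)
  y <- unlist(groups, use.names = FALSE)
  N <- length(y)
  grand <- mean(y)
  m <- vapply(groups, mean, 0)
  ss_b <- sum(sizes * (m - grand)^2)
  ss_w <- sum(vapply(groups, function(gr) sum((gr - mean(gr))^2), 0))
  df_b <- k - 1L; df_w <- N - k
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  F <- if (ms_w > 1e-12) ms_b / ms_w else if (ss_b <= 1e-12) 0 else Inf
  list(F = F, df = c(df_num = df_b, df_den = df_w),
       p = stats::pf(F, df_b, df_w, lower.tail = FALSE),
       ms_between = ms_b, ms_error = ms_w,
       group_means = m, n_per_group = sizes)
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  cat("Mixed (split-plot) repeated-measures ANOVA\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
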