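test_that("split-plot ANOVA has the canonical degrees of freedom", {
  set.seed(1)
  d <- random_split_plot_data(a = 4, n = 8, b = 4)
  tab <- mixed_anova(d)
  expect_equal(tab$df[tab$effect == "between"], 3)
  expect_equal(tab$df_den[tab$effect == "between"], 28)
  expect_equal(tab$df[tab$effect == "within"], 3)
  expect_equal(tab$df_den[tab$effect == "within"], 84)
  expect_equal(tab$df[tab$effect == "interaction"], 9)
  expect_equal(tab$df_den[tab$effect == "interaction"], 84)
})

test_that("split-plot ANOVA matches the aov() error-strata reference", {
  set.seed(2)
  for (r in 1:50) {
    d <- random_split_plot_data(a = sample(2:4, 1), n = sample(3:8, 1),
                                b = sample(2:4, 1),
                                paradigm_effect = runif(1, 0, 1),
                                time_effect = runif(1, 0, 1))
    tab <- mixed_anova(d)
    ref <- aov_split_plot(d)
    expect_equal(tab$F[tab$effect == "between"], ref$F_between,
                 tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "within"], ref$F_within,
                 tolerance = 1e-8)
    expect_equal(tab$F[tab$effect == "interaction"], ref$F_inter,
                 tolerance = 1e-8)
    # SS decomposition closes
    expect_lt(abs(sum(tab$ss[1:5]) - tab$ss[6]), 1e-9 * max(1, tab$ss[6]))
  }
})

test_that("degenerate and unbalanced designs are handled", {
  d <- random_split_plot_data(a = 2, n = 3, b = 2)
  d$value <- 5
  tab <- mixed_anova(d)
  expect_true(all(tab$F[!is.na(tab$F)] == 0))
  expect_true(all(tab$zero_ss[!is.na(tab$zero_ss)]))

  d2 <- random_split_plot_data(a = 2, n = 3, b = 2)[-1, ]
  expect_error(mixed_anova(d2), "balanced")
})

test_that("one-way ANOVA matches hand sums of squares", {
  set.seed(3)
  groups <- replicate(4, rnorm(8), simplify = FALSE)
  res <- oneway_anova(groups)
  expect_equal(unname(res$df), c(3, 28))
  ref <- summary(stats::aov(y ~ g, data.frame(
    y = unlist(groups), g = factor(rep(1:4, each = 8)))))[[1]]
  expect_equal(res$F, ref["g", "F value"], tolerance = 1e-10)
  expect_equal(res$p, ref["g", "Pr(>F)"], tolerance = 1e-10)

  same <- oneway_anova(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(same$F, 0)
  # hand case: groups (1,2) and (3,4): SSb = 4, SSw = 1, F = 4/0.5 = 8
  hand <- oneway_anova(list(c(1, 2), c(3, 4)))
  expect_equal(hand$F, 8)
  expect_error(oneway_anova(list(1, c(2, 3))), "2 observations")
})

test_that("Ryan's nominal levels follow the span formula", {
  m <- c(a = 1, b = 2, c = 4, d = 8)
  res <- ryan_posthoc(m, 8, ms_error = 1, df_error = 28)
  # alpha_r = 2 * 0.05 / (k * (r - 1)) for k = 4
  expect_equal(sort(unique(res$nominal_level[res$span_r == 2])), 0.1 / 4)
  expect_equal(sort(unique(res$nominal_level[res$span_r == 3])), 0.1 / 8)
  expect_equal(sort(unique(res$nominal_level[res$span_r == 4])), 0.1 / 12)
  # k = 2 degenerates to a single comparison at alpha
  res2 <- ryan_posthoc(c(a = 0, b = 3), 8, 1, 14, alpha = 0.05)
  expect_equal(nrow(res2), 1)
  expect_equal(res2$nominal_level, 0.05)
  expect_error(ryan_posthoc(m, 8, ms_error = 0, df_error = 28), "ms_error")
})

test_that("Ryan closure forbids isolated rejections inside retained spans", {
  set.seed(4)
  for (r in 1:200) {
    k <- sample(3:5, 1)
    m <- sort(rnorm(k, sd = sample(c(0.2, 1), 1)))
    names(m) <- paste0("r", seq_len(k))        # names encode the rank order
    res <- ryan_posthoc(m, n_per_level = 8, ms_error = 1, df_error = 28)
    rk <- function(lv) as.integer(sub("r", "", lv))
    for (q in which(res$significant)) {
      i <- rk(res$level_i[q]); j <- rk(res$level_j[q])
      lo <- min(i, j); hi <- max(i, j)
      enclosing <- which(pmin(rk(res$level_i), rk(res$level_j)) <= lo &
                           pmax(rk(res$level_i), rk(res$level_j)) >= hi)
      expect_true(all(res$significant[enclosing]))
      expect_true(all(res$tested[enclosing]))
    }
    # untested pairs are never flagged significant
    expect_true(all(res$tested[res$significant]))
  }
})

test_that("Ryan rejections sit between Bonferroni-all-pairs and unadjusted", {
  set.seed(6)
  for (r in 1:50) {
    k <- 4; n <- 8
    groups <- replicate(k, rnorm(n, mean = runif(1, 0, 2)),
                        simplify = FALSE)
    ow <- oneway_anova(groups)
    res <- ryan_posthoc(ow$group_means, n, ow$ms_error, ow$df["df_den"])
    n_pairs <- choose(k, 2)
    bonf <- res$p < 0.05 / n_pairs
    unadj <- res$p < 0.05
    expect_true(all(res$significant[bonf]))       # superset of Bonferroni
    expect_true(all(unadj[res$significant]))      # subset of unadjusted
  }
})

test_that("paired t with Holm matches hand adjustment and guards ties", {
  # Holm on raw (0.01, 0.03, 0.04) -> (0.03, 0.06, 0.06)
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  set.seed(7)
  conds <- list(base = rnorm(10), a = rnorm(10, 1), b = rnorm(10, 0.2),
                c = rnorm(10, 0.1))
  res <- paired_t_holm(conds)
  expect_equal(nrow(res), 3)
  # agrees with t.test raw p-values
  ref <- t.test(conds$a, conds$base, paired = TRUE)$p.value
  expect_equal(res$p_raw[res$condition_b == "a"], ref)
  # adjusted p monotone in sorted raw p and order-invariant
  o <- order(res$p_raw)
  expect_true(all(diff(res$p_holm[o]) >= 0))
  res_rev <- paired_t_holm(conds, comparisons = list(c("base", "c"),
                                                     c("base", "b"),
                                                     c("base", "a")))
  expect_equal(sort(res_rev$p_holm), sort(res$p_holm))

  single <- paired_t_holm(conds, comparisons = list(c("base", "a")))
  expect_equal(single$p_holm, single$p_raw)
  same <- paired_t_holm(list(x = 1:5, y = 1:5))
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  expect_error(paired_t_holm(list(x = 1:4, y = 1:5)), "mismatched")
})
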