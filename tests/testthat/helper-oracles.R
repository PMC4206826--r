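# Independent oracles and shared fixtures for the test suite.

# naive per-sample sort-and-pick median of a truncating window
naive_sliding_median <- function(trace, fps, half_window_s) {
  n <- length(trace)
  h <- floor(half_window_s * fps + 1e-9)
  vapply(seq_len(n), function(i) {
    w <- sort(trace[max(1, i - h):min(n, i + h)])
    m <- length(w)
    if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  }, 0)
}

naive_dff <- function(trace, fps, half_window_s) {
  f0 <- naive_sliding_median(trace, fps, half_window_s)
  (trace - f0) / f0
}

# split-plot ANOVA reference via aov() error strata
aov_split_plot <- function(d) {
  d$animal_uid <- interaction(d$paradigm, d$animal, drop = TRUE)
  d$paradigm <- factor(d$paradigm)
  d$time_point <- factor(d$time_point)
  fit <- stats::aov(value ~ paradigm * time_point + Error(animal_uid),
                    data = d)
  s <- summary(fit)
  btab <- s[[1]][[1]]; wtab <- s[[2]][[1]]
  rownames(btab) <- trimws(rownames(btab))
  rownames(wtab) <- trimws(rownames(wtab))
  list(F_between = btab["paradigm", "F value"],
       F_within = wtab["time_point", "F value"],
       F_inter = wtab["paradigm:time_point", "F value"],
       df = c(btab["paradigm", "Df"], btab["Residuals", "Df"],
              wtab["time_point", "Df"], wtab["Residuals", "Df"]))
}

random_split_plot_data <- function(a = 4, n = 8, b = 4,
                                   paradigm_effect = 0, time_effect = 0) {
  g <- rep(paste0("P", seq_len(a)), each = n * b)
  an <- rep(rep(seq_len(n), each = b), a)
  tp <- rep(paste0("t", seq_len(b)), a * n)
  subj_eff <- rep(stats::rnorm(a * n, 0, 0.5), each = b)
  data.frame(paradigm = g, animal = an, time_point = tp,
             value = stats::rnorm(a * n * b) + subj_eff +
               paradigm_effect * (g == "P1") +
               time_effect * (tp == paste0("t", b)))
}

# movie fixture used for the imaging front-end checks: 10 neurons,
# 3 astrocytes, contrast-to-noise 5, fixed seed
standard_movie <- function(seed = 7, ...) {
  simulate_movie(movie_config(...), seed = seed)
}

match_rois <- function(det, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    any(sqrt((det$cx - truth$cx[i])^2 + (det$cy - truth$cy[i])^2) <=
          truth$r[i]), TRUE)
}
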