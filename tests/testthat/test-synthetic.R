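test_that("transient kernels are unit-peak with exact exponential decay", {
  k <- make_transient_kernel("long", peak_time_s = 6.5, tau_s = 8, fps = 2.3)
  expect_equal(which.max(k$values), k$peak_index)
  expect_equal(k$values[k$peak_index], 1.0)
  expect_equal(k$peak_index, round(6.5 * 2.3) + 1L)
  expect_true(all(k$values >= 0))
  t <- (seq_along(k$values) - 1) / 2.3
  post <- t >= k$peak_time_s
  expect_equal(k$values[post], exp(-(t[post] - k$peak_time_s) / 8))

  ks <- make_transient_kernel("short", peak_time_s = 0.5, tau_s = 1.5,
                              fps = 2.3)
  expect_lte((length(ks$values) - 1) / 2.3, 5)      # support within 5 s
  expect_lt(eval_transient_kernel(ks, 5), 0.05)     # exp(-4.5/1.5) ~ 0.0498
  expect_equal(eval_transient_kernel(ks, ks$peak_time_s), 1.0)
})

test_that("kernel parameter validation rejects degenerate inputs", {
  expect_error(make_transient_kernel("short", 0.5, tau_s = 0, fps = 2.3),
               "tau")
  expect_error(make_transient_kernel("short", 0.5, tau_s = 1, fps = 0),
               "fps")
  expect_error(make_transient_kernel("long", peak_time_s = 2, tau_s = 8,
                                     fps = 2.3), "peak_time_s")
  expect_error(make_transient_kernel("short", 0.5, 1.5, 2.3,
                                     duration_s = 10), "duration")
})

test_that("simulate_trace matches its construction contract", {
  k <- make_transient_kernel("short", 0.5, 1.5, 2.3)
  flat <- simulate_trace(1000, duration_s = 30, fps = 2.3, noise_sd = 0,
                         drift_amplitude = 0)
  expect_equal(flat, rep(1000, floor(30 * 2.3)))

  ev <- stimulus_event(10, "V2L", 20, 5)
  tr <- simulate_trace(1000, ev, k, 0.5, duration_s = 30, fps = 2.3,
                       noise_sd = 0)
  expect_equal(max(tr / 1000 - 1), 0.5)
  peak_frame <- round(10 * 2.3) + k$peak_index
  expect_equal(which.max(tr), peak_frame)

  expect_error(simulate_trace(-5, duration_s = 10, fps = 2.3), "positive")
  expect_error(simulate_trace(1000, stimulus_event(40, "V2L"), k, 0.5,
                              duration_s = 30, fps = 2.3),
               "outside the recording")
})

test_that("trace simulation is deterministic in the seed", {
  k <- make_transient_kernel("short", 0.5, 1.5, 2.3)
  ev <- stimulus_event(10, "V2L")
  a <- simulate_trace(1000, ev, k, 0.3, duration_s = 30, fps = 2.3,
                      noise_sd = 0.02, seed = 7)
  b <- simulate_trace(1000, ev, k, 0.3, duration_s = 30, fps = 2.3,
                      noise_sd = 0.02, seed = 7)
  d <- simulate_trace(1000, ev, k, 0.3, duration_s = 30, fps = 2.3,
                      noise_sd = 0.02, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("injected amplitudes are linear and scale-invariant through dF/F", {
  k <- make_transient_kernel("long", 6.5, 8, 2.3)
  ev <- stimulus_event(60, "VTA", 50, 10)
  peak_of <- function(amp, f0 = 1000) {
    tr <- simulate_trace(f0, ev, k, amp, duration_s = 150, fps = 2.3,
                         noise_sd = 0)
    max(compute_dff(tr, 2.3, 40))
  }
  p1 <- peak_of(0.25); p2 <- peak_of(0.5)
  expect_lt(abs(p2 - 2 * p1), 1e-9)                 # linearity
  expect_lt(abs(p1 - 0.25) / 0.25, 0.02)            # amplitude recovery
  # dF/F invariant to the baseline scale
  set.seed(3)
  noise <- rnorm(floor(150 * 2.3))
  tr1 <- 1000 * (1 + 0.02 * noise); tr1[80] <- tr1[80] * 1.3
  tr2 <- 7 * tr1
  expect_equal(compute_dff(tr1, 2.3, 40), compute_dff(tr2, 2.3, 40))
})

test_that("estimated response gain is monotone in the injected gain", {
  k <- make_transient_kernel("short", 0.5, 1.5, 2.3)
  ev <- stimulus_event(15, "V2L", 20, 5)
  gains <- c(1, 1.25, 1.5, 2)
  set.seed(11)
  est <- sapply(gains, function(g) {
    mean(replicate(100, {
      tr <- simulate_trace(1000, ev, k, 0.2 * g, duration_s = 40, fps = 2.3,
                           noise_sd = 0.02)
      peak_response(compute_dff(tr, 2.3, 40), 2.3, c(15, 20))$peak_dff
    }))
  })
  expect_equal(cor(est, gains, method = "spearman"), 1)
})

test_that("all-unity effects give identical responses across time points", {
  unity <- default_paradigm_effects()
  unity$T1 <- unity$T2
  cfg <- sim_config(n_animals_per_paradigm = 2, n_cells = 15, noise_sd = 0,
                    drift_amplitude = 0, paradigm_effects = unity,
                    duration_s = 24, stim_times_s = c(6, 12, 18))
  sim <- simulate_experiment(experiment_design(), cfg, seed = 5)
  amp <- sim$ground_truth$amplitudes$T1[[1]]
  for (tp in dimnames(amp)[[3]][-1])
    expect_identical(amp[, , tp], amp[, , 1])
  # and the rendered recordings are identical too
  rec <- sim$recordings$T1[[1]]
  expect_identical(rec[["2hr"]]$traces, rec[["before"]]$traces)
})

test_that("a pure gain scales mean ground-truth amplitude exactly", {
  eff <- default_paradigm_effects()
  eff$T1$gain[] <- c(1, 1, 1, 1.5)
  eff$T1$coupling[] <- 0
  cfg <- sim_config(n_animals_per_paradigm = 2, n_cells = 20,
                    paradigm_effects = eff, duration_s = 24,
                    stim_times_s = c(6, 12, 18))
  sim <- simulate_experiment(experiment_design("T1"), cfg, seed = 9)
  amp <- sim$ground_truth$amplitudes$T1[[1]]
  expect_equal(mean(amp[, , "2hr"]), 1.5 * mean(amp[, , "before"]))
})

test_that("similarity coupling raises inter-repetition pattern similarity", {
  mean_sim_at <- function(coupling, seed) {
    eff <- list(T1 = list(
      gain = c(before = 1, right_after = 1, `1hr` = 1, `2hr` = 1),
      coupling = c(before = coupling, right_after = coupling,
                   `1hr` = coupling, `2hr` = coupling)))
    cfg <- sim_config(n_animals_per_paradigm = 1, n_cells = 200,
                      paradigm_effects = eff, duration_s = 24,
                      stim_times_s = c(6, 12, 18), noise_sd = 0)
    sim <- simulate_experiment(experiment_design("T1"), cfg, seed = seed)
    amp <- sim$ground_truth$amplitudes$T1[[1]][, , "before"]
    pattern_similarity(amp[, 1], amp[, 2], amp[, 3])$mean_cosine
  }
  sims <- vapply(1:100, function(s)
    c(mean_sim_at(0, s), mean_sim_at(0.5, s), mean_sim_at(0.9, s)),
    numeric(3))
  m <- rowMeans(sims)
  expect_lt(m[1], m[2])
  expect_lt(m[2], m[3])
})

test_that("unknown paradigms and inconsistent schedules are rejected", {
  expect_error(experiment_design("T3"), "unknown paradigm")
  cfg <- sim_config(stim_times_s = c(6, 12), duration_s = 24)
  expect_error(simulate_experiment(experiment_design(), cfg),
               "one time per repetition")
})

test_that("experiment generation is deterministic in (config, seed)", {
  cfg <- sim_config(n_animals_per_paradigm = 1, n_cells = 5,
                    duration_s = 24, stim_times_s = c(6, 12, 18))
  s1 <- simulate_experiment(experiment_design("T1"), cfg, seed = 3)
  s2 <- simulate_experiment(experiment_design("T1"), cfg, seed = 3)
  expect_identical(s1$recordings, s2$recordings)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("synthetic movies reproduce injected traces and handle edge cases", {
  mv <- standard_movie(snr = Inf)
  tr <- extract_traces(mv, mv$rois, exclude_astrocytes = TRUE)
  expect_equal(nrow(tr$traces), 10)
  expect_equal(unname(tr$traces), unname(mv$traces), tolerance = 1e-12)

  empty <- simulate_movie(movie_config(n_neurons = 0, n_astrocytes = 0),
                          seed = 1)
  expect_equal(nrow(empty$rois), 0)
  expect_equal(dim(empty$green)[3], 60)

  expect_error(simulate_movie(movie_config(n_neurons = 500), seed = 1),
               "could not place")
})

test_that("drug scalars rescale long-transient amplitude and decay constant", {
  cfg <- sim_config(noise_sd = 0.005)
  ctrl <- simulate_drug_condition(cfg, list(amplitude = 1, tau = 1),
                                  n_cells = 30, seed = 13)
  drug <- simulate_drug_condition(cfg, list(amplitude = 0.5, tau = 0.4),
                                  n_cells = 30, seed = 13)
  measure <- function(tm) {
    dm <- compute_dff_matrix(tm, 40)
    peaks <- apply(dm$dff, 1, function(tr)
      peak_response(tr, dm$fps, c(30, 60))$peak_dff)
    pop <- colMeans(dm$dff)
    pk_idx <- which.max(pop)
    tau <- fit_decay(pop, dm$fps, pk_idx,
                     decay_fit_window(pop, dm$fps, pk_idx))$tau_s
    c(peak = mean(peaks), tau = tau)
  }
  mc <- measure(ctrl); md <- measure(drug)
  expect_equal(unname(changing_ratio(md["peak"], mc["peak"])), 0.5,
               tolerance = 0.1)
  expect_equal(unname(md["tau"] / mc["tau"]), 0.4, tolerance = 0.1)
})

test_that("movie drift is recovered by registration", {
  mv <- standard_movie(snr = 5, drift_px = c(3, 0), drift_from_frame = 50)
  reg <- register_frames(mv)
  expect_true(all(reg$shifts[50:60, "dx"] == -3))
  expect_true(all(reg$shifts[50:60, "dy"] == 0))
  expect_true(all(reg$shifts[1:49, ] == 0))
})
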