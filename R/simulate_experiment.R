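#' Default per-paradigm conditioning effects
#'
#' Multiplicative amplitude gains and similarity-coupling values per test
#' time point for the four conditioning paradigms. `T1` (sensory stimulus
#' 0.5 s before the dopaminergic burst) is the only paradigm with a
#' conditioning effect: its response gain ramps to 1.5 at 2 hr and its
#' inter-repetition similarity coupling to 0.8; the temporal-separation
#' control `T2` and the single-site controls (`V2L_only`, `VTA_only`)
#' stay at gain 1 and coupling 0.
#'
#' @param time_points Character vector of test time points.
#' @return Named list (per paradigm) of lists with numeric vectors `gain`
#'   and `coupling`, one entry per time point.
#' @export
default_paradigm_effects <- function(time_points = c("before", "right_after",
                                                     "1hr", "2hr")) {
  unity <- stats::setNames(rep(1, length(time_points)), time_points)
  zero <- stats::setNames(rep(0, length(time_points)), time_points)
  t1_gain <- unity
  t1_gain[c("right_after", "1hr", "2hr")] <- c(1.1, 1.25, 1.5)
  t1_coupling <- zero
  t1_coupling[c("1hr", "2hr")] <- c(0.5, 0.8)
  list(T1 = list(gain = t1_gain, coupling = t1_coupling),
       T2 = list(gain = unity, coupling = zero),
       V2L_only = list(gain = unity, coupling = zero),
       VTA_only = list(gain = unity, coupling = zero))
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-experiment generator. Defaults
#' emulate the conditioning study design: 8 animals per paradigm, 50--80
#' cells per animal sampled uniformly, 2.3 Hz acquisition, three sensory
#' (V2L) stimulus repetitions per test time point, response amplitudes
#' below the 0.2 dF/F responder criterion at baseline.
#'
#' @param n_animals_per_paradigm Animals per conditioning group.
#' @param n_cells Cells per animal: a single count or a length-2 range to
#'   sample uniformly.
#' @param fps Frames per second.
#' @param duration_s Recording length per test time point, seconds.
#' @param stim_times_s Times of the three sensory stimulus repetitions.
#' @param baseline_f0 Baseline fluorescence, arbitrary units.
#' @param noise_sd White-noise SD as a fraction of baseline.
#' @param drift_amplitude Slow-drift amplitude as a fraction of baseline.
#' @param responder_fraction Probability that a cell responds at all.
#' @param amplitude_mean,amplitude_sd Mean/SD of per-cell response
#'   amplitudes (dF/F units) among responders.
#' @param rep_jitter_sd SD of the per-repetition perturbation of the latent
#'   population vector (dF/F units) at similarity coupling 0; the
#'   perturbation SD shrinks as `(1 - coupling)`.
#' @param paradigm_effects As returned by [default_paradigm_effects()].
#' @param drug_scalars Named list of multiplicative factors applied to
#'   long-transient amplitude (`amplitude`) and decay constant (`tau`),
#'   used when simulating pharmacological conditions.
#' @param kernel Transient kernel for the evoked responses; defaults to the
#'   short sensory kernel (peak 0.5 s, tau 1.5 s).
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_animals_per_paradigm = 8,
                       n_cells = c(50, 80),
                       fps = 2.3,
                       duration_s = 190,
                       stim_times_s = c(30, 90, 150),
                       baseline_f0 = 1000,
                       noise_sd = 0.02,
                       drift_amplitude = 0.01,
                       responder_fraction = 0.6,
                       amplitude_mean = 0.15,
                       amplitude_sd = 0.05,
                       rep_jitter_sd = 0.1,
                       paradigm_effects = default_paradigm_effects(),
                       drug_scalars = list(amplitude = 1, tau = 1),
                       kernel = NULL,
                       seed = 1L) {
  n_cells <- unlist(n_cells)
  paradigm_effects <- lapply(paradigm_effects, function(pe)
    list(gain = unlist(pe$gain), coupling = unlist(pe$coupling)))
  if (n_animals_per_paradigm < 1 || any(n_cells < 1))
    stop("counts must be >= 1")
  if (fps <= 0) stop("'fps' must be > 0")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("'responder_fraction' must be in [0, 1]")
  for (pe in paradigm_effects)
    if (any(pe$coupling < 0) || any(pe$coupling > 1))
      stop("similarity coupling must be in [0, 1]")
  if (is.null(kernel))
    kernel <- make_transient_kernel("short", peak_time_s = 0.5, tau_s = 1.5,
                                    fps = fps)
  structure(list(n_animals_per_paradigm = n_animals_per_paradigm,
                 n_cells = n_cells, fps = fps, duration_s = duration_s,
                 stim_times_s = stim_times_s, baseline_f0 = baseline_f0,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 responder_fraction = responder_fraction,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 rep_jitter_sd = rep_jitter_sd,
                 paradigm_effects = paradigm_effects,
                 drug_scalars = drug_scalars, kernel = kernel, seed = seed),
            class = "sim_config")
}

#' Experiment design
#'
#' Phases and schedules of the paired-conditioning experiment: four
#' conditioning paradigms run on separate groups of animals, each tested at
#' four time points (before, right after, 1 hr and 2 hr after conditioning)
#' with three sensory stimulus repetitions per time point. The conditioning
#' phase itself (one paired stimulation per minute for 30 min, sensory
#' offset -0.5 s for T1 and +45 s for T2) is recorded in the design for
#' provenance; test-phase recordings are what the pipeline analyses.
#'
#' @param paradigms Subset of `c("T1", "T2", "V2L_only", "VTA_only")`.
#' @param time_points Test time points.
#' @param n_repetitions Sensory stimulus repetitions per time point (3 is
#'   required for the three-pair pattern-similarity statistic).
#' @param conditioning_interval_s,conditioning_n_events,conditioning_offsets_s
#'   Conditioning-phase schedule metadata.
#' @return A list of class `"experiment_design"`.
#' @export
experiment_design <- function(paradigms = c("T1", "T2", "V2L_only", "VTA_only"),
                              time_points = c("before", "right_after",
                                              "1hr", "2hr"),
                              n_repetitions = 3,
                              conditioning_interval_s = 60,
                              conditioning_n_events = 30,
                              conditioning_offsets_s = c(T1 = -0.5, T2 = 45)) {
  known <- c("T1", "T2", "V2L_only", "VTA_only")
  bad <- setdiff(paradigms, known)
  if (length(bad)) stop("unknown paradigm: ", paste(bad, collapse = ", "))
  structure(list(paradigms = paradigms, time_points = time_points,
                 n_repetitions = n_repetitions,
                 conditioning_interval_s = conditioning_interval_s,
                 conditioning_n_events = conditioning_n_events,
                 conditioning_offsets_s = conditioning_offsets_s),
            class = "experiment_design")
}

#' Simulate a full multi-animal conditioning experiment
#'
#' For every animal the generator draws a fixed set of per-cell base
#' response amplitudes (zero for non-responders) and a fixed set of
#' per-repetition perturbation draws. The injected amplitude of cell *i* on
#' repetition *r* at a test time point with gain *g* and similarity
#' coupling *c* is
#' `g * max(0, a_i + (1 - c) * rep_jitter_sd * eps_{i,r})` for responders
#' and 0 otherwise. Sharing `a` and `eps` across time points makes the
#' design interpretable: with all-unity effects the injected responses are
#' identical at every time point, a pure gain change scales mean amplitude
#' exactly, and raising the coupling shrinks inter-repetition scatter so
#' that expected pairwise cosine similarity increases monotonically.
#' Raw traces are then rendered with [simulate_trace()].
#'
#' @param design An [experiment_design()].
#' @param config A [sim_config()].
#' @param seed Integer seed overriding `config$seed`.
#' @return A list of class `"sim_experiment"` with elements
#'   `recordings[[paradigm]][[animal]][[time_point]]` (each a
#'   [trace_matrix()] annotated with the three stimulus events) and
#'   `ground_truth` (per-cell injected amplitudes and occurrence flags per
#'   repetition and time point, latent population vectors, applied effects).
#' @export
simulate_experiment <- function(design = experiment_design(),
                                config = sim_config(), seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  if (length(config$stim_times_s) != design$n_repetitions)
    stop("'stim_times_s' must provide one time per repetition")
  eff <- config$paradigm_effects
  missing_par <- setdiff(design$paradigms, names(eff))
  if (length(missing_par))
    stop("unknown paradigm: ", paste(missing_par, collapse = ", "))
  tps <- design$time_points
  n_rep <- design$n_repetitions
  recordings <- list()
  truth <- list(amplitudes = list(), occurrence = list(), latent = list(),
                effects = eff[design$paradigms],
                kernel = config$kernel[c("kind", "peak_time_s", "tau_s",
                                         "duration_s")])
  events <- do.call(rbind, lapply(config$stim_times_s, function(ts)
    stimulus_event(ts, "V2L", frequency_hz = 20, n_pulses = 5)))
  for (par in design$paradigms) {
    recordings[[par]] <- list()
    truth$amplitudes[[par]] <- list()
    truth$occurrence[[par]] <- list()
    truth$latent[[par]] <- list()
    gains <- eff[[par]]$gain[tps]
    couplings <- eff[[par]]$coupling[tps]
    if (anyNA(gains) || anyNA(couplings))
      stop("paradigm_effects for ", par, " must cover every time point")
    for (an in seq_len(config$n_animals_per_paradigm)) {
      nc <- if (length(config$n_cells) > 1)
        sample(config$n_cells[1]:config$n_cells[2], 1) else config$n_cells
      responder <- stats::runif(nc) < config$responder_fraction
      base_amp <- ifelse(responder,
                         pmax(stats::rnorm(nc, config$amplitude_mean,
                                           config$amplitude_sd), 0), 0)
      eps <- matrix(stats::rnorm(nc * n_rep), nc, n_rep)
      amp_arr <- array(0, dim = c(nc, n_rep, length(tps)),
                       dimnames = list(NULL, NULL, tps))
      latent <- matrix(0, nc, length(tps), dimnames = list(NULL, tps))
      for (j in seq_along(tps)) {
        latent[, j] <- gains[j] * base_amp
        for (r in seq_len(n_rep)) {
          a <- base_amp + (1 - couplings[j]) * config$rep_jitter_sd * eps[, r]
          a <- gains[j] * pmax(a, 0)
          a[!responder] <- 0
          amp_arr[, r, j] <- a
        }
      }
      anim_rec <- list()
      for (j in seq_along(tps)) {
        traces <- matrix(0, nc, floor(config$duration_s * config$fps + 1e-9))
        for (i in seq_len(nc)) {
          traces[i, ] <- simulate_trace(
            baseline_f0 = config$baseline_f0, events = events,
            kernels = config$kernel, amplitudes = amp_arr[i, , j],
            duration_s = config$duration_s, fps = config$fps,
            noise_sd = config$noise_sd,
            drift_amplitude = config$drift_amplitude)
        }
        anim_rec[[tps[j]]] <- trace_matrix(traces, config$fps, events)
      }
      recordings[[par]][[an]] <- anim_rec
      truth$amplitudes[[par]][[an]] <- amp_arr
      truth$occurrence[[par]][[an]] <- amp_arr > 0
      truth$latent[[par]][[an]] <- latent
    }
  }
  structure(list(recordings = recordings, ground_truth = truth,
                 design = design, config = config, seed = seed),
            class = "sim_experiment")
}

#' Simulate a pharmacological condition recording
#'
#' Renders one animal's population response to a single phasic
#' dopaminergic (VTA) stimulation under a drug condition expressed as
#' multiplicative scalars on the long-transient amplitude and decay
#' constant (e.g. a D1-antagonist-like condition halves the amplitude and
#' shortens tau). Useful for exercising the changing-ratio / peak / tau
#' quantification chain.
#'
#' @param config A [sim_config()]; `amplitude_mean`/`amplitude_sd`,
#'   `noise_sd`, `baseline_f0` and `fps` are honoured.
#' @param drug_scalars List with `amplitude` and `tau` multipliers;
#'   defaults to `config$drug_scalars`.
#' @param n_cells Number of cells.
#' @param stim_time_s Stimulation time, seconds.
#' @param duration_s Recording length, seconds.
#' @param base_tau_s Drug-free decay constant of the long transient.
#' @param seed Integer seed.
#' @return A [trace_matrix()] with attribute `"ground_truth"` (injected
#'   amplitudes and the scaled tau).
#' @export
simulate_drug_condition <- function(config = sim_config(),
                                    drug_scalars = config$drug_scalars,
                                    n_cells = 40, stim_time_s = 30,
                                    duration_s = 120, base_tau_s = 8,
                                    seed = 1L) {
  set.seed(seed)
  tau <- base_tau_s * drug_scalars$tau
  kern <- make_transient_kernel("long", peak_time_s = 6.5, tau_s = tau,
                                fps = config$fps)
  ev <- stimulus_event(stim_time_s, "VTA", frequency_hz = 50, n_pulses = 10)
  amps <- drug_scalars$amplitude *
    pmax(stats::rnorm(n_cells, config$amplitude_mean, config$amplitude_sd), 0)
  traces <- t(vapply(amps, function(a)
    simulate_trace(config$baseline_f0, ev, kern, a, duration_s = duration_s,
                   fps = config$fps, noise_sd = config$noise_sd),
    numeric(floor(duration_s * config$fps + 1e-9))))
  tm <- trace_matrix(traces, config$fps, ev)
  attr(tm, "ground_truth") <- list(amplitudes = amps, tau_s = tau,
                                   drug_scalars = drug_scalars)
  tm
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment: %d paradigm(s) x %d animal(s) x %d time point(s), seed %d>\n",
              length(x$design$paradigms), x$config$n_animals_per_paradigm,
              length(x$design$time_points), x$seed))
  invisible(x)
}
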