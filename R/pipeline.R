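#' Analysis parameter defaults
#'
#' Baseline half window 2.5 s (the fast-transient convention, matching the
#' sensory-evoked responses analysed in the conditioning design), peak
#' summary within 5 s of stimulus onset, occurrence criterion 3 baseline
#' SDs, summed-response window 5 s, first 10 s of each recording excluded
#' from displays (mechanical-onset artifacts), and no per-cell decay
#' fitting (a pharmacology-oriented metric, off by default).
#'
#' @return Named list of analysis parameters.
#' @export
default_analysis_params <- function() {
  list(baseline_half_window_s = 2.5,
       response_window_s = 5,
       response_summary = "peak",
       occurrence_k_sd = 3,
       occurrence_window_s = 5,
       summed_window_s = 5,
       discard_initial_s = 10,
       fit_tau = FALSE,
       alpha = 0.05)
}

#' Analyse a simulated (or loaded) experiment
#'
#' Runs the trace-level analysis over every recording: dF/F with the
#' sliding-median baseline, per-repetition population response vectors,
#' occurrence detection, then per-animal aggregation (mean dF/F across
#' cells and repetitions, three-pair cosine pattern similarity, Cronbach's
#' alpha of occurrence).
#'
#' @param sim A `"sim_experiment"` from [simulate_experiment()].
#' @param params Analysis parameters, see [default_analysis_params()].
#' @return A list: `cell_metrics`, `animal_summary`, `delta_dff`,
#'   `population_traces` (all `data.frame`s), `example_dff` (the dF/F
#'   matrix of the first recording at the last time point, for the cell
#'   map figure).
#' @export
analyze_experiment <- function(sim, params = default_analysis_params()) {
  stopifnot(inherits(sim, "sim_experiment"))
  p <- utils::modifyList(default_analysis_params(), params)
  cell_rows <- list(); animal_rows <- list(); pop_rows <- list()
  example_dff <- NULL
  tps <- sim$design$time_points
  for (par in names(sim$recordings)) {
    for (an in seq_along(sim$recordings[[par]])) {
      for (tp in tps) {
        tm <- sim$recordings[[par]][[an]][[tp]]
        dm <- compute_dff_matrix(tm, p$baseline_half_window_s)
        stim <- tm$events$time_s
        vecs <- lapply(stim, function(s)
          response_vector(dm, s, summary = p$response_summary,
                          window_s = p$response_window_s))
        occ <- vapply(stim, function(s)
          apply(dm$dff, 1, detect_occurrence, fps = dm$fps,
                stim_time_s = s, response_window_s = p$occurrence_window_s,
                k_sd = p$occurrence_k_sd),
          logical(nrow(dm$dff)))
        summed <- vapply(stim, function(s)
          apply(dm$dff, 1, function(tr)
            summed_response(tr, dm$fps, c(s, s + p$summed_window_s))$summed_dff),
          numeric(nrow(dm$dff)))
        peak_cell <- rowMeans(do.call(cbind, vecs))
        tau <- rep(NA_real_, nrow(dm$dff))
        if (isTRUE(p$fit_tau)) {
          for (i in seq_len(nrow(dm$dff))) {
            pk <- peak_response(dm$dff[i, ], dm$fps,
                                c(stim[1], stim[1] + p$response_window_s))
            pk_idx <- round(pk$peak_time_s * dm$fps) + 1L
            tau[i] <- tryCatch(
              fit_decay(dm$dff[i, ], dm$fps, pk_idx,
                        decay_fit_window(dm$dff[i, ], dm$fps, pk_idx))$tau_s,
              error = function(e) NA_real_)
          }
        }
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          paradigm = par, animal = an, time_point = tp,
          cell_id = dm$cell_ids, peak_dff = peak_cell,
          summed_dff = rowMeans(summed), tau_s = tau,
          occurrence_rate = rowMeans(occ), stringsAsFactors = FALSE)
        sim_res <- tryCatch(pattern_similarity(vecs[[1]], vecs[[2]], vecs[[3]]),
                            error = function(e) NULL)
        alpha_res <- tryCatch(cronbach_alpha(t(occ) * 1),
                              error = function(e) NULL)
        animal_rows[[length(animal_rows) + 1L]] <- data.frame(
          paradigm = par, animal = an, time_point = tp,
          mean_dff = mean(peak_cell),
          pair_12 = if (is.null(sim_res)) NA else sim_res$pair_cosines["c12"],
          pair_23 = if (is.null(sim_res)) NA else sim_res$pair_cosines["c23"],
          pair_13 = if (is.null(sim_res)) NA else sim_res$pair_cosines["c13"],
          mean_cosine = if (is.null(sim_res)) NA else sim_res$mean_cosine,
          alpha = if (is.null(alpha_res)) NA else alpha_res$alpha,
          ci_low = if (is.null(alpha_res)) NA else alpha_res$ci95["low"],
          ci_high = if (is.null(alpha_res)) NA else alpha_res$ci95["high"],
          stringsAsFactors = FALSE)
        pop_rows[[length(pop_rows) + 1L]] <- data.frame(
          paradigm = par, animal = an, time_point = tp,
          time_s = dm$time_s, mean_dff = colMeans(dm$dff),
          stringsAsFactors = FALSE)
        if (is.null(example_dff) && tp == tps[length(tps)])
          example_dff <- dm
      }
    }
  }
  cell_metrics <- do.call(rbind, cell_rows)
  animal_summary <- do.call(rbind, animal_rows)
  rownames(animal_summary) <- NULL
  first_tp <- tps[1]; last_tp <- tps[length(tps)]
  wide <- merge(
    animal_summary[animal_summary$time_point == first_tp,
                   c("paradigm", "animal", "mean_dff")],
    animal_summary[animal_summary$time_point == last_tp,
                   c("paradigm", "animal", "mean_dff")],
    by = c("paradigm", "animal"), suffixes = c("_before", "_after"))
  wide$delta_dff <- wide$mean_dff_after - wide$mean_dff_before
  pop <- do.call(rbind, pop_rows)
  pop_agg <- stats::aggregate(mean_dff ~ paradigm + time_point + time_s,
                              data = pop, FUN = mean)
  pop_sem <- stats::aggregate(mean_dff ~ paradigm + time_point + time_s,
                              data = pop,
                              FUN = function(x) stats::sd(x) / sqrt(length(x)))
  names(pop_agg)[4] <- "mean"; pop_agg$sem <- pop_sem$mean_dff
  list(cell_metrics = cell_metrics, animal_summary = animal_summary,
       delta_dff = wide[, c("paradigm", "animal", "delta_dff")],
       population_traces = pop_agg, example_dff = example_dff,
       stim_times_s = sim$config$stim_times_s, params = p,
       time_points = tps)
}

#' Group-level inference tables
#'
#' Mixed (split-plot) repeated-measures ANOVA on the per-animal mean dF/F
#' and on the mean cosine similarity, Ryan's post hoc across time points
#' within each paradigm (tested against the within-subjects residual), and
#' a one-way ANOVA with Ryan's post hoc on the before-to-final dF/F change
#' across paradigms.
#'
#' @param analysis Output of [analyze_experiment()].
#' @param alpha Familywise significance level for post hoc tests.
#' @return A list of tables: `anova_dff`, `anova_similarity`,
#'   `posthoc_dff`, `posthoc_similarity`, `oneway_delta`, `posthoc_delta`.
#' @export
stats_tables <- function(analysis, alpha = 0.05) {
  asum <- analysis$animal_summary
  run_measure <- function(col) {
    d <- asum[, c("paradigm", "animal", "time_point")]
    d$value <- asum[[col]]
    tab <- mixed_anova(d)
    ms_res <- tab$ms[tab$effect == "residual"]
    df_res <- tab$df[tab$effect == "residual"]
    ph <- lapply(split(d, d$paradigm), function(dd) {
      m <- tapply(dd$value, dd$time_point, mean)[analysis$time_points]
      n <- as.integer(table(dd$time_point)[analysis$time_points])
      out <- ryan_posthoc(m, n, ms_res, df_res, alpha = alpha)
      out$paradigm <- dd$paradigm[1]
      out
    })
    list(anova = tab, posthoc = do.call(rbind, ph))
  }
  dff <- run_measure("mean_dff")
  simres <- run_measure("mean_cosine")
  delta <- analysis$delta_dff
  groups <- split(delta$delta_dff, delta$paradigm)
  ow <- oneway_anova(groups)
  ph_delta <- ryan_posthoc(ow$group_means, ow$n_per_group, ow$ms_error,
                           ow$df["df_den"], alpha = alpha)
  list(anova_dff = dff$anova, anova_similarity = simres$anova,
       posthoc_dff = dff$posthoc, posthoc_similarity = simres$posthoc,
       oneway_delta = data.frame(F = ow$F, df_num = ow$df["df_num"],
                                 df_den = ow$df["df_den"], p = ow$p,
                                 row.names = NULL),
       posthoc_delta = ph_delta)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generator -> dF/F -> per-cell metrics -> population
#' statistics -> group inference, writing all tables as CSV plus a JSON
#' run manifest. Deterministic given the seed: re-running with the same
#' configuration and seed reproduces byte-identical tables.
#'
#' @param config `NULL` for the demo configuration, a YAML file path, or a
#'   nested list with optional sections `sim` ([sim_config()] fields),
#'   `design` ([experiment_design()] fields) and `analysis`
#'   ([default_analysis_params()] fields).
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; overrides `config$sim$seed`.
#' @return Invisibly, a list with all tables and the manifest.
#' @export
run_pipeline <- function(config = NULL, outdir, seed = NULL) {
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim_cfg <- do.call(sim_config, cfg$sim)
  design <- do.call(experiment_design, cfg$design)
  sim <- simulate_experiment(design, sim_cfg)
  analysis <- analyze_experiment(sim, cfg$analysis)
  stats_out <- stats_tables(analysis,
                            alpha = utils::modifyList(
                              default_analysis_params(), cfg$analysis)$alpha)
  tables <- c(analysis[c("cell_metrics", "animal_summary", "delta_dff",
                         "population_traces")],
              stats_out)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  ex <- analysis$example_dff
  cellmap <- data.frame(cell_id = rep(ex$cell_ids, each = ncol(ex$dff)),
                        time_s = rep(ex$time_s, nrow(ex$dff)),
                        dff = as.vector(t(ex$dff)))
  utils::write.csv(cellmap, file.path(outdir, "cellmap.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_config_yaml(cfg, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = sim_cfg$seed,
    package_version = as.character(utils::packageVersion("calpop")),
    stim_times_s = analysis$stim_times_s,
    discard_initial_s = analysis$params$discard_initial_s,
    time_points = analysis$time_points,
    outputs = paste0(c(names(tables), "cellmap"), ".csv"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(tables, list(cellmap = cellmap, manifest = manifest,
                           analysis = analysis)))
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- read_config_yaml(config)
  if (is.null(config)) config <- list()      # empty YAML parses to NULL
  if (!is.list(config)) stop("config must be NULL, a path or a list")
  for (sec in c("sim", "design", "analysis"))
    if (is.null(config[[sec]])) config[[sec]] <- list()
  check_fields <- function(given, allowed, sec) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown config key: ", sec, "$", bad[1])
  }
  check_fields(config$sim, names(formals(sim_config)), "sim")
  check_fields(config$design, names(formals(experiment_design)), "design")
  check_fields(config$analysis, names(default_analysis_params()), "analysis")
  config
}

#' Render summary figures from a pipeline output directory
#'
#' Writes four PNG figures: the population-average dF/F trace with an SEM
#' band and stimulus markers, a cell-by-time dF/F colour map for an
#' example recording, the per-paradigm before-to-final dF/F change bar
#' chart, and the pattern-similarity time course with 95% confidence
#' intervals. The first `discard_initial_s` seconds are omitted from trace
#' displays.
#'
#' @param outdir Directory produced by [run_pipeline()].
#' @return Character vector of figure paths, invisibly.
#' @export
make_report <- function(outdir) {
  need <- c("population_traces.csv", "cellmap.csv", "delta_dff.csv",
            "animal_summary.csv", "manifest.json")
  absent <- need[!file.exists(file.path(outdir, need))]
  if (length(absent))
    stop("missing pipeline outputs: ", paste(absent, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE)
  t0 <- manifest$discard_initial_s
  tp_levels <- manifest$time_points
  pop <- utils::read.csv(file.path(outdir, "population_traces.csv"))
  if (!nrow(pop)) stop("empty cell set: no population traces")
  pop <- pop[pop$time_s >= t0, ]
  pop$time_point <- factor(pop$time_point, levels = tp_levels)
  figs <- character(0)
  gg <- ggplot2::ggplot(pop, ggplot2::aes(x = time_s, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                         fill = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = manifest$stim_times_s,
                        colour = "red", linetype = 2) +
    ggplot2::facet_grid(paradigm ~ time_point) +
    ggplot2::labs(x = "time (s)", y = "population mean dF/F")
  figs["population_average"] <- save_fig(gg, outdir, "population_average")
  cellmap <- utils::read.csv(file.path(outdir, "cellmap.csv"))
  if (!nrow(cellmap)) stop("empty cell set: no cell map")
  cellmap <- cellmap[cellmap$time_s >= t0, ]
  gg <- ggplot2::ggplot(cellmap, ggplot2::aes(time_s, factor(cell_id),
                                              fill = dff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "cell", fill = "dF/F")
  figs["cell_map"] <- save_fig(gg, outdir, "cell_map")
  delta <- utils::read.csv(file.path(outdir, "delta_dff.csv"))
  dsum <- stats::aggregate(delta_dff ~ paradigm, delta, mean)
  dsem <- stats::aggregate(delta_dff ~ paradigm, delta,
                           function(x) stats::sd(x) / sqrt(length(x)))
  dsum$sem <- dsem$delta_dff
  gg <- ggplot2::ggplot(dsum, ggplot2::aes(paradigm, delta_dff)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = delta_dff - sem,
                                        ymax = delta_dff + sem), width = 0.3) +
    ggplot2::labs(y = "dF/F (final - before)")
  figs["delta_dff"] <- save_fig(gg, outdir, "delta_dff")
  asum <- utils::read.csv(file.path(outdir, "animal_summary.csv"))
  asum$time_point <- factor(asum$time_point, levels = tp_levels)
  ssum <- stats::aggregate(mean_cosine ~ paradigm + time_point, asum, mean)
  sci <- stats::aggregate(mean_cosine ~ paradigm + time_point, asum,
                          function(x) stats::qt(0.975, length(x) - 1) *
                            stats::sd(x) / sqrt(length(x)))
  ssum$ci <- sci$mean_cosine
  gg <- ggplot2::ggplot(ssum, ggplot2::aes(time_point, mean_cosine,
                                           group = paradigm,
                                           colour = paradigm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_cosine - ci,
                                        ymax = mean_cosine + ci),
                           width = 0.2) +
    ggplot2::labs(y = "pattern similarity (mean cosine)", x = NULL)
  figs["similarity_timecourse"] <- save_fig(gg, outdir,
                                            "similarity_timecourse")
  invisible(figs)
}

save_fig <- function(gg, outdir, name) {
  path <- file.path(outdir, paste0(name, ".png"))
  suppressMessages(ggplot2::ggsave(path, gg, width = 8, height = 6, dpi = 120,
                                   device = grDevices::png))
  path
}
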