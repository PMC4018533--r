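#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults set to
#' the study's stated values where one exists: 50-200 ms analysis range in
#' 10-ms windows, 8-80 Hz grid in 3 Hz steps, 1000 trial shuffles, 1000
#' bootstrap resamples, 10000 sign-flip permutations, alpha 0.05. All
#' randomness derives from the single `seed` (per-stage seeds are drawn
#' from it at run time), so a rerun with the same config reproduces every
#' table exactly.
#'
#' @param design a [study_design()]
#' @param couplings list of [coupling_spec()]
#' @param behavioral a [behavioral_spec()]
#' @param grid a [frequency_grid()]
#' @param rejection a [rejection_criteria()] or `NULL` to skip rejection
#' @param analysis_window analysis range in ms (default c(50, 200))
#' @param window_width WPLI averaging bin width in ms (default 10)
#' @param pairs list of ROI pairs to analyze (default: all pairs)
#' @param n_shuffles surrogate trial orders (default 1000)
#' @param n_boot bootstrap resamples (default 1000)
#' @param n_perm sign-flip permutations (default 10000)
#' @param alpha significance level (default 0.05)
#' @param evoked_amplitude evoked component amplitude in the generator
#' @param sem_lag SEM lag in samples; `NULL` picks a quarter cycle at each
#'   effect's peak frequency
#' @param loop_nodes nodes for the loop-model comparison, or `NULL` to skip
#' @param seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(design = study_design(),
                            couplings = list(),
                            behavioral = behavioral_spec(),
                            grid = frequency_grid(),
                            rejection = NULL,
                            analysis_window = c(50, 200),
                            window_width = 10,
                            pairs = NULL,
                            n_shuffles = 1000,
                            n_boot = 1000,
                            n_perm = 10000,
                            alpha = 0.05,
                            evoked_amplitude = 1,
                            sem_lag = NULL,
                            loop_nodes = NULL,
                            seed = 1L) {
  structure(list(design = design, couplings = couplings,
                 behavioral = behavioral, grid = grid,
                 rejection = rejection,
                 analysis_window = analysis_window,
                 window_width = window_width, pairs = pairs,
                 n_shuffles = n_shuffles, n_boot = n_boot,
                 n_perm = n_perm, alpha = alpha,
                 evoked_amplitude = evoked_amplitude,
                 sem_lag = sem_lag, loop_nodes = loop_nodes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max, 6)
  names(s) <- c("synth", "equalize", "surrogate", "sem", "perm", "misc")
  s
}

#' Preprocess one subject's epochs into per-cell cleaned data
#'
#' Baseline correction over the prestimulus period, optional amplitude
#' rejection, split into condition x stimulus cells, and trial-count
#' equalization across the cells.
#'
#' @param epochs an [epoch_array()]
#' @param config a [pipeline_config()]
#' @param seed seed for the equalization subsampling
#' @return named list of per-cell `epoch_array` objects
#' @export
preprocess_subject <- function(epochs, config, seed = 1L) {
  ep <- baseline_correct(epochs,
                         c(epochs$time[1], 0))
  if (!is.null(config$rejection))
    ep <- reject_trials(ep, config$rejection)$epochs
  cells <- split_cells(ep)
  eq <- equalize_trial_counts(cells, seed = seed)
  names(eq) <- names(cells)
  eq
}

#' Per-subject windowed WPLI maps for every cell
#'
#' Morlet-transforms each cell (cropped to the analysis window) and
#' computes windowed WPLI for the configured pairs.
#'
#' @param cells named list of per-cell `epoch_array` objects
#' @param config a [pipeline_config()]
#' @param subject subject label for the metadata
#' @return list of `sync_map` objects, one per cell
#' @export
subject_sync_maps <- function(cells, config, subject = NA_character_) {
  lapply(names(cells), function(cell) {
    parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
    tf <- morlet_transform(cells[[cell]], config$grid,
                           time_range = config$analysis_window)
    sync_map(tf, pairs = config$pairs,
             window_range = config$analysis_window,
             width = config$window_width,
             meta = list(subject = subject, condition = parts[1],
                         stimulus = parts[2]))
  })
}

#' Run the full synthetic phase-synchrony pipeline
#'
#' Chains all stages: cohort generation, preprocessing, time-frequency
#' decomposition, windowed WPLI, group-level repeated-measures contrasts
#' with BH-FDR per test family, Spearman correlation of synchrony with
#' behavioral accuracy, trial-shuffle surrogate checks on the significant
#' effects, pairwise SEM directionality for the significant pairs, and
#' (optionally) the loop-model comparison. Every stage is a pure function
#' of (config, seed); reruns are reproducible.
#'
#' The behavioral accuracy entering the correlation is the proportion
#' correct for noisy syllables in the active condition, and the WPLI
#' correlated with it is taken from the matching active/noisy cell.
#'
#' @param config a [pipeline_config()]
#' @param verbose print stage progress
#' @return list of class `pipeline_report`: `group_table`, `effects`,
#'   `correlations`, `surrogates`, `directionality`, `model_ranking`,
#'   `accuracy`, `config`
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage 1/6: generating cohort (%d subjects)", config$design$n_subjects)
  cohort <- generate_cohort(config$design, config$couplings,
                            config$behavioral, seed = seeds["synth"],
                            evoked_amplitude = config$evoked_amplitude)
  accuracy <- vapply(cohort, function(s) s$accuracy, numeric(1))

  say("stage 2/6: preprocessing + time-frequency + WPLI")
  rows <- list()
  tf_noisy_active <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    cells <- preprocess_subject(cohort[[s]]$epochs, config,
                                seed = seeds["equalize"] %% 100000L + s)
    maps <- subject_sync_maps(cells, config,
                              subject = cohort[[s]]$epochs$subject)
    rows[[s]] <- do.call(rbind, lapply(maps, sync_map_to_df))
    na_cell <- which(names(cells) == "active.noisy")
    if (length(na_cell) == 1)
      tf_noisy_active[[s]] <- morlet_transform(
        cells[[na_cell]], config$grid, time_range = config$analysis_window)
  }
  group_table <- do.call(rbind, rows)
  group_table$accuracy <- accuracy[match(group_table$subject,
                                         vapply(cohort, function(s)
                                           s$epochs$subject, character(1)))]

  say("stage 3/6: group statistics")
  keys <- unique(group_table[, c("pair", "frequency", "window_start")])
  effects <- list(); correlations <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- group_table$pair == keys$pair[i] &
      group_table$frequency == keys$frequency[i] &
      group_table$window_start == keys$window_start[i]
    sub <- group_table[sel, ]
    if (anyNA(sub$wpli)) next
    aov2 <- rm_anova_2x2(data.frame(subject = sub$subject,
                                    condition = sub$condition,
                                    stimulus = sub$stimulus,
                                    value = sub$wpli))
    aov2$pair <- keys$pair[i]; aov2$frequency <- keys$frequency[i]
    aov2$window_start <- keys$window_start[i]
    pas <- sub[sub$condition == "passive", ]
    aov1 <- rm_anova_oneway(data.frame(subject = pas$subject,
                                       level = pas$stimulus,
                                       value = pas$wpli))
    aov1$effect <- "oneway_stimulus"
    aov1$pair <- keys$pair[i]; aov1$frequency <- keys$frequency[i]
    aov1$window_start <- keys$window_start[i]
    effects[[length(effects) + 1]] <- rbind(aov2, aov1)

    act <- sub[sub$condition == "active" & sub$stimulus == "noisy", ]
    act <- act[order(act$subject), ]
    # constant WPLI across subjects (e.g. saturated at 1) has no ranks
    ct <- tryCatch(spearman_correlation(act$wpli, act$accuracy),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    correlations[[length(correlations) + 1]] <-
      data.frame(pair = keys$pair[i], frequency = keys$frequency[i],
                 window_start = keys$window_start[i], r = ct$r, p = ct$p,
                 stringsAsFactors = FALSE)
  }
  effects <- do.call(rbind, effects)
  correlations <- do.call(rbind, correlations)
  # one FDR family per test type, across all pair x freq x window comparisons
  effects$p_fdr <- NA_real_
  for (e in unique(effects$effect)) {
    idx <- effects$effect == e
    effects$p_fdr[idx] <- fdr_correct(effects$p[idx])
  }
  correlations$p_fdr <- NA_real_
  ok <- !is.na(correlations$p)
  correlations$p_fdr[ok] <- fdr_correct(correlations$p[ok])

  say("stage 4/6: surrogate checks on significant effects")
  sig_corr <- correlations[correlations$p_fdr < config$alpha, , drop = FALSE]
  surrogates <- NULL
  if (nrow(sig_corr) > 0 && config$n_shuffles > 0) {
    top <- sig_corr[order(sig_corr$p_fdr), , drop = FALSE][1, ]
    pair <- strsplit(top$pair, "--", fixed = TRUE)[[1]]
    sres <- surrogate_correlation_test(
      tf_noisy_active, accuracy, pair,
      n_shuffles = config$n_shuffles, seed = seeds["surrogate"],
      freq_range = rep(top$frequency, 2),
      window_range = c(top$window_start, top$window_start + config$window_width),
      width = config$window_width)
    surrogates <- data.frame(pair = top$pair, frequency = top$frequency,
                             window_start = top$window_start,
                             statistic = "spearman_r",
                             observed = sres$observed, p = sres$p_value,
                             stringsAsFactors = FALSE)
  }

  say("stage 5/6: pairwise SEM directionality")
  directionality <- NULL
  if (!is.null(sig_corr) && nrow(sig_corr) > 0) {
    top <- sig_corr[order(sig_corr$p_fdr), , drop = FALSE][1, ]
    pair <- strsplit(top$pair, "--", fixed = TRUE)[[1]]
    lag <- config$sem_lag
    if (is.null(lag))
      lag <- max(1L, round(config$design$sampling_rate /
                             (4 * top$frequency)))
    signals <- lapply(tf_noisy_active, function(tf)
      extract_band_signal(tf, rep(top$frequency, 2),
                          config$analysis_window, rois = pair))
    set.seed(seeds["sem"])
    pd <- fit_pairwise(signals, pair, lag, n_boot = config$n_boot,
                       n_perm = config$n_perm, seed = seeds["perm"])
    directionality <- data.frame(
      pair = top$pair, lag = lag, t = pd$t, p = pd$p,
      mean_beta_ab = mean(pd$beta_ab), mean_beta_ba = mean(pd$beta_ba),
      stringsAsFactors = FALSE)
  }

  say("stage 6/6: loop-model comparison")
  model_ranking <- NULL
  if (!is.null(config$loop_nodes)) {
    lag <- if (is.null(config$sem_lag)) 12L else config$sem_lag
    models <- enumerate_loop_models(config$loop_nodes, lag = lag)
    freq_range <- range(config$grid$freqs)
    fits <- lapply(models, function(m) {
      lapply(tf_noisy_active, function(tf) {
        sig <- extract_band_signal(tf, freq_range, config$analysis_window,
                                   rois = config$loop_nodes)
        fit_loop_model(m, sig, lag = lag)
      })
    })
    model_ranking <- compare_models(fits)
  }

  structure(list(group_table = group_table, effects = effects,
                 correlations = correlations, surrogates = surrogates,
                 directionality = directionality,
                 model_ranking = model_ranking,
                 accuracy = accuracy, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d group-table rows; %d effect tests; %d correlations\n",
              nrow(x$group_table), NROW(x$effects), NROW(x$correlations)))
  nsig <- sum(x$effects$p_fdr < x$config$alpha, na.rm = TRUE)
  cat(sprintf("  FDR-significant effects: %d; correlations: %d\n", nsig,
              sum(x$correlations$p_fdr < x$config$alpha, na.rm = TRUE)))
  if (!is.null(x$directionality))
    cat(sprintf("  directionality: %s t = %.2f, p = %.3g\n",
                x$directionality$pair, x$directionality$t,
                x$directionality$p))
  if (!is.null(x$model_ranking))
    cat(sprintf("  best loop model: %s (mean RMSEA %.3f)\n",
                x$model_ranking$model[1], x$model_ranking$mean_rmsea[1]))
  invisible(x)
}

#' Write a pipeline report to CSV/JSON files
#'
#' @param report a `pipeline_report`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name) {
    if (is.null(obj)) return()
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$group_table, "group_table.csv")
  wr(report$effects, "effects.csv")
  wr(report$correlations, "correlations.csv")
  wr(report$surrogates, "surrogates.csv")
  wr(report$directionality, "directionality.csv")
  wr(report$model_ranking, "model_ranking.csv")
  invisible(paths)
}
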