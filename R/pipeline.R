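# End-to-end orchestration: simulate -> wavelet features -> biomarker ->
# band powers -> trial summaries -> statistical battery -> report files.

#' Pretrain the feature bank and load biomarker on a calibration corpus
#'
#' Generates the labeled high-/low-load corpus, prunes the wavelet-packet
#' tree to the feature bank by median-energy ranking, trains the LDA
#' biomarker on the pooled per-second features, and fixes the 1-100
#' normalization on the calibration raw scores.
#'
#' @param config a [run_config()]
#' @param seed corpus seed (defaults to the scenario seed)
#' @return list: `baf_spec`, `model`, `corpus_features`, `corpus_labels`,
#'   `segment_id`
#' @export
pretrain_biomarker <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config$scenario$seed
  corpus <- generate_calibration_corpus(
    config$calibration_n, seed = seed,
    duration_s = config$calibration_duration_s,
    eeg_noise_sd = config$scenario$eeg_noise_sd)
  filter <- build_filter_pair(config$filter)
  trees <- lapply(corpus$recordings, function(r) {
    n_sec <- floor(length(r$samples) / r$fs)
    epochs <- pad_dyadic(matrix(r$samples[seq_len(n_sec * r$fs)],
                                nrow = r$fs),
                         2^ceiling(log2(r$fs)))
    wp_decompose(epochs, filter, config$max_depth)
  })
  baf_spec <- prune_to_baf(trees, k = config$k_features)
  feats <- lapply(corpus$recordings, baf_extract, spec = baf_spec)
  rows_per <- vapply(feats, function(f) nrow(f$values), numeric(1))
  X <- do.call(rbind, lapply(feats, function(f) f$values))
  labels <- rep(corpus$labels, rows_per)
  segment_id <- rep(seq_along(feats), rows_per)
  model <- train_load_biomarker(X, labels, transfer = config$transfer)
  model <- calibrate_biomarker(model, X, probs = config$norm_probs)
  list(baf_spec = baf_spec, model = model, corpus_features = X,
       corpus_labels = labels, segment_id = segment_id)
}

#' Per-trial dependent-variable summaries of a cohort
#'
#' Runs both feature banks over every recording and joins them with the
#' behavioral records: one row per participant x trial with accuracy,
#' economy, time, the normalized biomarker (`vc9`) and the per-band powers.
#'
#' @param cohort a [generate_cohort()] result
#' @param baf_spec a [prune_to_baf()] feature bank
#' @param model a calibrated [train_load_biomarker()] model
#' @param bands band definitions (default [default_bands()])
#' @return data frame of trial summaries
#' @export
cohort_summaries <- function(cohort, baf_spec, model,
                             bands = default_bands()) {
  rows <- lapply(seq_len(nrow(cohort$records)), function(i) {
    rec <- cohort$recordings[[i]]
    baf <- baf_extract(rec, baf_spec)
    scores <- predict(model, baf, type = "normalized")
    summarize_trial(band_powers(rec, bands), scores,
                    cohort$records[i, , drop = FALSE])
  })
  do.call(rbind, rows)
}

#' Run the trial-level statistical battery on a summary table
#'
#' Per dependent variable: Shapiro/Levene gating, then either the
#' dummy-coded mixed model (Wald inference, effect sizes) or paired
#' Wilcoxon trial contrasts. Mixed models are additionally fitted for every
#' EEG feature to drive the selection rule, and repeated-measures
#' correlations are computed between each EEG feature and each behavioral
#' measure.
#'
#' @param summaries a [cohort_summaries()] table
#' @param dvs dependent variables to gate and test
#' @param eeg_features EEG feature columns used for selection/correlation
#' @param behaviors behavioral columns used for correlation
#' @param alpha significance level
#' @return list: `gates`, `trial_tests` (gated results, Table-1-shaped for
#'   the LMM route), `lmm_fits` (all-DV fits), `rmcorr` table,
#'   `selected_features`
#' @export
analyze_summaries <- function(summaries,
                              dvs = c("accuracy", "economy", "time_s",
                                      "vc9", "theta", "delta"),
                              eeg_features = c("vc9", "theta", "delta",
                                               "alpha", "beta", "gamma"),
                              behaviors = c("accuracy", "economy", "time_s"),
                              alpha = 0.05) {
  eeg_features <- intersect(eeg_features, names(summaries))
  all_fit_dvs <- union(dvs, eeg_features)
  lmm_fits <- lapply(all_fit_dvs, function(dv) fit_trial_lmm(summaries, dv))
  names(lmm_fits) <- all_fit_dvs

  gates <- list()
  tests <- list()
  for (dv in dvs) {
    groups <- split(summaries[[dv]], summaries$trial)
    gate <- withCallingHandlers(gate_test(groups, alpha = alpha),
                                warning = function(w) invokeRestart("muffleWarning"))
    gates[[dv]] <- data.frame(dv = dv,
                              shapiro_min_p = min(gate$shapiro_p, na.rm = TRUE),
                              levene_p = gate$levene_p,
                              chosen_test = gate$chosen_test)
    if (gate$chosen_test == "lmm") {
      tab <- lmm_fits[[dv]]$table
      tests[[dv]] <- data.frame(dv = dv, test = "lmm", tab)
    } else {
      by_p <- split(summaries, summaries$participant)
      vals <- function(t) vapply(by_p, function(g) g[[dv]][g$trial == t],
                                 numeric(1))
      w2 <- suppressWarnings(wilcoxon_paired(vals(2), vals(1)))
      w3 <- suppressWarnings(wilcoxon_paired(vals(3), vals(1)))
      tests[[dv]] <- data.frame(
        dv = dv, test = "wilcoxon",
        effect = c("trial2_vs_1", "trial3_vs_1"),
        coef = NA_real_, std_err = NA_real_,
        z = c(w2$W, w3$W), p = c(w2$p, w3$p),
        ci_lo = NA_real_, ci_hi = NA_real_, d = NA_real_)
    }
  }

  rm_rows <- list()
  rmcorr_by_feature <- list()
  for (f in eeg_features) {
    fits <- lapply(behaviors, function(b) {
      rmcorr_fit(summaries$participant, summaries[[b]], summaries[[f]])
    })
    names(fits) <- behaviors
    rmcorr_by_feature[[f]] <- fits
    rm_rows[[f]] <- data.frame(
      feature = f, behavior = behaviors,
      r_rm = vapply(fits, function(x) x$r_rm, numeric(1)),
      df = vapply(fits, function(x) x$df, numeric(1)),
      p = vapply(fits, function(x) x$p, numeric(1)))
  }
  selected <- select_features(lmm_fits[eeg_features], rmcorr_by_feature,
                              alpha = alpha)
  list(gates = do.call(rbind, gates),
       trial_tests = do.call(rbind, tests),
       lmm_fits = lmm_fits,
       rmcorr = do.call(rbind, rm_rows),
       selected_features = selected)
}

log_stage <- function(con, stage, t0, seed, extra = "") {
  line <- sprintf("stage=%s seed=%d elapsed_s=%.2f %s", stage, seed,
                  as.numeric(proc.time()[3] - t0), extra)
  writeLines(line, con)
  invisible(line)
}

#' Run the full pipeline and write the artifact tree
#'
#' simulate -> pretrain biomarker -> extract features -> summarize ->
#' statistical battery, writing: `trial_records.csv`, `eeg/*.edf`
#' (optional), `biomarker_model.json`, `trial_summaries.csv`, `gates.csv`,
#' `lmm_fits.csv` (Table-1 schema), `trial_tests.csv`, `rmcorr_fits.csv`,
#' `selected_features.csv`, `config.json` and `run_log.txt`. Outputs are
#' fully determined by config + seed.
#'
#' @param config a [run_config()]
#' @param out_dir output directory (created if needed)
#' @param pretrained optional [pretrain_biomarker()] result to reuse
#' @return invisibly, a list with `summaries`, `analysis`, `baf_spec`,
#'   `model`, `cohort`
#' @export
run_pipeline <- function(config, out_dir, pretrained = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$scenario$seed
  log_path <- file.path(out_dir, "run_log.txt")
  con <- file(log_path, "w")
  on.exit(close(con))
  t0 <- proc.time()[3]

  write_run_config(config, file.path(out_dir, "config.json"))
  cohort <- generate_cohort(config$scenario)
  write_trial_records(cohort$records,
                      file.path(out_dir, "trial_records.csv"))
  log_stage(con, "simulate", t0, seed,
            sprintf("records=%d", nrow(cohort$records)))

  if (isTRUE(config$write_edf)) {
    edf_dir <- file.path(out_dir, "eeg")
    dir.create(edf_dir, showWarnings = FALSE)
    for (r in cohort$recordings) {
      fn <- sprintf("%s_%s_t%d.edf", r$trial_link$participant,
                    r$trial_link$experiment, r$trial_link$trial)
      write_eeg_edf(r, file.path(edf_dir, fn))
    }
    log_stage(con, "write_edf", t0, seed,
              sprintf("files=%d", length(cohort$recordings)))
  }

  if (is.null(pretrained)) pretrained <- pretrain_biomarker(config)
  write_biomarker_json(pretrained$model,
                       file.path(out_dir, "biomarker_model.json"))
  log_stage(con, "train_biomarker", t0, seed,
            sprintf("features=%d", pretrained$baf_spec$k))

  summaries <- cohort_summaries(cohort, pretrained$baf_spec,
                                pretrained$model, config$bands)
  utils::write.csv(summaries, file.path(out_dir, "trial_summaries.csv"),
                   row.names = FALSE)
  log_stage(con, "features", t0, seed, sprintf("rows=%d", nrow(summaries)))

  analysis <- analyze_summaries(summaries, alpha = config$alpha)
  utils::write.csv(analysis$gates, file.path(out_dir, "gates.csv"),
                   row.names = FALSE)
  lmm_tab <- do.call(rbind, lapply(names(analysis$lmm_fits), function(dv) {
    data.frame(experiment = config$scenario$experiment_id, feature = dv,
               analysis$lmm_fits[[dv]]$table)
  }))
  utils::write.csv(lmm_tab, file.path(out_dir, "lmm_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$trial_tests,
                   file.path(out_dir, "trial_tests.csv"), row.names = FALSE)
  utils::write.csv(analysis$rmcorr, file.path(out_dir, "rmcorr_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(feature = analysis$selected_features),
                   file.path(out_dir, "selected_features.csv"),
                   row.names = FALSE)
  log_stage(con, "analyze", t0, seed,
            sprintf("selected=%s",
                    paste(analysis$selected_features, collapse = "+")))

  invisible(list(summaries = summaries, analysis = analysis,
                 baf_spec = pretrained$baf_spec, model = pretrained$model,
                 cohort = cohort))
}

#' Compare the last trial of one run with the first trial of another
#'
#' Convenience wrapper producing the Table-2-shaped session comparison for
#' participants present in both summary tables.
#'
#' @param summaries_first summaries of the earlier session
#' @param summaries_second summaries of the later session
#' @param ... passed to [compare_sessions()]
#' @return data frame: feature, test, statistic, p
#' @export
compare_experiment_sessions <- function(summaries_first, summaries_second,
                                        ...) {
  last_trial <- max(summaries_first$trial)
  a <- summaries_first[summaries_first$trial == last_trial, ]
  b <- summaries_second[summaries_second$trial == 1, ]
  shared <- intersect(a$participant, b$participant)
  compare_sessions(a[a$participant %in% shared, ],
                   b[b$participant %in% shared, ], ...)
}
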