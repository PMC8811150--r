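# Shared small fixtures and a cross-file cache for expensive ensembles.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# A small, fast configuration used by unit tests (not the study defaults).
tiny_config <- function(seed = 1, ...) {
  run_config(
    scenario = load_scenario(n_participants = 4, regime = "same_session",
                             trial_duration_s = 6, seed = seed, ...),
    calibration_n = 6, calibration_duration_s = 4, write_edf = FALSE)
}

# Pretrained bank + biomarker at the study's calibration defaults
# (50 segments/class, 10 s each); shared by biomarker and acceptance tests.
default_pretrained <- function() {
  cached("pretrained_default", {
    cfg <- run_config(scenario_same_session(seed = 20260101))
    pretrain_biomarker(cfg, seed = 20260101)
  })
}

# Trial summaries of one synthetic cohort under a pretrained model.
make_summaries <- function(scenario, pretrained = default_pretrained()) {
  cohort <- generate_cohort(scenario)
  cohort_summaries(cohort, pretrained$baf_spec, pretrained$model)
}

# Simulated trial-summary table at the summary level (no EEG): dv = mu +
# subject offset + trial effects + residual noise.
simulate_summary_table <- function(n = 19, beta2 = -1.5, beta3 = -1.75,
                                   sd_subj = 4, sd_resid = 2, mu = 50,
                                   seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant = sprintf("P%02d", seq_len(n)), trial = 1:3,
                   stringsAsFactors = FALSE)
  off <- stats::setNames(stats::rnorm(n, 0, sd_subj), unique(d$participant))
  d$y <- mu + off[d$participant] + beta2 * (d$trial == 2) +
    beta3 * (d$trial == 3) + stats::rnorm(nrow(d), 0, sd_resid)
  d
}
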