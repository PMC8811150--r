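# Seeded synthetic cohorts: latent load trajectories, single-channel
# frontal EEG with load-dependent delta/theta content, and coupled
# behavioral scores, emulating three-trial simulator-training experiments.

#' Define a simulated training scenario
#'
#' A scenario fixes everything about one synthetic experiment: cohort size,
#' the trial-scheduling regime, the latent-load trajectory, noise levels and
#' the trial length. Three regimes are supported: `same_session` (three
#' back-to-back trials, load decays with practice), `next_day` (a follow-up
#' session after performance has plateaued; load frozen at the final level
#' of a first-day session) and `daily` (one trial per day; the load
#' trajectory follows the same decaying form, and `offline_gain_per_trial`
#' can add consolidation gains to behavior that are not mediated by load).
#'
#' @param n_participants cohort size
#' @param regime `"same_session"`, `"next_day"` or `"daily"`
#' @param trials_per_participant trials per participant (default 3)
#' @param load_start latent load on trial 1, in (0, 1]
#' @param load_decay_per_trial load drop per repetition (>= 0)
#' @param between_subject_sd SD of the per-participant load offset
#' @param eeg_noise_sd white sensor-noise SD, microvolts
#' @param behav_noise_sd behavioral score noise SD, percent points (time
#'   noise is `2.5 *` this value, in seconds)
#' @param offline_gain_per_trial percent points of load-independent
#'   behavioral improvement per repetition (default 0); time improves by
#'   `2.5 *` this value in seconds
#' @param trial_duration_s trial length in seconds (default 144, the mean
#'   task-completion time the analysis is built around)
#' @param experiment_id label stored in the emitted records
#' @param seed base integer seed; all draws are derived from it
#' @return an object of class `load_scenario`
#' @examples
#' sc <- load_scenario(n_participants = 19, regime = "same_session", seed = 1)
#' @export
load_scenario <- function(n_participants,
                          regime = c("same_session", "next_day", "daily"),
                          trials_per_participant = 3,
                          load_start = 0.85,
                          load_decay_per_trial = 0.25,
                          between_subject_sd = 0.05,
                          eeg_noise_sd = 2,
                          behav_noise_sd = 4,
                          offline_gain_per_trial = 0,
                          trial_duration_s = 144,
                          experiment_id = NULL,
                          seed = 1) {
  regime <- match.arg(regime)
  if (n_participants < 1) stopf("n_participants must be >= 1")
  if (trials_per_participant < 1) stopf("trials_per_participant must be >= 1")
  if (load_start <= 0 || load_start > 1) stopf("load_start must be in (0, 1]")
  if (load_decay_per_trial < 0) stopf("load_decay_per_trial must be >= 0")
  if (trial_duration_s < 2) stopf("trial_duration_s must be >= 2 s")
  if (between_subject_sd < 0 || eeg_noise_sd < 0 || behav_noise_sd < 0) {
    stopf("noise SDs must be >= 0")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_participant = as.integer(trials_per_participant),
    regime = regime,
    load_start = load_start,
    load_decay_per_trial = load_decay_per_trial,
    between_subject_sd = between_subject_sd,
    eeg_noise_sd = eeg_noise_sd,
    behav_noise_sd = behav_noise_sd,
    offline_gain_per_trial = offline_gain_per_trial,
    trial_duration_s = trial_duration_s,
    experiment_id = if (is.null(experiment_id)) regime else experiment_id,
    seed = as.integer(seed)
  ), class = "load_scenario")
}

#' @export
print.load_scenario <- function(x, ...) {
  cat(sprintf(
    "Load scenario '%s': %d participants x %d trials (%s), %g s trials\n",
    x$experiment_id, x$n_participants, x$trials_per_participant, x$regime,
    x$trial_duration_s))
  cat(sprintf("  load %.2f - %.2f/trial (subject SD %.2f), seed %d\n",
              x$load_start, x$load_decay_per_trial, x$between_subject_sd,
              x$seed))
  invisible(x)
}

# Preset scenarios mirroring the three experiments: 19 participants with
# three same-session trials; 10 returning participants at plateau the next
# day; 19 new participants with one trial per day and consolidation gains.

#' @rdname load_scenario
#' @export
scenario_same_session <- function(seed = 1, n_participants = 19, ...) {
  load_scenario(n_participants = n_participants, regime = "same_session",
                experiment_id = "exp1", seed = seed, ...)
}

#' @rdname load_scenario
#' @export
scenario_next_day <- function(seed = 1, n_participants = 10, ...) {
  load_scenario(n_participants = n_participants, regime = "next_day",
                experiment_id = "exp2", seed = seed, ...)
}

#' @rdname load_scenario
#' @export
scenario_daily <- function(seed = 1, n_participants = 19, ...) {
  load_scenario(n_participants = n_participants, regime = "daily",
                load_decay_per_trial = 0, offline_gain_per_trial = 10,
                experiment_id = "exp3", seed = seed, ...)
}

participant_ids <- function(scenario) {
  sprintf("P%02d", seq_len(scenario$n_participants))
}

# Per-participant load offset, deterministic in (seed, participant).
subject_load_offset <- function(scenario, participant) {
  if (scenario$between_subject_sd == 0) return(0)
  with_seed(mix_seed(scenario$seed, participant, 101),
            stats::rnorm(1, 0, scenario$between_subject_sd))
}

#' Latent cognitive load of one trial
#'
#' `same_session` and `daily` regimes follow a linearly decaying practice
#' curve, `load_start - (trial - 1) * load_decay_per_trial`; the `next_day`
#' regime freezes load at the final (plateau) level of that curve, modelling
#' a session run after performance has ceiled. A per-participant offset with
#' SD `between_subject_sd` shifts the whole trajectory; the result is
#' clipped to [0, 1].
#'
#' @param scenario a [load_scenario()]
#' @param participant participant id (string or index)
#' @param trial trial index in 1..trials_per_participant
#' @return latent load in [0, 1]
#' @examples
#' sc <- load_scenario(1, "same_session", load_start = 0.9,
#'                     load_decay_per_trial = 0.2, between_subject_sd = 0)
#' load_trajectory(sc, "P01", 3) # 0.5
#' @export
load_trajectory <- function(scenario, participant, trial) {
  if (trial < 1 || trial > scenario$trials_per_participant) {
    stopf("trial %d out of range 1..%d", trial,
          scenario$trials_per_participant)
  }
  base <- scenario$load_start + subject_load_offset(scenario, participant)
  lvl <- switch(scenario$regime,
    same_session = ,
    daily = base - (trial - 1) * scenario$load_decay_per_trial,
    next_day = base - (scenario$trials_per_participant - 1) *
      scenario$load_decay_per_trial)
  clip(lvl, 0, 1)
}

#' Default spectral recipe of the EEG generator
#'
#' Band-limited noise components on a pink (1/f) background. The delta and
#' theta RMS amplitudes are affine increasing in latent load — the coupling
#' direction both bands show with working-memory load — while alpha and beta
#' are load-independent.
#'
#' @return list of component definitions (`lo`, `hi` Hz; `base_rms`
#'   microvolts; `load_gain` per unit load) plus `pink_rms`
#' @export
default_eeg_recipe <- function() {
  list(
    delta = list(lo = 0.5, hi = 4, base_rms = 5, load_gain = 1.2),
    theta = list(lo = 4, hi = 7, base_rms = 4, load_gain = 1.5),
    alpha = list(lo = 8, hi = 12, base_rms = 4, load_gain = 0),
    beta = list(lo = 13, hi = 30, base_rms = 2, load_gain = 0),
    pink_rms = 8
  )
}

#' Closed-form RMS of one generated band component
#'
#' @param recipe a [default_eeg_recipe()]-shaped list
#' @param band component name (`"delta"`, `"theta"`, ...)
#' @param load latent load in [0, 1]
#' @return RMS amplitude in microvolts
#' @export
band_component_rms <- function(recipe, band, load) {
  comp <- recipe[[band]]
  comp$base_rms * (1 + comp$load_gain * load)
}

# Gaussian noise with support confined to [lo, hi) Hz, exact target RMS.
# Built in the frequency domain: random phases/amplitudes on the in-band
# bins, Hermitian symmetry, inverse FFT.
band_noise <- function(n, fs, lo, hi, rms) {
  if (rms <= 0) return(numeric(n))
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(floor(n / 2) + 1) # positive-frequency bins
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  sel <- half[freqs[half] >= lo & freqs[half] < hi]
  spec[sel] <- complex(real = stats::rnorm(length(sel)),
                       imaginary = stats::rnorm(length(sel)))
  if (n %% 2 == 0) {
    spec[n / 2 + 1] <- complex(real = Re(spec[n / 2 + 1]), imaginary = 0)
  }
  spec[seq(floor(n / 2) + 2, n)] <- Conj(spec[seq(floor(n / 2), 2)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) return(numeric(n))
  x * rms / s
}

# 1/f-amplitude background noise over [lo, fs/2), exact target RMS.
pink_noise <- function(n, fs, rms, lo = 0.5) {
  if (rms <= 0) return(numeric(n))
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(floor(n / 2) + 1)
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  sel <- half[freqs[half] >= lo]
  amp <- 1 / sqrt(freqs[sel])
  spec[sel] <- complex(real = stats::rnorm(length(sel)),
                       imaginary = stats::rnorm(length(sel))) * amp
  if (n %% 2 == 0) {
    spec[n / 2 + 1] <- complex(real = Re(spec[n / 2 + 1]), imaginary = 0)
  }
  spec[seq(floor(n / 2) + 2, n)] <- Conj(spec[seq(floor(n / 2), 2)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

#' Construct an EEG recording object
#'
#' @param samples voltage series, microvolts
#' @param fs sampling rate, Hz
#' @param channels channel labels (default the referenced forehead
#'   derivation `"Fp1-Fpz"`)
#' @param trial_link optional list(participant, experiment, trial)
#' @return object of class `eeg_recording`
#' @export
eeg_recording <- function(samples, fs = 500, channels = "Fp1-Fpz",
                          trial_link = NULL) {
  if (!all(is.finite(samples))) stopf("EEG samples must be finite")
  if (fs <= 0) stopf("fs must be positive")
  structure(list(samples = as.numeric(samples), fs = fs,
                 channels = channels, trial_link = trial_link),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %.1f s at %g Hz (%s)\n",
              length(x$samples) / x$fs, x$fs,
              paste(x$channels, collapse = ", ")))
  if (!is.null(x$trial_link)) {
    cat(sprintf("  trial: %s / %s / %s\n", x$trial_link$participant,
                x$trial_link$experiment, x$trial_link$trial))
  }
  invisible(x)
}

#' Synthesize one trial's single-channel EEG
#'
#' Sum of a pink broadband background, band-limited delta and theta
#' components whose RMS amplitudes increase affinely with latent load,
#' load-independent alpha and beta components, and white sensor noise.
#' Deterministic given the seed.
#'
#' @param load latent load in [0, 1]
#' @param duration_s trial length, seconds (>= 2)
#' @param fs sampling rate (default 500 Hz)
#' @param seed integer seed
#' @param eeg_noise_sd white-noise SD, microvolts
#' @param recipe spectral recipe, see [default_eeg_recipe()]
#' @param trial_link optional trial identifier list
#' @return an [eeg_recording()] of `round(fs * duration_s)` samples
#' @export
synthesize_eeg <- function(load, duration_s, fs = 500, seed = 1,
                           eeg_noise_sd = 2, recipe = default_eeg_recipe(),
                           trial_link = NULL) {
  if (!is.finite(load) || load < 0 || load > 1) {
    stopf("load must be finite and in [0, 1]")
  }
  if (duration_s < 2) stopf("duration_s must be >= 2 s")
  n <- round(fs * duration_s)
  x <- with_seed(seed, {
    out <- pink_noise(n, fs, recipe$pink_rms)
    for (band in c("delta", "theta", "alpha", "beta")) {
      comp <- recipe[[band]]
      out <- out + band_noise(n, fs, comp$lo, comp$hi,
                              band_component_rms(recipe, band, load))
    }
    if (eeg_noise_sd > 0) out <- out + stats::rnorm(n, 0, eeg_noise_sd)
    out
  })
  eeg_recording(x, fs = fs, trial_link = trial_link)
}

# Behavioral anchor coefficients: performance at zero load and the linear
# cost of load, in the simulator's units.
.behav_anchors <- list(
  accuracy = list(best = 95, load_slope = 45),
  economy = list(best = 85, load_slope = 50),
  time_s = list(best = 110, load_slope = 100)
)

#' Behavioral scores generated from latent load
#'
#' Accuracy and economy of movement are affine decreasing in load, task time
#' affine increasing; Gaussian noise is added and percentages are clipped to
#' [0, 100] (time floored at 10 s). `offline_gain_per_trial` adds
#' load-independent improvement across repetitions.
#'
#' @param load latent load in [0, 1]
#' @param scenario a [load_scenario()] (noise SD and offline gain)
#' @param seed integer seed
#' @param trial trial index (default 1), used only for the offline gain
#' @param anchors affine anchor list (best-performance value and load slope
#'   per measure)
#' @return named numeric vector: `accuracy`, `economy`, `time_s`
#' @export
behavioral_from_load <- function(load, scenario, seed = 1, trial = 1,
                                 anchors = .behav_anchors) {
  if (!is.finite(load) || load < 0 || load > 1) {
    stopf("load must be finite and in [0, 1]")
  }
  gain <- scenario$offline_gain_per_trial * (trial - 1)
  mu_acc <- anchors$accuracy$best - anchors$accuracy$load_slope * load + gain
  mu_eco <- anchors$economy$best - anchors$economy$load_slope * load + gain
  mu_time <- anchors$time_s$best + anchors$time_s$load_slope * load -
    2.5 * gain
  sdb <- scenario$behav_noise_sd
  draws <- with_seed(seed, stats::rnorm(3))
  c(accuracy = clip(mu_acc + sdb * draws[1], 0, 100),
    economy = clip(mu_eco + sdb * draws[2], 0, 100),
    time_s = max(mu_time + 2.5 * sdb * draws[3], 10))
}

#' Generate a full synthetic cohort
#'
#' One trial record and one EEG recording per participant x trial. The
#' latent load driving each trial is stored in the records for recovery
#' tests; it would be absent from real data.
#'
#' @param scenario a [load_scenario()]
#' @return list with `records` (data frame: participant, experiment, trial,
#'   accuracy, economy, time_s, latent_load) and `recordings` (list of
#'   [eeg_recording()], in record order)
#' @examples
#' coh <- generate_cohort(load_scenario(3, "same_session",
#'                                      trial_duration_s = 4, seed = 7))
#' nrow(coh$records) # 9
#' @export
generate_cohort <- function(scenario) {
  pids <- participant_ids(scenario)
  grid <- expand.grid(trial = seq_len(scenario$trials_per_participant),
                      participant = pids, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant, grid$trial), ]
  recs <- vector("list", nrow(grid))
  eegs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$participant[i]
    t <- grid$trial[i]
    load <- load_trajectory(scenario, p, t)
    link <- list(participant = p, experiment = scenario$experiment_id,
                 trial = t)
    # the experiment id enters the trial-noise seeds (a person's two
    # sessions are independent realizations) but not the subject offset
    # (the same person keeps their load offset across experiments)
    eegs[[i]] <- synthesize_eeg(load, scenario$trial_duration_s,
                                seed = mix_seed(scenario$seed,
                                                scenario$experiment_id,
                                                p, t, 1),
                                eeg_noise_sd = scenario$eeg_noise_sd,
                                trial_link = link)
    beh <- behavioral_from_load(load, scenario,
                                seed = mix_seed(scenario$seed,
                                                scenario$experiment_id,
                                                p, t, 2),
                                trial = t)
    recs[[i]] <- data.frame(participant = p,
                            experiment = scenario$experiment_id,
                            trial = t,
                            accuracy = unname(beh["accuracy"]),
                            economy = unname(beh["economy"]),
                            time_s = unname(beh["time_s"]),
                            latent_load = load)
  }
  list(records = do.call(rbind, recs), recordings = eegs)
}

#' Generate a labeled high-/low-load calibration corpus
#'
#' Emulates the external labeled data a load biomarker is trained on: EEG
#' segments recorded under a demanding task (high load, latent load drawn
#' uniformly in [0.8, 1]) and an easy task (low load, in [0, 0.2]), with
#' balanced classes.
#'
#' @param n_segments_per_class segments per class (>= 1)
#' @param seed integer seed
#' @param duration_s segment length, seconds (default 10)
#' @param fs sampling rate (default 500)
#' @param eeg_noise_sd white-noise SD (default 2)
#' @return list with `recordings` (list of [eeg_recording()]), `labels`
#'   (character, `"high_load"`/`"low_load"`) and `loads` (latent truth)
#' @export
generate_calibration_corpus <- function(n_segments_per_class, seed = 1,
                                        duration_s = 10, fs = 500,
                                        eeg_noise_sd = 2) {
  if (n_segments_per_class < 1) stopf("need at least one segment per class")
  n <- n_segments_per_class
  labels <- rep(c("high_load", "low_load"), each = n)
  loads <- numeric(2 * n)
  recs <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    lo_hi <- if (labels[i] == "high_load") c(0.8, 1) else c(0, 0.2)
    loads[i] <- with_seed(mix_seed(seed, i, 301),
                          stats::runif(1, lo_hi[1], lo_hi[2]))
    recs[[i]] <- synthesize_eeg(loads[i], duration_s, fs = fs,
                                seed = mix_seed(seed, i, 302),
                                eeg_noise_sd = eeg_noise_sd)
  }
  list(recordings = recs, labels = labels, loads = loads)
}
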