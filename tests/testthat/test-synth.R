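test_that("load trajectories follow the practice curve and clip", {
  sc <- load_scenario(1, "same_session", load_start = 0.9,
                      load_decay_per_trial = 0.2, between_subject_sd = 0)
  expect_equal(load_trajectory(sc, "P01", 1), 0.9)
  expect_equal(load_trajectory(sc, "P01", 3), 0.5)
  # zero decay leaves load identical across trials
  sc0 <- load_scenario(1, "same_session", load_decay_per_trial = 0,
                       between_subject_sd = 0)
  expect_equal(load_trajectory(sc0, "P01", 1), load_trajectory(sc0, "P01", 3))
  # clipping at the floor
  scl <- load_scenario(1, "same_session", load_start = 0.3,
                       load_decay_per_trial = 0.2, between_subject_sd = 0)
  expect_equal(load_trajectory(scl, "P01", 3), 0)
  expect_error(load_trajectory(sc, "P01", 4), "out of range")
})

test_that("next_day regime sits at the plateau of the practice curve", {
  sc <- load_scenario(5, "next_day", load_start = 0.9,
                      load_decay_per_trial = 0.2, between_subject_sd = 0)
  for (t in 1:3) expect_equal(load_trajectory(sc, "P02", t), 0.5)
})

test_that("scenario validation rejects impossible parameters", {
  expect_error(load_scenario(0, "daily"), "n_participants")
  expect_error(load_scenario(3, "daily", load_start = 1.4), "load_start")
  expect_error(load_scenario(3, "daily", trial_duration_s = 1), ">= 2")
})

test_that("synthesized EEG honours the length and determinism contracts", {
  rec <- synthesize_eeg(0.5, 144, fs = 500, seed = 7)
  expect_equal(length(rec$samples), 72000)
  rec2 <- synthesize_eeg(0.5, 144, fs = 500, seed = 7)
  expect_identical(rec$samples, rec2$samples)
  expect_error(synthesize_eeg(NaN, 10), "finite")
  expect_error(synthesize_eeg(0.5, 1), ">= 2")
})

test_that("theta-band RMS increases strictly with load at zero sensor noise", {
  hi <- synthesize_eeg(1, 20, seed = 3, eeg_noise_sd = 0)
  lo <- synthesize_eeg(0, 20, seed = 3, eeg_noise_sd = 0)
  expect_gt(periodogram_band_power(hi$samples, 500, 4, 7),
            periodogram_band_power(lo$samples, 500, 4, 7))
  expect_gt(periodogram_band_power(hi$samples, 500, 0.5, 4),
            periodogram_band_power(lo$samples, 500, 0.5, 4))
})

test_that("generated band power matches the configured closed form", {
  # isolate the theta component: periodogram-integrated power within 10%
  # of the analytically configured RMS^2
  recipe <- default_eeg_recipe()
  recipe$pink_rms <- 0
  for (b in c("delta", "alpha", "beta")) recipe[[b]]$base_rms <- 0
  rec <- synthesize_eeg(0.5, 60, seed = 15, eeg_noise_sd = 0,
                        recipe = recipe)
  configured <- band_component_rms(default_eeg_recipe(), "theta", 0.5)^2
  measured <- periodogram_band_power(rec$samples, 500, 4, 7)
  expect_lt(abs(measured - configured) / configured, 0.10)
})

test_that("behavioral scores are affine in load with configured anchors", {
  sc <- load_scenario(1, "same_session", behav_noise_sd = 0)
  b0 <- behavioral_from_load(0, sc, seed = 1)
  expect_equal(unname(b0), c(95, 85, 110)) # best-performance anchors
  b_hi <- behavioral_from_load(0.8, sc, seed = 1)
  b_lo <- behavioral_from_load(0.2, sc, seed = 1)
  expect_lt(b_hi["accuracy"], b_lo["accuracy"])
  expect_lt(b_hi["economy"], b_lo["economy"])
  expect_gt(b_hi["time_s"], b_lo["time_s"])
})

test_that("behavioral noise is centred on the affine prediction", {
  sc <- load_scenario(1, "same_session", behav_noise_sd = 4)
  draws <- t(vapply(1:1000,
                    function(i) behavioral_from_load(0.5, sc, seed = i),
                    numeric(3)))
  se <- 4 / sqrt(1000)
  expect_lt(abs(mean(draws[, "accuracy"]) - (95 - 45 * 0.5)), 3 * se)
  expect_lt(abs(mean(draws[, "economy"]) - (85 - 50 * 0.5)), 3 * se)
  expect_lt(abs(mean(draws[, "time_s"]) - (110 + 100 * 0.5)), 3 * 2.5 * se)
})

test_that("cohorts have one record+recording per participant x trial", {
  sc <- load_scenario(19, "same_session", trial_duration_s = 2, seed = 3)
  coh <- generate_cohort(sc)
  expect_equal(nrow(coh$records), 57)
  expect_equal(length(coh$recordings), 57)
  expect_false(anyDuplicated(
    coh$records[c("participant", "experiment", "trial")]) > 0)
  # bit-identical regeneration
  coh2 <- generate_cohort(sc)
  expect_identical(coh$records, coh2$records)
  expect_identical(coh$recordings[[30]]$samples,
                   coh2$recordings[[30]]$samples)
})

test_that("emitted scores respect the clipping invariants", {
  sc <- load_scenario(6, "same_session", behav_noise_sd = 40,
                      between_subject_sd = 0.5, trial_duration_s = 2,
                      seed = 8)
  coh <- generate_cohort(sc)
  expect_true(all(coh$records$accuracy >= 0 & coh$records$accuracy <= 100))
  expect_true(all(coh$records$economy >= 0 & coh$records$economy <= 100))
  expect_true(all(coh$records$time_s > 0))
  expect_true(all(coh$records$latent_load >= 0 &
                    coh$records$latent_load <= 1))
})

test_that("a participant's sessions differ while their load offset persists", {
  s1 <- load_scenario(4, "same_session", experiment_id = "exp1",
                      trial_duration_s = 2, seed = 11)
  s2 <- load_scenario(4, "next_day", experiment_id = "exp2",
                      trial_duration_s = 2, seed = 11)
  c1 <- generate_cohort(s1)
  c2 <- generate_cohort(s2)
  # same person, same latent plateau, different noise realizations
  expect_equal(c1$records$latent_load[c1$records$trial == 3],
               c2$records$latent_load[c2$records$trial == 1])
  expect_false(identical(c1$recordings[[3]]$samples,
                         c2$recordings[[1]]$samples))
})

test_that("calibration corpus is balanced with separated theta content", {
  corpus <- generate_calibration_corpus(50, seed = 5, duration_s = 2)
  expect_equal(length(corpus$recordings), 100)
  expect_equal(sum(corpus$labels == "high_load"), 50)
  expect_true(all(corpus$loads[corpus$labels == "high_load"] >= 0.8))
  expect_true(all(corpus$loads[corpus$labels == "low_load"] <= 0.2))
  theta <- vapply(corpus$recordings, function(r) {
    periodogram_band_power(r$samples, r$fs, 4, 7)
  }, numeric(1))
  expect_gt(mean(theta[corpus$labels == "high_load"]),
            mean(theta[corpus$labels == "low_load"]))
})
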