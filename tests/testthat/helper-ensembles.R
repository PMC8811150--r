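# Seeded replication ensembles of the three experiment designs, shared by
# the acceptance tests. One biomarker is pretrained on a fixed external
# calibration corpus and reused across seeds (the biomarker is pretrained
# on external data by construction). Trials are 20 s: the per-trial EEG
# means then have standard errors far below the simulated effect sizes.

replication_trial_s <- 20

# Fit the trial LMMs for the named DVs and return contrast rows.
contrast_rows <- function(summaries, dvs) {
  do.call(rbind, lapply(dvs, function(dv) {
    tab <- fit_trial_lmm(summaries, dv)$table
    cbind(dv = dv, tab[tab$effect != "intercept", c("effect", "coef", "p")])
  }))
}

same_session_ensemble <- function(n_seeds = 100) {
  cached("ens_same_session", {
    pre <- default_pretrained()
    lapply(seq_len(n_seeds), function(s) {
      sc <- scenario_same_session(seed = 5000 + s,
                                  trial_duration_s = replication_trial_s)
      smry <- make_summaries(sc, pre)
      ctr <- contrast_rows(smry, c("economy", "time_s", "vc9", "delta",
                                   "beta"))
      beta_rm_p <- vapply(c("accuracy", "economy", "time_s"), function(b) {
        rmcorr_fit(smry$participant, smry[[b]], smry$beta)$p
      }, numeric(1))
      list(contrasts = ctr, beta_rmcorr_p = beta_rm_p)
    })
  })
}

next_day_ensemble <- function(n_seeds = 100) {
  cached("ens_next_day", {
    pre <- default_pretrained()
    dvs <- c("accuracy", "economy", "time_s", "vc9", "theta", "delta")
    lapply(seq_len(n_seeds), function(s) {
      first <- make_summaries(
        load_scenario(10, "same_session", experiment_id = "exp1",
                      trial_duration_s = replication_trial_s,
                      seed = 5000 + s), pre)
      second <- make_summaries(
        scenario_next_day(seed = 5000 + s, n_participants = 10,
                          trial_duration_s = replication_trial_s), pre)
      list(contrasts = contrast_rows(second, dvs),
           paired = compare_experiment_sessions(first, second))
    })
  })
}

daily_ensemble <- function(n_seeds = 100) {
  cached("ens_daily", {
    pre <- default_pretrained()
    lapply(seq_len(n_seeds), function(s) {
      smry <- make_summaries(
        scenario_daily(seed = 5000 + s,
                       trial_duration_s = replication_trial_s), pre)
      ctr <- contrast_rows(smry, c("economy", "time_s", "vc9", "theta",
                                   "delta"))
      by_p <- split(smry, smry$participant)
      acc <- function(t) vapply(by_p, function(g) g$accuracy[g$trial == t],
                                numeric(1))
      acc_p <- c(trial2 = suppressWarnings(wilcoxon_paired(acc(2), acc(1)))$p,
                 trial3 = suppressWarnings(wilcoxon_paired(acc(3), acc(1)))$p)
      list(contrasts = ctr, accuracy_wilcoxon_p = acc_p)
    })
  })
}
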