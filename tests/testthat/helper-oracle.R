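# Independent pure-R observer path: per-trial loop over the exported
# primitives, used as a Monte-Carlo oracle for the compiled experiment
# simulator. Shares no code with simulate_experiment()'s hot path.
ref_experiment_dprime <- function(config, rel, n_trials,
                                  correction = "loglinear") {
  n_present <- round(config$present_prob * n_trials)
  hits <- 0L; fas <- 0L
  for (i in seq_len(n_trials)) {
    present <- i <= n_present
    disp <- simulate_display(present, config, rel)
    d <- global_decision(local_llr(disp$measurements, config, rel))
    resp <- decide(d, config$decision_threshold)
    if (present && resp == "present") hits <- hits + 1L
    if (!present && resp == "present") fas <- fas + 1L
  }
  cnt <- response_counts(hits, n_present - hits, fas,
                         (n_trials - n_present) - fas)
  sensitivity_and_bias(cnt, correction = correction)[["dprime"]]
}

# behavioral dataset holding given group-mean d' trajectories as one
# pseudo-observer per group (counts are placeholders; d' is authoritative)
mean_dataset <- function(dprime_matrix) {
  rows <- do.call(rbind, lapply(rownames(dprime_matrix), function(g)
    data.frame(observer_id = paste0("mean-", g), group = g,
               session_label = colnames(dprime_matrix),
               n_present = 270L, hits = 200L, n_absent = 270L,
               false_alarms = 20L, dprime = dprime_matrix[g, ],
               criterion = 0, stringsAsFactors = FALSE)))
  as_behavioral_dataset(rows)
}

# noiseless group-mean trajectories simulated at the given parameters
truth_trajectories <- function(params, n_trials = 40000L, seed = 100L,
                               n_training = 6L, include_test = TRUE) {
  sess <- paste0("D", seq_len(n_training))
  if (include_test) sess <- c(sess, "OrTest")
  out <- matrix(NA_real_, 2, length(sess),
                dimnames = list(c("near-cardinal", "oblique"), sess))
  for (g in rownames(out)) for (j in seq_along(sess)) {
    ph <- if (sess[j] == "OrTest") "orientation-test" else "training"
    si <- if (ph == "training") j else 1L
    out[g, j] <- model_dprime(params, g, si, ph, n_trials = n_trials,
                              seed = seed + j + 50 * (g == "oblique"),
                              n_training = n_training)
  }
  out
}

tiny_cohort <- function(seed = 1L, trials = 120L, n_per_group = 5L, ...) {
  simulate_cohort(cohort_spec(n_per_group = n_per_group,
                              trials_per_session = trials, seed = seed, ...))
}
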