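#' Ground-truth parameters of the default synthetic cohort
#'
#' A Reliability-and-Learning parameter set whose simulated trajectories
#' show the three qualitative signatures of the study the package emulates:
#' a baseline search asymmetry favouring the oblique-target group, monotone
#' learning over six sessions, and full transfer of learning in the
#' near-cardinal group versus partial specificity in the oblique group. The
#' learning rates are the study's fitted estimates (distractor 0.65, target
#' 0.24 per session); the initial uncertainties (5.5 and 6.9 degrees) were
#' calibrated once so that baseline group sensitivity and the
#' transfer/specificity pattern fall in the observed range.
#'
#' @return A [variant_params()] object (variant `"RL"`).
#' @export
default_truth <- function() {
  variant_params("RL", sigma_cardinal = 5.5, sigma_oblique = 6.9,
                 rates = c(tau_target = 0.24, tau_distractor = 0.65))
}

#' Specification of a synthetic behavioral cohort
#'
#' Describes the study structure to simulate: two groups of `n_per_group`
#' observers, `n_training_sessions` training days plus an optional
#' orientation-transfer test, `trials_per_session` trials at 50% target
#' prevalence, generated from a ground-truth observer model with
#' multiplicative lognormal inter-observer parameter jitter.
#'
#' @param n_per_group observers per group (default 5).
#' @param n_training_sessions training sessions (default 6).
#' @param include_orientation_test simulate the transfer session? (default TRUE).
#' @param trials_per_session trials per session (default 540).
#' @param truth generating [variant_params()] (default [default_truth()]).
#' @param jitter_cv coefficient of variation of the per-observer lognormal
#'   parameter jitter (default 0.2; 0 gives identical observers).
#' @param seed integer seed making the cohort fully reproducible.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 5L, n_training_sessions = 6L,
                        include_orientation_test = TRUE,
                        trials_per_session = 540L,
                        truth = default_truth(), jitter_cv = 0.2,
                        seed = 1L) {
  stopifnot(inherits(truth, "variant_params"))
  n_per_group <- as.integer(n_per_group)
  n_training_sessions <- as.integer(n_training_sessions)
  trials_per_session <- as.integer(trials_per_session)
  if (n_per_group < 1L || n_training_sessions < 1L || trials_per_session < 2L)
    stop_invalid("cohort counts must be positive (and >= 2 trials/session)")
  if (!is.finite(jitter_cv) || jitter_cv < 0)
    stop_invalid("'jitter_cv' must be >= 0")
  structure(list(n_per_group = n_per_group,
                 n_training_sessions = n_training_sessions,
                 include_orientation_test = isTRUE(include_orientation_test),
                 trials_per_session = trials_per_session,
                 truth = truth, jitter_cv = jitter_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw observer-specific parameters around a ground truth
#'
#' Multiplies every positive parameter by an independent lognormal factor
#' with unit median and coefficient of variation `jitter_cv`, preserving
#' positivity and the variant's parameter count. Uses the current RNG
#' stream.
#'
#' @param truth a [variant_params()] object.
#' @param jitter_cv coefficient of variation (>= 0).
#' @return A [variant_params()] object of the same variant.
#' @export
sample_observer_params <- function(truth, jitter_cv) {
  stopifnot(inherits(truth, "variant_params"))
  if (!is.finite(jitter_cv) || jitter_cv < 0)
    stop_invalid("'jitter_cv' must be >= 0")
  v <- pack_params(truth)
  if (jitter_cv > 0) {
    sdlog <- sqrt(log(1 + jitter_cv^2))
    v <- v * rlnorm(length(v), meanlog = 0, sdlog = sdlog)
  }
  unpack_params(v, truth$variant)
}

#' Simulate a full behavioral cohort from the observer model
#'
#' For each observer, draws jittered parameters, then simulates every
#' session (training days at the session's learned uncertainties; the
#' orientation test with end-of-training uncertainties and swapped roles)
#' with [simulate_experiment()], and tabulates counts, d' and criterion.
#'
#' @param spec a [cohort_spec()].
#' @param config a [search_config()].
#' @param correction extreme-rate correction for d', see
#'   [sensitivity_and_bias()].
#' @return A [as_behavioral_dataset()] data frame with attributes
#'   `observer_params` (list of generating [variant_params()] per observer)
#'   and `spec`.
#' @examples
#' d <- simulate_cohort(cohort_spec(trials_per_session = 60, seed = 7))
#' group_means(d)
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = search_config(),
                            correction = "loglinear") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "search_config"))
  with_seed(spec$seed, {
    sessions <- paste0("D", seq_len(spec$n_training_sessions))
    if (spec$include_orientation_test) sessions <- c(sessions, "OrTest")
    rows <- vector("list", 2L * spec$n_per_group * length(sessions))
    obs_params <- list()
    k <- 0L
    for (g in .groups) {
      for (i in seq_len(spec$n_per_group)) {
        id <- sprintf("%s-%02d", if (g == "near-cardinal") "NC" else "OB", i)
        p_i <- sample_observer_params(spec$truth, spec$jitter_cv)
        obs_params[[id]] <- p_i
        for (s in sessions) {
          phase <- if (s == "OrTest") "orientation-test" else "training"
          idx <- if (phase == "training") as.integer(sub("^D", "", s)) else 1L
          rel <- session_reliabilities(p_i, g, idx, phase,
                                       n_training = spec$n_training_sessions)
          cnt <- simulate_experiment(config, rel, spec$trials_per_session)
          sb <- sensitivity_and_bias(cnt, correction = correction)
          k <- k + 1L
          rows[[k]] <- data.frame(
            observer_id = id, group = g, session_label = s,
            n_present = cnt$hits + cnt$misses, hits = cnt$hits,
            n_absent = cnt$false_alarms + cnt$correct_rejections,
            false_alarms = cnt$false_alarms,
            dprime = sb[["dprime"]], criterion = sb[["criterion"]],
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- as_behavioral_dataset(do.call(rbind, rows), correction = correction)
    attr(out, "observer_params") <- obs_params
    attr(out, "spec") <- spec
    out
  })
}
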