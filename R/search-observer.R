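#' Display geometry and stimulus orientations for the search task
#'
#' Bundles the quantities that enter the optimal decision rule: the number of
#' display locations the target can occupy, the target and distractor
#' orientations (degrees, linear scale), the log-odds decision threshold and
#' the target prevalence. Defaults match the study design the package
#' emulates: a 5x5 inner array (25 locations), an 80 degree (near-cardinal)
#' and a 50 degree (oblique) orientation, threshold 0 and 50% prevalence.
#'
#' @param n_locations number of display locations (N >= 1).
#' @param s_target target orientation in degrees.
#' @param s_distractor distractor orientation in degrees; must differ from
#'   `s_target`.
#' @param decision_threshold log-odds criterion for responding "present";
#'   0 is optimal at 50% prevalence.
#' @param present_prob probability that a trial contains a target, in (0, 1).
#' @return An object of class `"search_config"`.
#' @examples
#' search_config()
#' @export
search_config <- function(n_locations = 25L, s_target = 80, s_distractor = 50,
                          decision_threshold = 0, present_prob = 0.5) {
  n_locations <- as.integer(n_locations)
  if (length(n_locations) != 1L || is.na(n_locations) || n_locations < 1L)
    stop_invalid("'n_locations' must be a single integer >= 1")
  if (!is.finite(s_target) || !is.finite(s_distractor))
    stop_invalid("orientations must be finite")
  if (s_target == s_distractor)
    stop_invalid("'s_target' must differ from 's_distractor'")
  if (!is.finite(decision_threshold))
    stop_invalid("'decision_threshold' must be finite")
  if (!is.finite(present_prob) || present_prob <= 0 || present_prob >= 1)
    stop_invalid("'present_prob' must be in (0, 1)")
  structure(list(n_locations = n_locations, s_target = s_target,
                 s_distractor = s_distractor,
                 decision_threshold = decision_threshold,
                 present_prob = present_prob),
            class = "search_config")
}

#' @export
print.search_config <- function(x, ...) {
  cat("Search display: ", x$n_locations, " locations; target ", x$s_target,
      "°, distractors ", x$s_distractor, "°; threshold ",
      x$decision_threshold, "; P(present) = ", x$present_prob, "\n", sep = "")
  invisible(x)
}

#' Measurement uncertainty of target and distractor representations
#'
#' The pair (sigma_T, sigma_D) of orientation measurement standard deviations
#' (degrees) in force on a given session. Sensory reliability is the inverse
#' of these uncertainties.
#'
#' @param sigma_target,sigma_distractor positive, finite standard deviations
#'   in degrees.
#' @return An object of class `"reliability_pair"`.
#' @examples
#' reliability_pair(4, 8)
#' @export
reliability_pair <- function(sigma_target, sigma_distractor) {
  if (!is.numeric(sigma_target) || !is.numeric(sigma_distractor) ||
      length(sigma_target) != 1L || length(sigma_distractor) != 1L ||
      !is.finite(sigma_target) || !is.finite(sigma_distractor) ||
      sigma_target <= 0 || sigma_distractor <= 0)
    stop_invalid("uncertainties must be single positive finite numbers")
  structure(list(sigma_target = sigma_target,
                 sigma_distractor = sigma_distractor),
            class = "reliability_pair")
}

#' @export
print.reliability_pair <- function(x, ...) {
  cat("sigma_T = ", format(x$sigma_target), "°, sigma_D = ",
      format(x$sigma_distractor), "°\n", sep = "")
  invisible(x)
}

#' Simulate the orientation measurements of one search display
#'
#' Each distractor location yields an independent Gaussian measurement with
#' mean `s_distractor` and SD `sigma_distractor`; on target-present displays
#' one uniformly chosen location instead yields a Gaussian measurement with
#' mean `s_target` and SD `sigma_target`. Uses the current R random number
#' stream.
#'
#' @param target_present logical; does the display contain a target?
#' @param config a [search_config()].
#' @param rel a [reliability_pair()].
#' @return A list of class `"display_measurements"` with elements
#'   `measurements` (numeric vector of length `n_locations`),
#'   `target_present`, and `target_location` (`NA` when absent).
#' @examples
#' set.seed(1)
#' simulate_display(TRUE, search_config(), reliability_pair(4, 8))
#' @export
simulate_display <- function(target_present, config = search_config(),
                             rel) {
  stopifnot(inherits(config, "search_config"), inherits(rel, "reliability_pair"))
  if (!is.logical(target_present) || length(target_present) != 1L ||
      is.na(target_present))
    stop_invalid("'target_present' must be TRUE or FALSE")
  n <- config$n_locations
  x <- rnorm(n, mean = config$s_distractor, sd = rel$sigma_distractor)
  loc <- NA_integer_
  if (target_present) {
    loc <- sample.int(n, 1L)
    x[loc] <- rnorm(1L, mean = config$s_target, sd = rel$sigma_target)
  }
  structure(list(measurements = x, target_present = target_present,
                 target_location = loc),
            class = "display_measurements")
}

#' Local log-likelihood ratio of target vs distractor at one location
#'
#' For an orientation measurement x the log likelihood ratio of
#' "this element is the target" against "this element is a distractor" under
#' the Gaussian measurement model has the closed form
#' \deqn{d_i = \tfrac12 \log(\sigma_D^2/\sigma_T^2) -
#'   \tfrac12\left[(x - s_T)^2/\sigma_T^2 - (x - s_D)^2/\sigma_D^2\right].}
#'
#' @param x numeric vector of orientation measurements (degrees).
#' @inheritParams simulate_display
#' @return Numeric vector of log-odds, same length as `x`.
#' @examples
#' local_llr(80, search_config(), reliability_pair(4, 8))
#' @export
local_llr <- function(x, config = search_config(), rel) {
  stopifnot(inherits(config, "search_config"), inherits(rel, "reliability_pair"))
  sT <- rel$sigma_target
  sD <- rel$sigma_distractor
  0.5 * log(sD^2 / sT^2) -
    0.5 * ((x - config$s_target)^2 / sT^2 -
             (x - config$s_distractor)^2 / sD^2)
}

#' Pool local decision variables into the global present/absent log-odds
#'
#' With a single target equally likely at each of N locations, the global
#' log-likelihood ratio for target presence is the log of the mean
#' exponentiated local ratio, \eqn{d = \log\frac{1}{N}\sum_i e^{d_i}},
#' computed here with overflow-safe shifting.
#'
#' @param locals numeric vector of local log-likelihood ratios.
#' @param n_locations number of display locations; defaults to
#'   `length(locals)` and must equal it.
#' @return A single log-odds value.
#' @examples
#' global_decision(c(log(2), log(4)))  # log(3)
#' @export
global_decision <- function(locals, n_locations = length(locals)) {
  if (length(locals) == 0L)
    stop_invalid("'locals' must be a non-empty numeric vector")
  if (length(locals) != n_locations)
    stop_invalid("'n_locations' must equal length(locals)")
  m <- max(locals)
  if (!is.finite(m)) return(m)  # all -Inf => -Inf; +Inf dominates
  m + log(sum(exp(locals - m))) - log(n_locations)
}

#' Map a global decision variable to a present/absent response
#'
#' Responds "present" iff the decision variable strictly exceeds the
#' threshold; a tie is resolved as "absent" (a measure-zero event, fixed for
#' determinism).
#'
#' @param d global log-odds (finite).
#' @param threshold log-odds criterion (default 0).
#' @return `"present"` or `"absent"` (character vector along `d`).
#' @examples
#' decide(c(-5, 0, 0.01))
#' @export
decide <- function(d, threshold = 0) {
  if (any(!is.finite(d))) stop_invalid("'d' must be finite")
  ifelse(d > threshold, "present", "absent")
}

#' Response counts of a simulated present/absent experiment
#'
#' Validated container for the four response-outcome cells.
#'
#' @param hits,misses,false_alarms,correct_rejections nonnegative counts.
#' @return An object of class `"response_counts"`.
#' @export
response_counts <- function(hits, misses, false_alarms, correct_rejections) {
  v <- c(hits = hits, misses = misses, false_alarms = false_alarms,
         correct_rejections = correct_rejections)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop_invalid("counts must be nonnegative integers")
  structure(as.list(v), class = "response_counts")
}

#' @export
print.response_counts <- function(x, ...) {
  np <- x$hits + x$misses
  na <- x$false_alarms + x$correct_rejections
  cat("present trials: ", np, " (", x$hits, " hits); absent trials: ", na,
      " (", x$false_alarms, " false alarms)\n", sep = "")
  invisible(x)
}

#' Simulate a full search experiment and tally responses
#'
#' Runs `n_trials` independent trials (a fraction `present_prob` of them
#' target-present, rounded) through the optimal observer: Gaussian
#' measurements at every location, local log-likelihood ratios, log-mean-exp
#' pooling, and thresholding at `decision_threshold`. The trial-level loop is
#' implemented in compiled code for speed; [simulate_display()] and friends
#' provide an equivalent pure-R path.
#'
#' @inheritParams simulate_display
#' @param n_trials total number of trials (>= 2).
#' @param seed optional integer; when given, the simulation is reproducible
#'   and the caller's RNG state is untouched.
#' @return A [response_counts()] object.
#' @examples
#' simulate_experiment(search_config(), reliability_pair(4, 8), 400, seed = 1)
#' @export
simulate_experiment <- function(config = search_config(), rel, n_trials = 4000L,
                                seed = NULL) {
  stopifnot(inherits(config, "search_config"), inherits(rel, "reliability_pair"))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 2L)
    stop_invalid("'n_trials' must be an integer >= 2")
  with_seed(seed, {
    n_present <- as.integer(round(config$present_prob * n_trials))
    n <- config$n_locations
    z <- matrix(rnorm(n_trials * n), n_trials, n)
    present <- c(rep(TRUE, n_present), rep(FALSE, n_trials - n_present))
    target_col <- ifelse(present, sample.int(n, n_trials, replace = TRUE), 0L)
    cnt <- sim_counts_cpp(z, present, as.integer(target_col),
                          config$s_target, config$s_distractor,
                          rel$sigma_target, rel$sigma_distractor,
                          config$decision_threshold)
    response_counts(cnt[1L], cnt[2L], cnt[3L], cnt[4L])
  })
}

#' Sensitivity (d') and criterion (c) from response counts
#'
#' Computes the standard signal-detection indices d' = z(H) - z(F) and
#' c = -(z(H) + z(F))/2 from hit and false-alarm rates. Extreme rates (0 or
#' 1) make the raw indices infinite; the default log-linear correction adds
#' 0.5 to every cell and 1 to every trial count before computing rates.
#'
#' @param counts a [response_counts()] object.
#' @param correction `"loglinear"` (default) applies the log-linear rule to
#'   all cells; `"none"` uses raw rates (may yield infinite values).
#' @return Named numeric vector `c(dprime, criterion)`.
#' @examples
#' sensitivity_and_bias(response_counts(80, 20, 20, 80))
#' @export
sensitivity_and_bias <- function(counts, correction = c("loglinear", "none")) {
  stopifnot(inherits(counts, "response_counts"))
  correction <- match.arg(correction)
  n_present <- counts$hits + counts$misses
  n_absent <- counts$false_alarms + counts$correct_rejections
  if (n_present < 1L || n_absent < 1L)
    stop_invalid("need at least one present and one absent trial")
  if (correction == "loglinear") {
    h <- (counts$hits + 0.5) / (n_present + 1)
    f <- (counts$false_alarms + 0.5) / (n_absent + 1)
  } else {
    h <- counts$hits / n_present
    f <- counts$false_alarms / n_absent
  }
  zh <- qnorm(h)
  zf <- qnorm(f)
  c(dprime = zh - zf, criterion = -(zh + zf) / 2)
}
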