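# Simulation-based least-squares fitting of the observer-model variants.
#
# The objective is stochastic (each evaluation simulates full experiments),
# so it is stabilized by common random numbers: one base seed fixes every
# measurement draw across candidate parameter vectors, making the objective
# a deterministic function of the parameters within a fit.

# one row per (group x session) point entering the objective
build_cells <- function(sessions, n_training) {
  cells <- expand.grid(group = .groups, session_label = sessions,
                       stringsAsFactors = FALSE)
  cells$phase <- ifelse(cells$session_label == "OrTest",
                        "orientation-test", "training")
  cells$session_index <- ifelse(cells$phase == "training",
                                suppressWarnings(as.integer(
                                  sub("^D", "", cells$session_label))),
                                NA_integer_)
  cells$n_training <- n_training
  cells
}

# frozen measurement noise for every cell: standard-normal draws, the
# present/absent split and the target location of each trial
make_sim_context <- function(config, n_trials, seed, cells) {
  n <- config$n_locations
  n_present <- as.integer(round(config$present_prob * n_trials))
  lapply(seq_len(nrow(cells)), function(i) {
    with_seed(derive_seed(seed, i), {
      present <- c(rep(TRUE, n_present), rep(FALSE, n_trials - n_present))
      list(z = matrix(rnorm(n_trials * n), n_trials, n),
           present = present,
           target_col = as.integer(ifelse(
             present, sample.int(n, n_trials, replace = TRUE), 0L)))
    })
  })
}

# model d' for every cell at the given parameters, using frozen noise
evaluate_cells <- function(params, cells, ctx, config, correction) {
  vapply(seq_len(nrow(cells)), function(i) {
    rel <- session_reliabilities(params, cells$group[i],
                                 session_index = if (is.na(cells$session_index[i])) 1L
                                                 else cells$session_index[i],
                                 phase = cells$phase[i],
                                 n_training = cells$n_training[i])
    cnt <- sim_counts_cpp(ctx[[i]]$z, ctx[[i]]$present, ctx[[i]]$target_col,
                          config$s_target, config$s_distractor,
                          rel$sigma_target, rel$sigma_distractor,
                          config$decision_threshold)
    sensitivity_and_bias(response_counts(cnt[1L], cnt[2L], cnt[3L], cnt[4L]),
                         correction = correction)[["dprime"]]
  }, numeric(1))
}

#' Model sensitivity for one group and session
#'
#' Composes [session_reliabilities()], [simulate_experiment()] and
#' [sensitivity_and_bias()]: the model's d' for a given group, session and
#' phase, estimated from a simulated experiment (4,000 trials at 50% target
#' prevalence by default).
#'
#' @inheritParams session_reliabilities
#' @param config a [search_config()].
#' @param n_trials simulated trials per experiment.
#' @param seed optional integer seed for reproducibility.
#' @param correction extreme-rate correction, see [sensitivity_and_bias()].
#' @return Model d' (single number).
#' @examples
#' model_dprime(default_truth(), "oblique", 1, seed = 1)
#' @export
model_dprime <- function(params, group, session_index = 1L,
                         phase = c("training", "orientation-test"),
                         config = search_config(), n_trials = 4000L,
                         seed = NULL, correction = "loglinear",
                         n_training = 6L) {
  phase <- match.arg(phase)
  rel <- session_reliabilities(params, group, session_index, phase, n_training)
  cnt <- simulate_experiment(config, rel, n_trials, seed = seed)
  sensitivity_and_bias(cnt, correction = correction)[["dprime"]]
}

#' Sum of squared errors between model and observed group-mean sensitivity
#'
#' For every (group, session) point, simulates the model's d' at the
#' candidate parameters and accumulates the squared deviation from the
#' observed group-mean d'. All measurement noise is frozen by `seed`
#' (common random numbers), so repeated calls with the same seed and
#' candidate give identical values.
#'
#' @param param_vector packed parameter vector (see [pack_params()]).
#' @param variant model variant.
#' @param data a behavioral dataset.
#' @param sessions session labels to include (default: all in `data`);
#'   both groups are always included.
#' @inheritParams model_dprime
#' @return The sum of squared errors (single number).
#' @export
objective_sse <- function(param_vector, variant, data, sessions = NULL,
                          config = search_config(), n_trials = 4000L,
                          seed = 1L, correction = "loglinear") {
  obs <- group_means(data, sessions)
  sessions <- colnames(obs)
  n_training <- sum(grepl("^D[0-9]+$", session_labels(data)))
  cells <- build_cells(sessions, n_training)
  ctx <- make_sim_context(config, as.integer(n_trials), seed, cells)
  params <- unpack_params(param_vector, variant)
  pred <- evaluate_cells(params, cells, ctx, config, correction)
  sum((pred - obs[cbind(cells$group, cells$session_label)])^2)
}

#' Corrected Akaike information criterion for a least-squares fit
#'
#' Uses the Gaussian-error identification of the log-likelihood,
#' \eqn{AICc = n \ln(SSE/n) + 2k + 2k(k+1)/(n-k-1)}, with `k` counting the
#' variant's named parameters only. Lower is better; only differences
#' between variants are meaningful.
#'
#' @param sse sum of squared errors (>= 0).
#' @param n_points number of fitted data points.
#' @param k number of free parameters; requires `n_points > k + 1`.
#' @return The AICc value.
#' @examples
#' aicc(0.5, 14, 4)
#' @export
aicc <- function(sse, n_points, k) {
  if (!is.finite(sse) || sse < 0) stop_invalid("'sse' must be >= 0")
  if (n_points <= k + 1)
    stop_invalid("AICc undefined: need n_points > k + 1")
  n_points * log(sse / n_points) + 2 * k + 2 * k * (k + 1) / (n_points - k - 1)
}

# draw multi-start initial values: uncertainties uniform on sigma_range
# (upper bound capped at 20, where first-session hit rates vanish), rates
# uniform on tau_range
sample_starts <- function(variant, n_starts, sigma_range, tau_range) {
  sigma_range <- sort(sigma_range)
  if (sigma_range[2] > 20) sigma_range[2] <- 20
  if (sigma_range[1] <= 0) stop_invalid("sigma starts must be positive")
  tau_range <- sort(tau_range)
  if (tau_range[1] < 0) stop_invalid("tau starts must be >= 0")
  k <- n_free_params(variant)
  n_sigma <- if (variant == "L") 1L else 2L
  t(vapply(seq_len(n_starts), function(i) {
    c(runif(n_sigma, sigma_range[1], sigma_range[2]),
      runif(k - n_sigma, tau_range[1], tau_range[2]))
  }, numeric(k)))
}

#' Fit an observer-model variant to group-mean sensitivity trajectories
#'
#' Minimizes the sum of squared errors between simulated model d' and the
#' observed group-mean d' across both groups and the selected sessions,
#' using multi-start Nelder-Mead simplex search on log-transformed
#' parameters. Each candidate evaluation simulates a full experiment per
#' (group, session) point; all measurement draws are frozen by the fit seed
#' (common random numbers), so the whole fit is reproducible bit-for-bit.
#'
#' @param data a behavioral dataset (see [as_behavioral_dataset()] or
#'   [simulate_cohort()]).
#' @param variant `"R"`, `"L"`, `"RL"` or `"RLG"`.
#' @param sessions `"all"` fits every session in `data` (training days plus
#'   the orientation test); `"training"` fits the training days only, which
#'   permits [predict_transfer()].
#' @param config a [search_config()].
#' @param n_trials simulated trials per experiment evaluation (default 4000).
#' @param n_starts number of Nelder-Mead starts (default 20).
#' @param sigma_range,tau_range uniform sampling ranges for the starting
#'   uncertainties and learning rates; sigma starts above 20 degrees are
#'   capped (hit rates vanish there and the objective is flat).
#' @param seed integer seed governing both the frozen simulation noise and
#'   the start sampling.
#' @param correction extreme-rate correction for d'.
#' @param control passed to [stats::optim()]; defaults to
#'   `list(maxit = 400, reltol = 1e-4)`. `maxit = 0` evaluates the starts
#'   without optimization.
#' @return An object of class `"search_fit"`; see [coef.search_fit()],
#'   [predict.search_fit()], [plot.search_fit()].
#' @examples
#' d <- simulate_cohort(cohort_spec(trials_per_session = 100, seed = 3))
#' fit <- fit_search_model(d, "R", n_trials = 400, n_starts = 2, seed = 1)
#' fit
#' @export
fit_search_model <- function(data, variant = c("RL", "R", "L", "RLG"),
                             sessions = c("all", "training"),
                             config = search_config(), n_trials = 4000L,
                             n_starts = 20L, sigma_range = c(1, 20),
                             tau_range = c(0, 2), seed = 1L,
                             correction = "loglinear", control = list()) {
  variant <- match.arg(variant)
  sessions <- match.arg(sessions)
  stopifnot(inherits(data, "behavioral_dataset"))
  n_trials <- as.integer(n_trials)
  n_starts <- as.integer(n_starts)
  if (n_starts < 1L) stop_invalid("'n_starts' must be >= 1")
  control <- utils::modifyList(list(maxit = 400L, reltol = 1e-4), control)

  labs <- session_labels(data)
  train_labs <- labs[grepl("^D[0-9]+$", labs)]
  use_labs <- if (sessions == "training") train_labs else labs
  n_training <- length(train_labs)
  obs <- group_means(data, use_labs)
  cells <- build_cells(use_labs, n_training)
  obs_vec <- obs[cbind(cells$group, cells$session_label)]
  ctx <- make_sim_context(config, n_trials, seed, cells)

  sse_of <- function(theta) {
    params <- unpack_params(exp(theta), variant)
    pred <- evaluate_cells(params, cells, ctx, config, correction)
    sum((pred - obs_vec)^2)
  }

  starts <- with_seed(derive_seed(seed, 0L),
                      sample_starts(variant, n_starts, sigma_range, tau_range))
  # log-transform keeps parameters positive; floor rates at 1e-3 so a
  # tau = 0 start stays finite on the log scale
  eps <- 1e-3
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    th0 <- log(pmax(starts[i, ], eps))
    if (control$maxit == 0L) {
      results[[i]] <- list(par = th0, value = sse_of(th0), convergence = 1L)
    } else {
      results[[i]] <- tryCatch(
        optim(th0, sse_of, method = "Nelder-Mead", control = control),
        error = function(e) NULL)
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok))
    stop_invalid("optimization failed from every start (variant ", variant, ")")
  finals <- vapply(results, function(r) if (is.null(r)) Inf else r$value,
                   numeric(1))
  best_i <- which.min(finals)  # ties: first start index
  best <- results[[best_i]]
  best_par <- exp(best$par)
  params <- unpack_params(best_par, variant)
  fitted_vec <- evaluate_cells(params, cells, ctx, config, correction)
  fitted_mat <- obs
  fitted_mat[cbind(cells$group, cells$session_label)] <- fitted_vec
  k <- n_free_params(variant)
  n_points <- length(obs_vec)

  start_log <- as.data.frame(starts)
  names(start_log) <- paste0("start_", names(pack_params(params)))
  start_log$final_sse <- finals
  start_log$converged <- vapply(results, function(r)
    !is.null(r) && identical(r$convergence, 0L), logical(1))

  structure(list(
    variant = variant,
    params = params,
    coefficients = pack_params(params),
    sse = best$value,
    n_points = n_points,
    k = k,
    aicc = aicc(best$value, n_points, k),
    observed = obs,
    fitted = fitted_mat,
    starts = start_log,
    best_start = best_i,
    sessions_used = use_labs,
    n_training = n_training,
    settings = list(config = config, n_trials = n_trials,
                    n_starts = n_starts, sigma_range = sigma_range,
                    tau_range = tau_range, seed = as.integer(seed),
                    correction = correction, control = control,
                    sessions = sessions),
    call = match.call()),
    class = "search_fit")
}
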