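# per-observer d' vectors in canonical session order
observer_vectors <- function(data) {
  labs <- session_labels(data)
  ids <- unique(data$observer_id)
  out <- lapply(ids, function(id) {
    sub <- data[data$observer_id == id, ]
    v <- sub$dprime[match(labs, sub$session_label)]
    list(id = id, group = sub$group[1L], dprime = v)
  })
  names(out) <- ids
  out
}

# squared Pearson correlation; NA (with caller-side warning) when either
# vector is constant
r_squared <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Noise ceiling for cross-validated model performance
#'
#' Bounds the cross-validated r-squared achievable given between-observer
#' variability. For each observer, their per-session d' vector is correlated
#' with their own group's mean trajectory: including the observer in the
#' mean gives the upper bound, excluding them gives the lower bound; both
#' bounds are the mean squared correlation across observers.
#'
#' @param data a behavioral dataset with observer-level rows and at least
#'   two observers per group.
#' @return A list with elements `lower`, `upper` and `per_observer`
#'   (data frame of per-observer squared correlations).
#' @examples
#' d <- simulate_cohort(cohort_spec(trials_per_session = 100, seed = 5))
#' noise_ceiling(d)[c("lower", "upper")]
#' @export
noise_ceiling <- function(data) {
  stopifnot(inherits(data, "behavioral_dataset"))
  obs <- observer_vectors(data)
  for (g in unique(vapply(obs, `[[`, "", "group")))
    if (sum(vapply(obs, `[[`, "", "group") == g) < 2L)
      stop_invalid("need at least 2 observers per group")
  rows <- lapply(obs, function(o) {
    peers <- Filter(function(p) p$group == o$group, obs)
    incl <- colMeans(do.call(rbind, lapply(peers, `[[`, "dprime")))
    excl <- colMeans(do.call(rbind, lapply(
      Filter(function(p) p$id != o$id, peers), `[[`, "dprime")))
    data.frame(observer_id = o$id, group = o$group,
               r2_upper = r_squared(o$dprime, incl),
               r2_lower = r_squared(o$dprime, excl),
               stringsAsFactors = FALSE)
  })
  per_obs <- do.call(rbind, rows)
  rownames(per_obs) <- NULL
  if (anyNA(per_obs$r2_upper) || anyNA(per_obs$r2_lower))
    warning("constant d' vector(s); affected observers excluded from the ceiling")
  list(lower = mean(per_obs$r2_lower, na.rm = TRUE),
       upper = mean(per_obs$r2_upper, na.rm = TRUE),
       per_observer = per_obs)
}

#' Leave-one-observer-out cross-validated r-squared
#'
#' For each observer in turn: refit the variant to group means computed from
#' the remaining observers, predict the held-out observer's per-session d'
#' trajectory (their group's fitted model trajectory), and score the squared
#' Pearson correlation between prediction and observation. The mean across
#' observers is the cross-validated r-squared, reported next to the
#' [noise_ceiling()] bounds.
#'
#' @param data a behavioral dataset with at least two observers per group.
#' @param variant model variant to cross-validate.
#' @param sessions,config,n_trials,n_starts,seed,correction,control passed
#'   to [fit_search_model()] for every refit.
#' @return An object of class `"search_cv"`: per-observer r-squared, their
#'   mean and SD, the ceiling bounds, and the per-fold fitted coefficients.
#' @export
loo_cv <- function(data, variant = "RL", sessions = "all",
                   config = search_config(), n_trials = 4000L,
                   n_starts = 20L, seed = 1L, correction = "loglinear",
                   control = list()) {
  stopifnot(inherits(data, "behavioral_dataset"))
  obs <- observer_vectors(data)
  for (g in unique(vapply(obs, `[[`, "", "group")))
    if (sum(vapply(obs, `[[`, "", "group") == g) < 2L)
      stop_invalid("need at least 2 observers per group")
  ids <- names(obs)
  labs <- session_labels(data)
  use_labs <- if (sessions == "training") labs[grepl("^D", labs)] else labs
  folds <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    held <- ids[i]
    train_data <- data[data$observer_id != held, ]
    class(train_data) <- class(data)
    fit <- fit_search_model(train_data, variant, sessions = sessions,
                            config = config, n_trials = n_trials,
                            n_starts = n_starts, seed = derive_seed(seed, i),
                            correction = correction, control = control)
    pred <- fit$fitted[obs[[held]]$group, use_labs]
    truth <- obs[[held]]$dprime[match(use_labs, labs)]
    folds[[i]] <- list(observer_id = held, group = obs[[held]]$group,
                       n_fit_observers = length(ids) - 1L,
                       n_fit_in_group = sum(vapply(obs, `[[`, "", "group") ==
                                              obs[[held]]$group) - 1L,
                       r2 = r_squared(pred, truth),
                       coefficients = coef(fit), sse = fit$sse)
  }
  per_obs <- data.frame(
    observer_id = vapply(folds, `[[`, "", "observer_id"),
    group = vapply(folds, `[[`, "", "group"),
    r2 = vapply(folds, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE)
  if (anyNA(per_obs$r2))
    warning("constant prediction or observation; affected fold(s) excluded")
  ceiling <- noise_ceiling(data)
  structure(list(variant = variant,
                 per_observer = per_obs,
                 mean_r2 = mean(per_obs$r2, na.rm = TRUE),
                 sd_r2 = sd(per_obs$r2, na.rm = TRUE),
                 ceiling_lower = ceiling$lower,
                 ceiling_upper = ceiling$upper,
                 folds = folds,
                 settings = list(sessions = sessions, n_trials = n_trials,
                                 n_starts = n_starts, seed = seed)),
            class = "search_cv")
}

#' @export
print.search_cv <- function(x, digits = 3, ...) {
  cat("Leave-one-observer-out cross-validation, variant ", x$variant, "\n",
      sep = "")
  cat("mean r2 = ", round(x$mean_r2, digits), " (SD ", round(x$sd_r2, digits),
      "), noise ceiling [", round(x$ceiling_lower, digits), ", ",
      round(x$ceiling_upper, digits), "]\n", sep = "")
  invisible(x)
}
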