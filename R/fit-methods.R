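#' @export
print.search_fit <- function(x, digits = 4, ...) {
  cat("Observer-model fit, variant ", x$variant, " (", x$k,
      " free parameters)\n", sep = "")
  cat("Fitted to ", x$n_points, " group-mean d' points (sessions ",
      paste(x$sessions_used, collapse = ", "), ")\n", sep = "")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nSSE = ", format(x$sse, digits = digits),
      ",  AICc = ", format(x$aicc, digits = digits), "\n", sep = "")
  invisible(x)
}

#' @export
coef.search_fit <- function(object, ...) object$coefficients

#' @export
fitted.search_fit <- function(object, ...) object$fitted

#' @export
residuals.search_fit <- function(object, ...) object$observed - object$fitted

#' @export
summary.search_fit <- function(object, ...) {
  structure(list(fit = object,
                 residuals = residuals(object),
                 sigma = sigma_trajectories(object$params,
                                            n_training = object$n_training)),
            class = "summary.search_fit")
}

#' @export
print.summary.search_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nObserved group-mean d':\n")
  print(round(x$fit$observed, digits))
  cat("\nFitted model d':\n")
  print(round(x$fit$fitted, digits))
  cat("\nUncertainty trajectories (degrees):\n")
  sig <- x$sigma
  sig$sigma_target <- round(sig$sigma_target, digits)
  sig$sigma_distractor <- round(sig$sigma_distractor, digits)
  print(sig, row.names = FALSE)
  invisible(x)
}

#' Predict model sensitivity from a fitted variant
#'
#' Simulates fresh experiments at the fitted parameters for the requested
#' sessions of both groups. `sessions` may include `"OrTest"` even when the
#' fit used training days only, which is how transfer predictions are made.
#'
#' @param object a `"search_fit"`.
#' @param sessions session labels (default: the sessions the fit used).
#' @param n_trials,seed simulation size and seed; default to the fit's own
#'   settings, making the prediction reproducible.
#' @param ... unused.
#' @return Matrix of predicted d' (groups x sessions).
#' @export
predict.search_fit <- function(object, sessions = object$sessions_used,
                               n_trials = object$settings$n_trials,
                               seed = object$settings$seed, ...) {
  bad <- sessions[!grepl("^D[0-9]+$", sessions) & sessions != "OrTest"]
  if (length(bad))
    stop_invalid("unknown session label(s): ", paste(bad, collapse = ", "))
  cells <- build_cells(sessions, object$n_training)
  ctx <- make_sim_context(object$settings$config, as.integer(n_trials),
                          derive_seed(seed, 1000L), cells)
  pred <- evaluate_cells(object$params, cells, ctx, object$settings$config,
                         object$settings$correction)
  out <- matrix(NA_real_, 2L, length(sessions),
                dimnames = list(.groups, sessions))
  out[cbind(cells$group, cells$session_label)] <- pred
  out
}

#' Predict orientation-transfer performance from a training-only fit
#'
#' Evaluates the fitted model at the orientation-test phase (end-of-training
#' uncertainties, swapped target/distractor roles) for each group. The fit
#' must not have used the test session — this is the out-of-sample transfer
#' prediction.
#'
#' @param fit a `"search_fit"` produced with `sessions = "training"`.
#' @param n_trials,seed simulation settings; default to the fit's own.
#' @return Named numeric vector of predicted test d' per group.
#' @export
predict_transfer <- function(fit, n_trials = fit$settings$n_trials,
                             seed = fit$settings$seed) {
  stopifnot(inherits(fit, "search_fit"))
  if ("OrTest" %in% fit$sessions_used)
    stop_invalid("fit already used the orientation-test session; ",
                 "refit with sessions = \"training\"")
  predict(fit, sessions = "OrTest", n_trials = n_trials, seed = seed)[, "OrTest"]
}

#' Simulate cohorts from a fitted model
#'
#' Generates `nsim` synthetic behavioral cohorts whose ground truth is the
#' fitted parameter set.
#'
#' @param object a `"search_fit"`.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param jitter_cv inter-observer parameter jitter (default 0: all
#'   observers at the fitted parameters).
#' @param ... passed to [cohort_spec()] (e.g. `trials_per_session`).
#' @return A list of behavioral datasets (a single dataset if `nsim = 1`).
#' @importFrom stats simulate
#' @export
simulate.search_fit <- function(object, nsim = 1, seed = 1L,
                                jitter_cv = 0, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_cohort(cohort_spec(truth = object$params, jitter_cv = jitter_cv,
                                n_training_sessions = object$n_training,
                                seed = derive_seed(seed, i), ...),
                    config = object$settings$config,
                    correction = object$settings$correction)
  })
  if (nsim == 1) out[[1L]] else out
}

#' Plot observed and fitted sensitivity trajectories
#'
#' One panel per group: observed group-mean d' (points) and fitted model d'
#' (line) against session, with the orientation test separated from the
#' training days.
#'
#' @param x a `"search_fit"`.
#' @param ... further graphical parameters passed to [matplot()].
#' @return `x`, invisibly.
#' @export
plot.search_fit <- function(x, ...) {
  sess <- colnames(x$observed)
  n_s <- length(sess)
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(par(old))
  ylim <- range(x$observed, x$fitted, na.rm = TRUE) + c(-0.2, 0.2)
  for (g in rownames(x$observed)) {
    plot(seq_len(n_s), x$observed[g, ], ylim = ylim, xaxt = "n",
         xlab = "session", ylab = "d'", pch = 19,
         main = paste0(g, " group"), ...)
    lines(seq_len(n_s), x$fitted[g, ], lwd = 2)
    axis(1, at = seq_len(n_s), labels = sess)
  }
  mtext(paste("variant", x$variant), side = 3, line = -1.2, outer = TRUE)
  invisible(x)
}
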