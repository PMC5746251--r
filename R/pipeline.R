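#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: simulate (or ingest) a behavioral
#' dataset, fit the requested model variants to the group-mean d'
#' trajectories, rank them by AICc, optionally cross-validate the best
#' variant against the noise ceiling, refit on training days only to
#' predict orientation transfer, and collect everything — including the
#' per-session uncertainty trajectories implied by each fit and a
#' provenance block — into a report.
#'
#' @param data a behavioral dataset, or `NULL` to simulate one from `spec`.
#' @param spec a [cohort_spec()] used when `data` is `NULL`.
#' @param variants model variants to fit (default all four).
#' @param sessions `"all"` or `"training"` (see [fit_search_model()]).
#' @param config a [search_config()].
#' @param n_trials,n_starts fitting settings per variant.
#' @param cv_variant variant to cross-validate with [loo_cv()], or `NULL`
#'   to skip cross-validation.
#' @param cv_n_starts starts per cross-validation refit.
#' @param transfer_variants variants refit on training days only to predict
#'   the orientation test (default `c("R", "RL")`); `NULL` skips.
#' @param seed master seed; every stage derives its own stream from it.
#' @param correction extreme-rate correction for d'.
#' @param output_dir optional directory; when given, the dataset (CSV), the
#'   AICc table (CSV) and the report (JSON) are written there.
#' @return An object of class `"search_report"` with elements `dataset`,
#'   `fits`, `aicc_table`, `cv`, `transfer`, `sigma`, `provenance`.
#' @examples
#' rep <- run_pipeline(spec = cohort_spec(trials_per_session = 80, seed = 2),
#'                     n_trials = 300, n_starts = 2, cv_variant = NULL,
#'                     transfer_variants = NULL, seed = 2)
#' rep$aicc_table
#' @export
run_pipeline <- function(data = NULL, spec = cohort_spec(),
                         variants = c("R", "L", "RL", "RLG"),
                         sessions = "all", config = search_config(),
                         n_trials = 4000L, n_starts = 20L,
                         cv_variant = NULL, cv_n_starts = max(1L, n_starts %/% 2L),
                         transfer_variants = c("R", "RL"),
                         seed = 1L, correction = "loglinear",
                         output_dir = NULL) {
  if (!length(variants)) stop_invalid("need at least one variant")
  variants <- match.arg(variants, .variants, several.ok = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  dataset <- stage("data", {
    if (is.null(data)) simulate_cohort(spec, config, correction)
    else { stopifnot(inherits(data, "behavioral_dataset")); data }
  })

  fits <- stage("fit", {
    out <- lapply(seq_along(variants), function(i)
      fit_search_model(dataset, variants[i], sessions = sessions,
                       config = config, n_trials = n_trials,
                       n_starts = n_starts, seed = derive_seed(seed, i),
                       correction = correction))
    names(out) <- variants
    out
  })

  aicc_table <- stage("compare", {
    tab <- data.frame(
      variant = variants,
      k = vapply(fits, `[[`, integer(1), "k"),
      sse = vapply(fits, `[[`, numeric(1), "sse"),
      aicc = vapply(fits, `[[`, numeric(1), "aicc"),
      stringsAsFactors = FALSE)
    tab$delta_aicc <- tab$aicc - min(tab$aicc)
    tab[order(tab$aicc), ]
  })

  cv <- if (is.null(cv_variant)) NULL else stage("crossval",
    loo_cv(dataset, cv_variant, sessions = sessions, config = config,
           n_trials = n_trials, n_starts = cv_n_starts,
           seed = derive_seed(seed, 101L), correction = correction))

  transfer <- if (is.null(transfer_variants) ||
                  !"OrTest" %in% session_labels(dataset)) NULL else
    stage("predict-transfer", {
      obs <- group_means(dataset)
      lapply(stats::setNames(transfer_variants, transfer_variants),
             function(v) {
        tf <- fit_search_model(dataset, v, sessions = "training",
                               config = config, n_trials = n_trials,
                               n_starts = n_starts,
                               seed = derive_seed(seed, 201L),
                               correction = correction)
        pred <- predict_transfer(tf)
        list(fit = tf, predicted_test = pred,
             observed_test = obs[, "OrTest"],
             observed_day6 = obs[, paste0("D", tf$n_training)])
      })
    })

  sigma <- stage("report", {
    out <- lapply(fits, function(f)
      sigma_trajectories(f$params, n_training = f$n_training))
    out
  })

  report <- structure(list(
    dataset = dataset, fits = fits, aicc_table = aicc_table, cv = cv,
    transfer = transfer, sigma = sigma,
    provenance = list(package_version = as.character(packageVersion("searchvpl")),
                      seed = as.integer(seed),
                      settings = list(variants = variants, sessions = sessions,
                                      n_trials = n_trials, n_starts = n_starts,
                                      correction = correction),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "search_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(dataset, file.path(output_dir, "dataset.csv"))
    write.csv(aicc_table, file.path(output_dir, "aicc_table.csv"),
              row.names = FALSE)
    jsonlite::write_json(report_as_list(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# JSON-friendly view of a report (numbers, vectors and small tables only)
report_as_list <- function(report) {
  fits <- lapply(report$fits, function(f)
    list(variant = f$variant, coefficients = as.list(coef(f)), sse = f$sse,
         aicc = f$aicc, n_points = f$n_points, k = f$k,
         seed = f$settings$seed, n_trials = f$settings$n_trials,
         n_starts = f$settings$n_starts,
         best_start = f$best_start,
         start_final_sse = f$starts$final_sse,
         observed = apply(f$observed, 1, as.list),
         fitted = apply(f$fitted, 1, as.list)))
  cv <- if (is.null(report$cv)) NULL else
    list(variant = report$cv$variant, mean_r2 = report$cv$mean_r2,
         sd_r2 = report$cv$sd_r2, ceiling_lower = report$cv$ceiling_lower,
         ceiling_upper = report$cv$ceiling_upper,
         per_observer = report$cv$per_observer)
  transfer <- if (is.null(report$transfer)) NULL else
    lapply(report$transfer, function(t)
      list(coefficients = as.list(coef(t$fit)),
           predicted_test = as.list(t$predicted_test),
           observed_test = as.list(t$observed_test),
           observed_day6 = as.list(t$observed_day6)))
  list(fits = fits, aicc_table = report$aicc_table, cv = cv,
       transfer = transfer, sigma = report$sigma,
       provenance = report$provenance)
}

#' @export
print.search_report <- function(x, digits = 3, ...) {
  cat("Search-VPL pipeline report (seed ", x$provenance$seed, ")\n\n", sep = "")
  cat("AICc ranking:\n")
  tab <- x$aicc_table
  tab$sse <- round(tab$sse, digits)
  tab$aicc <- round(tab$aicc, digits)
  tab$delta_aicc <- round(tab$delta_aicc, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$cv)) { cat("\n"); print(x$cv, digits = digits) }
  if (!is.null(x$transfer)) {
    cat("\nTransfer predictions (training-only fits):\n")
    for (v in names(x$transfer)) {
      t <- x$transfer[[v]]
      cat("  ", v, ": predicted test d' ",
          paste(sprintf("%s = %.2f", names(t$predicted_test),
                        t$predicted_test), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
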