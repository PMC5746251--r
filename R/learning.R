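#' Exponential learning curve for orientation uncertainty
#'
#' Training reduces the uncertainty of an orientation representation over
#' sessions as \eqn{\sigma(t) = \sigma_0 (1 + e^{-\tau t})}: uncertainty
#' starts at \eqn{2\sigma_0} on day 1 (t = 0) and decays towards the
#' asymptote \eqn{\sigma_0} at per-session rate \eqn{\tau}.
#'
#' @param sigma0 asymptotic uncertainty in degrees (> 0).
#' @param tau per-session learning rate (>= 0).
#' @param t sessions elapsed since the first training session (>= 0); may be
#'   a vector.
#' @return Uncertainty in degrees, same length as `t`.
#' @examples
#' uncertainty_at(5, 0.65, 0:5)
#' @export
uncertainty_at <- function(sigma0, tau, t) {
  if (!is.finite(sigma0) || sigma0 <= 0) stop_invalid("'sigma0' must be > 0")
  if (!is.finite(tau) || tau < 0) stop_invalid("'tau' must be >= 0")
  if (any(!is.finite(t)) || any(t < 0)) stop_invalid("'t' must be >= 0")
  sigma0 * (1 + exp(-tau * t))
}

.groups <- c("near-cardinal", "oblique")
.variants <- c("R", "L", "RL", "RLG")

.rate_names <- list(
  R   = "tau",
  L   = c("tau_target", "tau_distractor"),
  RL  = c("tau_target", "tau_distractor"),
  RLG = c("tau_target_cardinal", "tau_distractor_cardinal",
          "tau_target_oblique", "tau_distractor_oblique"))

#' Which orientation's uncertainty plays the target and distractor role
#'
#' During training, the near-cardinal group searches for the near-cardinal
#' target among oblique distractors, so its sigma_T is the cardinal
#' orientation's uncertainty and its sigma_D the oblique orientation's; the
#' oblique group has the transposed assignment.
#'
#' @param group `"near-cardinal"` or `"oblique"`.
#' @return Named character vector with elements `sigma_target` and
#'   `sigma_distractor`, each `"cardinal"` or `"oblique"`.
#' @examples
#' role_mapping("near-cardinal")
#' @export
role_mapping <- function(group) {
  if (length(group) != 1L || !group %in% .groups)
    stop_invalid("'group' must be one of: ", paste(.groups, collapse = ", "))
  if (group == "near-cardinal")
    c(sigma_target = "cardinal", sigma_distractor = "oblique")
  else
    c(sigma_target = "oblique", sigma_distractor = "cardinal")
}

#' Free parameters of one observer-model variant
#'
#' The four nested variants differ in which asymmetries they allow:
#' \describe{
#'   \item{R (Reliability)}{initial uncertainty differs by orientation, one
#'     shared learning rate `tau` (3 parameters).}
#'   \item{L (Learning)}{one initial uncertainty for both orientations,
#'     separate rates for the training target and distractor roles,
#'     `tau_target` and `tau_distractor` (3 parameters).}
#'   \item{RL (Reliability-and-Learning)}{orientation-specific initial
#'     uncertainties and role-specific rates (4 parameters).}
#'   \item{RLG (Reliability-Learning-Group)}{orientation-specific initial
#'     uncertainties and rates specific to role-by-orientation, i.e.
#'     independent for the two groups (6 parameters).}
#' }
#' Learning rates attach to the role an orientation holds during training;
#' an orientation keeps its learned state when roles swap at the
#' orientation-transfer test.
#'
#' @param variant `"R"`, `"L"`, `"RL"` or `"RLG"`.
#' @param sigma_cardinal asymptotic uncertainty of the near-cardinal
#'   orientation, degrees (> 0).
#' @param sigma_oblique asymptotic uncertainty of the oblique orientation;
#'   under `"L"` it is forced equal to `sigma_cardinal`.
#' @param rates named numeric vector of learning rates; required names are
#'   `tau` (R), `tau_target`/`tau_distractor` (L, RL), or
#'   `tau_target_cardinal`, `tau_distractor_cardinal`, `tau_target_oblique`,
#'   `tau_distractor_oblique` (RLG). All rates must be >= 0.
#' @return An object of class `"variant_params"`.
#' @examples
#' variant_params("RL", sigma_cardinal = 5.5, sigma_oblique = 6.9,
#'                rates = c(tau_target = 0.24, tau_distractor = 0.65))
#' @export
variant_params <- function(variant = c("RL", "R", "L", "RLG"),
                           sigma_cardinal, sigma_oblique = sigma_cardinal,
                           rates) {
  variant <- match.arg(variant)
  if (!is.finite(sigma_cardinal) || sigma_cardinal <= 0 ||
      !is.finite(sigma_oblique) || sigma_oblique <= 0)
    stop_invalid("initial uncertainties must be positive and finite")
  if (variant == "L" && sigma_oblique != sigma_cardinal)
    stop_invalid("variant 'L' has a single initial uncertainty; ",
                 "'sigma_oblique' must equal 'sigma_cardinal'")
  wanted <- .rate_names[[variant]]
  if (!is.numeric(rates) || is.null(names(rates)) ||
      !setequal(names(rates), wanted) || length(rates) != length(wanted))
    stop_invalid("variant '", variant, "' needs rates named: ",
                 paste(wanted, collapse = ", "))
  rates <- rates[wanted]
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_invalid("learning rates must be finite and >= 0")
  structure(list(variant = variant, sigma_cardinal = sigma_cardinal,
                 sigma_oblique = sigma_oblique, rates = rates),
            class = "variant_params")
}

#' @export
print.variant_params <- function(x, digits = 4, ...) {
  cat("Model variant ", x$variant, " (", n_free_params(x$variant),
      " free parameters)\n", sep = "")
  print(round(pack_params(x), digits))
  invisible(x)
}

#' Number of free parameters of a variant
#' @param variant `"R"`, `"L"`, `"RL"` or `"RLG"`.
#' @return Integer count: 3, 3, 4 or 6.
#' @export
n_free_params <- function(variant) {
  variant <- match.arg(variant, .variants)
  n_sigma <- if (variant == "L") 1L else 2L
  n_sigma + length(.rate_names[[variant]])
}

#' Flatten variant parameters to an ordered vector and back
#'
#' The canonical order is the initial uncertainties followed by the
#' variant's learning rates: `R` packs `(sigma_cardinal, sigma_oblique,
#' tau)`; `L` packs `(sigma0, tau_target, tau_distractor)`; `RL` and `RLG`
#' prepend both uncertainties to their rate sets. `unpack_params()` is the
#' exact inverse.
#'
#' @param params a [variant_params()] object.
#' @return `pack_params()`: named numeric vector of length 3, 3, 4 or 6.
#' @examples
#' p <- variant_params("R", 5, 8, rates = c(tau = 0.4))
#' unpack_params(pack_params(p), "R")
#' @export
pack_params <- function(params) {
  stopifnot(inherits(params, "variant_params"))
  if (params$variant == "L")
    c(sigma0 = params$sigma_cardinal, params$rates)
  else
    c(sigma_cardinal = params$sigma_cardinal,
      sigma_oblique = params$sigma_oblique, params$rates)
}

#' @rdname pack_params
#' @param x numeric vector as produced by `pack_params()`.
#' @param variant `"R"`, `"L"`, `"RL"` or `"RLG"`.
#' @export
unpack_params <- function(x, variant = c("RL", "R", "L", "RLG")) {
  variant <- match.arg(variant)
  k <- n_free_params(variant)
  if (!is.numeric(x) || length(x) != k)
    stop_invalid("variant '", variant, "' expects a parameter vector of length ", k)
  rn <- .rate_names[[variant]]
  if (variant == "L") {
    rates <- x[2:3]
    names(rates) <- rn
    variant_params("L", sigma_cardinal = unname(x[1L]), rates = rates)
  } else {
    rates <- x[-(1:2)]
    names(rates) <- rn
    variant_params(variant, sigma_cardinal = unname(x[1L]),
                   sigma_oblique = unname(x[2L]), rates = rates)
  }
}

# learning rate attached to `orientation` ("cardinal"/"oblique") for a group,
# via the role the orientation holds during that group's training
.rate_for <- function(params, group, orientation) {
  map <- role_mapping(group)
  role <- if (map[["sigma_target"]] == orientation) "target" else "distractor"
  switch(params$variant,
         R = params$rates[["tau"]],
         L = ,
         RL = params$rates[[paste0("tau_", role)]],
         RLG = params$rates[[paste0("tau_", role, "_", orientation)]])
}

.sigma0_for <- function(params, orientation) {
  if (orientation == "cardinal") params$sigma_cardinal else params$sigma_oblique
}

#' Measurement uncertainties in force on a given session
#'
#' Combines the learning curve, the group's role mapping and the phase:
#' during training session `s` each orientation's uncertainty has decayed
#' for `t = s - 1` sessions at its variant-specific rate; at the
#' orientation-transfer test both orientations carry their end-of-training
#' uncertainty (t = `n_training - 1`) but the target/distractor roles are
#' swapped relative to training.
#'
#' @param params a [variant_params()] object.
#' @param group `"near-cardinal"` or `"oblique"`.
#' @param session_index training session number, 1-based (ignored at test).
#' @param phase `"training"` or `"orientation-test"`.
#' @param n_training number of training sessions (default 6).
#' @return A [reliability_pair()].
#' @examples
#' p <- variant_params("RL", 5.5, 6.9,
#'                     rates = c(tau_target = 0.24, tau_distractor = 0.65))
#' session_reliabilities(p, "near-cardinal", 1)
#' session_reliabilities(p, "near-cardinal", phase = "orientation-test")
#' @export
session_reliabilities <- function(params, group, session_index = 1L,
                                  phase = c("training", "orientation-test"),
                                  n_training = 6L) {
  stopifnot(inherits(params, "variant_params"))
  phase <- match.arg(phase)
  map <- role_mapping(group)
  sigma_of <- function(orientation, t)
    uncertainty_at(.sigma0_for(params, orientation),
                   .rate_for(params, group, orientation), t)
  if (phase == "training") {
    session_index <- as.integer(session_index)
    if (is.na(session_index) || session_index < 1L ||
        session_index > n_training)
      stop_invalid("'session_index' must be in 1..", n_training)
    t <- session_index - 1L
    reliability_pair(sigma_of(map[["sigma_target"]], t),
                     sigma_of(map[["sigma_distractor"]], t))
  } else {
    t_end <- n_training - 1L
    # roles swap: the training distractor orientation becomes the target
    reliability_pair(sigma_of(map[["sigma_distractor"]], t_end),
                     sigma_of(map[["sigma_target"]], t_end))
  }
}

#' Per-session uncertainty trajectories implied by a parameter set
#'
#' Tabulates sigma_T and sigma_D for every training session and the
#' orientation-transfer test, for one or both groups — the model analogue of
#' plotting estimated inverse reliability against training day.
#'
#' @inheritParams session_reliabilities
#' @param group groups to tabulate (default both).
#' @return A data frame with columns `group`, `session_label`, `phase`,
#'   `sigma_target`, `sigma_distractor`.
#' @export
sigma_trajectories <- function(params, group = .groups, n_training = 6L) {
  rows <- list()
  for (g in group) {
    for (s in seq_len(n_training)) {
      rp <- session_reliabilities(params, g, s, "training", n_training)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, session_label = paste0("D", s), phase = "training",
        sigma_target = rp$sigma_target, sigma_distractor = rp$sigma_distractor,
        stringsAsFactors = FALSE)
    }
    rp <- session_reliabilities(params, g, phase = "orientation-test",
                                n_training = n_training)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, session_label = "OrTest", phase = "orientation-test",
      sigma_target = rp$sigma_target, sigma_distractor = rp$sigma_distractor,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
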