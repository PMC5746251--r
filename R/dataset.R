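#' Behavioral dataset of per-observer, per-session search performance
#'
#' A `behavioral_dataset` is a data frame with one row per observer-session
#' and columns `observer_id`, `group`, `session_label`, `n_present`, `hits`,
#' `n_absent`, `false_alarms`, `dprime`, `criterion`. Session labels are
#' `D1..Dk` for training days plus optionally `OrTest` for the
#' orientation-transfer test; groups are `"near-cardinal"` and `"oblique"`.
#' `as_behavioral_dataset()` validates the schema and the count invariants
#' (`hits <= n_present`, `false_alarms <= n_absent`, nonnegative counts).
#'
#' @param x a data frame with the columns above (`dprime`/`criterion` are
#'   recomputed from the counts if absent).
#' @param correction extreme-rate correction used when recomputing d', see
#'   [sensitivity_and_bias()].
#' @return An object of classes `c("behavioral_dataset", "data.frame")`.
#' @export
as_behavioral_dataset <- function(x, correction = "loglinear") {
  if (!is.data.frame(x)) stop_invalid("expected a data frame")
  required <- c("observer_id", "group", "session_label", "n_present",
                "hits", "n_absent", "false_alarms")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop_invalid("missing column(s): ", paste(missing_cols, collapse = ", "))
  x$group <- as.character(x$group)
  x$session_label <- as.character(x$session_label)
  if (!all(x$group %in% .groups))
    stop_invalid("'group' must be one of: ", paste(.groups, collapse = ", "))
  counts <- c("n_present", "hits", "n_absent", "false_alarms")
  for (cc in counts) {
    v <- x[[cc]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stop_invalid("column '", cc, "' must hold nonnegative integer counts")
  }
  if (any(x$hits > x$n_present))
    stop_invalid("'hits' cannot exceed 'n_present'")
  if (any(x$false_alarms > x$n_absent))
    stop_invalid("'false_alarms' cannot exceed 'n_absent'")
  if (is.null(x$dprime) || is.null(x$criterion)) {
    sb <- t(mapply(function(h, np, f, na)
      sensitivity_and_bias(response_counts(h, np - h, f, na - f),
                           correction = correction),
      x$hits, x$n_present, x$false_alarms, x$n_absent))
    x$dprime <- sb[, "dprime"]
    x$criterion <- sb[, "criterion"]
  }
  class(x) <- c("behavioral_dataset", "data.frame")
  x
}

# ordered session labels present in a dataset
session_labels <- function(data) {
  labs <- unique(data$session_label)
  train <- sort(labs[grepl("^D[0-9]+$", labs)])
  train <- train[order(as.integer(sub("^D", "", train)))]
  c(train, intersect("OrTest", labs))
}

#' Group-mean sensitivity per session
#'
#' Averages d' across the observers of each group for each session — the
#' quantity the model variants are fitted to.
#'
#' @param data a [as_behavioral_dataset()] object.
#' @param sessions session labels to include, in order; default all present.
#' @param observers optional subset of observer ids to average over.
#' @return Numeric matrix with one row per group and one column per session.
#' @export
group_means <- function(data, sessions = NULL, observers = NULL) {
  stopifnot(inherits(data, "behavioral_dataset"))
  if (!is.null(observers)) data <- data[data$observer_id %in% observers, ]
  if (is.null(sessions)) sessions <- session_labels(data)
  miss <- setdiff(sessions, unique(data$session_label))
  if (length(miss))
    stop_invalid("session(s) absent from dataset: ", paste(miss, collapse = ", "))
  grps <- intersect(.groups, unique(data$group))
  out <- matrix(NA_real_, length(grps), length(sessions),
                dimnames = list(grps, sessions))
  for (g in grps) for (s in sessions)
    out[g, s] <- mean(data$dprime[data$group == g & data$session_label == s])
  out
}

#' Read and write behavioral datasets as CSV
#'
#' The CSV schema is one row per observer-session with the columns of
#' [as_behavioral_dataset()]. Counts round-trip exactly; d' and criterion
#' round-trip to full double precision.
#'
#' @param data a behavioral dataset.
#' @param path file path.
#' @return `read_dataset()` returns a validated `behavioral_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "behavioral_dataset"))
  df <- as.data.frame(data)
  df$dprime <- format(df$dprime, digits = 17, trim = TRUE)
  df$criterion <- format(df$criterion, digits = 17, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_behavioral_dataset(df)
}
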