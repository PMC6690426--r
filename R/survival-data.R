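#' Construct and validate a survival dataset
#'
#' Bundles per-patient follow-up times, event indicators and group labels
#' into the validated container used by every test and diagnostic in the
#' package.  Groups are re-indexed to integers `1..K` in order of first
#' appearance; the original labels are kept and reported in all outputs.
#'
#' Validation enforces the assumptions of the conditional log-rank test:
#' non-negative finite times, at least two patients, at least two groups
#' each with at least one member, and at least one observed event in the
#' pooled data (with zero events the statistic is undefined).  Events must
#' be coded as logical or as 0/1; any other coding is an error rather than
#' a silent guess, because miscoding event versus censor is the classic
#' survival-analysis bug.  A time of zero is allowed and enters the first
#' risk set.
#'
#' @param time numeric vector of non-negative follow-up times (any
#'   consistent unit).
#' @param event event indicators: `TRUE`/`FALSE` or `1`/`0`
#'   (`TRUE`/`1` = event observed, `FALSE`/`0` = right-censored).
#' @param group group labels (character, factor or numeric); `K >= 2`
#'   distinct values.
#' @param id optional patient identifiers (used when joining clustering
#'   solutions supplied by id).
#' @return An object of class `survival_dataset`: a list with elements
#'   `time`, `event` (logical), `group` (integer codes `1..K`),
#'   `levels` (original labels in first-appearance order), `n`, `k`
#'   and optionally `id`.
#' @examples
#' d <- survival_dataset(time = c(1, 2, 3, 4),
#'                       event = c(1, 1, 1, 1),
#'                       group = c("A", "A", "B", "B"))
#' d$n
#' d$levels
#' @export
survival_dataset <- function(time, event, group, id = NULL) {
  n <- length(time)
  if (length(event) != n || length(group) != n)
    stop("time, event and group must have equal length")
  if (!is.null(id) && length(id) != n)
    stop("id must have the same length as time")
  if (n < 2L) stop("need at least 2 patients")

  time <- as.numeric(time)
  if (anyNA(time) || any(!is.finite(time)))
    stop("non-finite or missing time at row(s): ",
         paste(which(!is.finite(time)), collapse = ", "))
  if (any(time < 0))
    stop("negative time at row(s): ",
         paste(which(time < 0), collapse = ", "))

  if (is.logical(event)) {
    ev <- event
  } else if (is.numeric(event) && all(event %in% c(0, 1))) {
    ev <- event == 1
  } else {
    stop("event must be logical or coded 0/1 (0 = censored, 1 = event)")
  }
  if (anyNA(ev)) stop("missing event indicator")
  if (!any(ev)) stop("no events: the log-rank statistic is undefined")

  if (anyNA(group)) stop("missing group label")
  lev <- unique(as.character(group))
  if (length(lev) < 2L) stop("K < 2: need at least two groups")
  g <- match(as.character(group), lev)

  structure(
    list(time = time, event = ev, group = g, levels = lev,
         n = n, k = length(lev), id = id),
    class = "survival_dataset"
  )
}

#' Coerce a data frame of patient records to a survival dataset
#'
#' @param x a data frame with one row per patient.
#' @param time_col,event_col,group_col,id_col column names (default
#'   `"time"`, `"event"`, `"group"`; `id_col = NULL` for none).
#' @return A validated [survival_dataset()].
#' @export
as_survival_dataset <- function(x, time_col = "time", event_col = "event",
                                group_col = "group", id_col = NULL) {
  stopifnot(is.data.frame(x))
  need <- c(time_col, event_col, group_col, id_col)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  survival_dataset(x[[time_col]], x[[event_col]], x[[group_col]],
                   id = if (is.null(id_col)) NULL else x[[id_col]])
}

#' @export
as.data.frame.survival_dataset <- function(x, ...) {
  out <- data.frame(time = x$time, event = as.integer(x$event),
                    group = x$levels[x$group], stringsAsFactors = FALSE)
  if (!is.null(x$id)) out <- cbind(id = x$id, out)
  out
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("Survival dataset: %d patients, %d groups, %d events\n",
              x$n, x$k, sum(x$event)))
  sizes <- tabulate(x$group, x$k)
  events <- vapply(seq_len(x$k), function(j) sum(x$event[x$group == j]), 0L)
  cat("  group sizes:  ",
      paste(sprintf("%s=%d (%d events)", x$levels, sizes, events),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Replace the per-patient (time, event) columns, keeping groups/labels.
replace_times <- function(data, time, event) {
  data$time <- as.numeric(time)
  data$event <- as.logical(event)
  data
}

#' Risk table at the observed event times
#'
#' Builds the sufficient statistic of the conditional log-rank test: for
#' each distinct time with at least one event, the number of patients at
#' risk and the number of events, in total and per group.  Patients
#' censored exactly at an event time are counted at risk at that time
#' (events precede censorings at ties, the standard survival convention).
#'
#' @param data a [survival_dataset()].
#' @return A data frame of class `risk_table` with columns `time`,
#'   `n_risk`, `n_event`, and per-group columns `n_risk_<label>` and
#'   `n_event_<label>`.
#' @examples
#' d <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' risk_table(d)
#' @export
risk_table <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  ord <- order(data$time, method = "radix")
  tt <- data$time[ord]; ev <- data$event[ord]; gg <- data$group[ord]
  K <- data$k

  ut <- unique(tt[ev])                      # distinct event times, ascending
  m <- length(ut)
  n_risk <- integer(m); n_event <- integer(m)
  nr_g <- matrix(0L, m, K); ne_g <- matrix(0L, m, K)
  for (i in seq_len(m)) {
    at <- tt >= ut[i]
    n_risk[i] <- sum(at)
    nr_g[i, ] <- tabulate(gg[at], K)
    here <- ev & tt == ut[i]
    n_event[i] <- sum(here)
    ne_g[i, ] <- tabulate(gg[here], K)
  }
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event)
  colnames(nr_g) <- paste0("n_risk_", data$levels)
  colnames(ne_g) <- paste0("n_event_", data$levels)
  out <- cbind(out, nr_g, ne_g)
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of the event-time distribution from
#' right-censored data.  Flipping the event flag (`1 - event`) yields the
#' reverse Kaplan-Meier estimate of the follow-up (censoring) distribution,
#' as used by the follow-up-conditioned permutation scheme.
#'
#' @param time numeric follow-up times.
#' @param event event indicators (logical or 0/1).
#' @return An object of class `km_curve`: a data frame with one row per
#'   distinct event time and columns `time`, `n_risk`, `n_event`,
#'   `survival` (the product-limit estimate just after that time).
#' @examples
#' kaplan_meier(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(time, event) {
  time <- as.numeric(time)
  event <- if (is.logical(event)) event else event == 1
  stopifnot(length(time) == length(event), all(time >= 0))
  if (!any(event)) stop("no events: Kaplan-Meier estimate is degenerate")
  ord <- order(time, method = "radix")
  tt <- time[ord]; ev <- event[ord]
  n <- length(tt)
  ut <- unique(tt[ev])
  m <- length(ut)
  n_risk <- integer(m); n_event <- integer(m)
  for (i in seq_len(m)) {
    n_risk[i] <- sum(tt >= ut[i])
    n_event[i] <- sum(ev & tt == ut[i])
  }
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  class(out) <- c("km_curve", "data.frame")
  attr(out, "tmax") <- max(tt)
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", nrow(x), "event times\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Plot a Kaplan-Meier curve per group
#'
#' Step-function survival curves, one per group, drawn with base graphics.
#' A significant log-rank p-value should always be accompanied by a look at
#' the curves themselves: the test rejects when any single group differs
#' and has low power against crossing curves.
#'
#' @param x a [survival_dataset()].
#' @param col colours, recycled over groups.
#' @param ... passed to [graphics::plot()].
#' @export
plot_km <- function(x, col = seq_len(x$k), ...) {
  stopifnot(inherits(x, "survival_dataset"))
  col <- rep_len(col, x$k)
  graphics::plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = "time", ylab = "survival", ...)
  for (j in seq_len(x$k)) {
    sel <- x$group == j
    if (!any(x$event[sel])) next
    km <- kaplan_meier(x$time[sel], x$event[sel])
    graphics::lines(stats::stepfun(km$time, c(1, km$survival)), col = col[j],
                    do.points = FALSE)
  }
  graphics::legend("topright", legend = x$levels, col = col, lty = 1)
  invisible(x)
}
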