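#' Kaplan-Meier survival curve
#'
#' Product-limit estimate S(t) = prod_{t_i <= t} (1 - d_i / n_i) over the
#' distinct observed times, computed via \code{survival::survfit}. Events
#' occurring at the same time as censorings precede them (the standard
#' convention).
#'
#' @param records Data frame with numeric \code{time} (months, > 0) and
#'   binary \code{event} (1 = event observed, 0 = censored).
#' @return Object of class \code{"km_curve"}: list with \code{time},
#'   \code{surv}, \code{n_risk}, \code{n_event} at each distinct observed
#'   time. \code{S(0) = 1} implicitly precedes the first entry.
#' @examples
#' km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 1, 1)))
#' @export
km_estimate <- function(records) {
  .check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "km_curve")
}

.check_records <- function(records, need_group = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame")
  }
  if (!all(c("time", "event") %in% names(records))) {
    stop("records must have columns 'time' and 'event'")
  }
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("times must be finite and positive")
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be binary (1 = observed, 0 = censored)")
  }
  if (need_group && !"group" %in% names(records)) {
    stop("records must have a 'group' column")
  }
  invisible(TRUE)
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest event time t with S(t) <= 0.5. Returns \code{NA} when the
#' curve never drops to 0.5 (median not reached).
#'
#' @param curve A \code{"km_curve"} from [km_estimate()].
#' @return Months (numeric scalar), or \code{NA_real_} when not reached.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  at_event <- curve$n_event > 0
  t_ev <- curve$time[at_event]
  s_ev <- curve$surv[at_event]
  hit <- which(s_ev <= 0.5 + 1e-12)
  if (length(hit) == 0) NA_real_ else t_ev[hit[1]]
}

.logrank <- function(records) {
  if (sum(records$event) == 0) {
    message("no events in either group; log-rank statistic is 0")
    return(list(statistic = 0, df = length(unique(records$group)) - 1L,
                p_value = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  stat <- sd$chisq
  df <- length(sd$n) - 1L
  if (!is.finite(stat)) {
    message("zero log-rank variance; p defined as 1")
    return(list(statistic = 0, df = df, p_value = 1))
  }
  list(statistic = unname(stat), df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival distributions: at each
#' distinct event time, observed events in group a are compared with their
#' expectation under the pooled-risk hypergeometric model; the statistic
#' (sum(O - E))^2 / Var is referred to a chi-square with 1 df.
#'
#' @param records Data frame with columns \code{time}, \code{event},
#'   \code{group}.
#' @param group_a,group_b The two group labels to compare.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
logrank_test <- function(records, group_a, group_b) {
  .check_records(records, need_group = TRUE)
  sub <- records[records$group %in% c(group_a, group_b), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% sub$group)) {
    stop("both groups must be non-empty")
  }
  res <- .logrank(sub)
  list(statistic = res$statistic, p_value = res$p_value)
}

#' k-group log-rank test
#'
#' Extension of [logrank_test()] to all groups present in \code{records};
#' the statistic is chi-square with k - 1 degrees of freedom.
#'
#' @inheritParams logrank_test
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
multigroup_logrank <- function(records) {
  .check_records(records, need_group = TRUE)
  if (length(unique(records$group)) < 2) {
    stop("need at least two groups")
  }
  .logrank(records)
}
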