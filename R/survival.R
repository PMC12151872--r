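# Lifespan-assay statistics.  Records are plain data frames with columns
#   group    identifier
#   lifespan positive real (days, months or divisions; unit is metadata)
#   observed logical, FALSE = right-censored
# Kaplan-Meier and log-rank stand on the survival package; only the thin
# record-level contracts live here.

check_lifespan_records <- function(records, nm = "records") {
  req <- c("group", "lifespan", "observed")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop_input(sprintf("`%s` needs columns group, lifespan, observed", nm))
  if (nrow(records) == 0L)
    stop_input(sprintf("`%s` is empty", nm))
  if (anyNA(records$lifespan) || any(!is.finite(records$lifespan)) ||
      any(records$lifespan <= 0))
    stop_input("lifespans must be positive and finite")
  if (!is.logical(records$observed) || anyNA(records$observed))
    stop_input("`observed` must be TRUE/FALSE without missing values")
  records
}

#' Summarise one lifespan cohort
#'
#' The mean is taken over observed (uncensored) lifespans only; `n` is
#' the full cohort size.  When the cohort contains censored records the
#' median is read off the Kaplan-Meier curve (the 50% point), otherwise
#' it is the sample median.
#'
#' @param records Lifespan record data frame (`group`, `lifespan`,
#'   `observed`).
#' @param group Which group to summarise.
#' @param unit Time unit label carried through (default `"unit"`).
#' @return Data frame of class `"survival_summary"`: `group`, `n`,
#'   `n_events`, `mean`, `median`, `unit`.
#' @export
summarize_group <- function(records, group, unit = "unit") {
  records <- check_lifespan_records(records)
  rec <- records[records$group == group, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_input(sprintf("no records for group '%s'", group))
  obs <- rec$lifespan[rec$observed]
  if (length(obs) == 0L)
    stop_input(sprintf("group '%s' has no observed events", group))
  if (any(!rec$observed)) {
    fit <- survival::survfit(
      survival::Surv(rec$lifespan, rec$observed) ~ 1)
    med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  } else {
    med <- stats::median(rec$lifespan)
  }
  structure(
    data.frame(group = group, n = nrow(rec), n_events = length(obs),
               mean = mean(obs), median = med, unit = unit,
               stringsAsFactors = FALSE),
    class = c("survival_summary", "data.frame"))
}

#' Percent lifespan extension of a treatment group over its control
#'
#' \eqn{100 (m_T - m_C) / m_C}.  Headline values are conventionally
#' reported rounded to one decimal (e.g. `round(x, 1)`); the full
#' precision value is returned.
#'
#' @param mean_treatment,mean_control Group mean lifespans; the control
#'   mean must be positive.
#' @return Percent extension (full precision).
#' @examples
#' round(percent_extension(28.10, 23.92), 1)  # 17.5
#' @export
percent_extension <- function(mean_treatment, mean_control) {
  check_number(mean_treatment, "mean_treatment")
  check_number(mean_control, "mean_control", lower = 0, strict_lower = TRUE)
  100 * (mean_treatment - mean_control) / mean_control
}

#' Kaplan-Meier survival curve for a set of lifespan records
#'
#' Product-limit estimate via [survival::survfit()].  The returned step
#' curve starts at time 0 with survival 1 and is non-increasing; with no
#' censoring it equals the empirical survival function.
#'
#' @param records Lifespan record data frame (one group, or pooled).
#' @return Data frame: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
kaplan_meier <- function(records) {
  records <- check_lifespan_records(records)
  fit <- survival::survfit(
    survival::Surv(records$lifespan, records$observed) ~ 1)
  data.frame(
    time = c(0, fit$time),
    n_risk = c(nrow(records), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' risk sets (hypergeometric variance, no continuity correction), with a
#' 1-df chi-square p-value, via [survival::survdiff()].  Symmetric in
#' group order.
#'
#' @param a,b Lifespan record data frames for the two groups (their
#'   `group` columns are ignored; `a` and `b` define the grouping).
#' @return List: `chi_square`, `p_value`, `n` (per-group sizes),
#'   `events` (per-group observed events).
#' @export
log_rank_test <- function(a, b) {
  a <- check_lifespan_records(a, "a")
  b <- check_lifespan_records(b, "b")
  if (!any(a$observed) && !any(b$observed))
    stop_input("log-rank test needs at least one observed event")
  time <- c(a$lifespan, b$lifespan)
  event <- c(a$observed, b$observed)
  grp <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       n = c(a = nrow(a), b = nrow(b)),
       events = c(a = sum(a$observed), b = sum(b$observed)))
}

#' LOESS dose-response smoothing
#'
#' Local linear regression with tricube weights (no robustness
#' iterations), as used to relate knockdown level or expression fold
#' change to lifespan extension.  The neighbourhood holds
#' `floor(span * n)` points.  Local linear fits reproduce straight-line
#' input exactly.
#'
#' @param points Data frame with columns `dose` and `response` (dose may
#'   be an expression fold change or an RNAi fraction).
#' @param span Neighbourhood fraction in (0, 1], default 0.75.
#' @param grid_n Number of evaluation points for the smooth curve.
#' @return List of class `"loess_dose_response"`: `points` (input plus
#'   `fitted`), `grid` (data frame `dose`, `fit`), `span`.
#' @export
loess_dose_response <- function(points, span = 0.75, grid_n = 100) {
  if (!is.data.frame(points) || !all(c("dose", "response") %in% names(points)))
    stop_input("`points` needs columns dose and response")
  if (anyNA(points$dose) || anyNA(points$response) ||
      any(!is.finite(points$dose)) || any(!is.finite(points$response)))
    stop_input("dose and response must be finite")
  n <- nrow(points)
  check_number(span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  if (n < 4L)
    stop_insufficient("at least 4 points are required")
  if (floor(span * n) < 3L)
    stop_insufficient(
      sprintf("span %.2f with %d points leaves fewer than 3 neighbours",
              span, n))
  fit <- stats::loess(response ~ dose, data = points, span = span,
                      degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- data.frame(dose = seq(min(points$dose), max(points$dose),
                                length.out = grid_n))
  grid$fit <- as.numeric(stats::predict(fit, newdata = grid))
  pts <- points
  pts$fitted <- as.numeric(stats::fitted(fit))
  structure(list(points = pts, grid = grid, span = span),
            class = "loess_dose_response")
}
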