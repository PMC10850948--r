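DAYS_PER_MONTH <- 30.4375  # mean Gregorian month

#' Survival interval conventions
#'
#' The four time-to-event intervals used throughout the cohort analysis:
#' \describe{
#'   \item{PFS1}{checkpoint-inhibitor monotherapy start to radiologic
#'     progression (censored at last follow-up).}
#'   \item{OS1}{monotherapy start to death (censored at last follow-up).}
#'   \item{PFS2}{salvage-treatment start to progression or death.}
#'   \item{OS2}{salvage-treatment start to death (censored at last
#'     follow-up).}
#' }
#'
#' @return data frame naming each interval's start and stop anchors.
#' @export
interval_definitions <- function() {
  data.frame(
    name = c("PFS1", "OS1", "PFS2", "OS2"),
    start = c("mono_start", "mono_start", "salvage_start", "salvage_start"),
    stop = c("progression", "death", "progression or death", "death"),
    stringsAsFactors = FALSE)
}

#' Build survival records from dated anchors
#'
#' Converts per-subject anchor dates into time-to-event records under one
#' of the interval conventions. Times are in months using 30.4375
#' days/month. Subjects missing the interval's start anchor are dropped;
#' a stop date before the start date is an error naming the subject.
#'
#' @param events data frame with subject_id and Date (or "YYYY-MM-DD")
#'   columns `mono_start`, `salvage_start`, `progression_date`,
#'   `death_date`, `last_followup` (NA where not applicable), and
#'   optionally `group`.
#' @param definition one of `"PFS1"`, `"OS1"`, `"PFS2"`, `"OS2"`.
#' @return data frame: subject_id, group, time (months), event (0/1).
#' @export
build_intervals <- function(events, definition = c("PFS1", "OS1", "PFS2", "OS2")) {
  definition <- match.arg(definition)
  as_date <- function(x) if (inherits(x, "Date")) x else as.Date(x)
  start_col <- if (definition %in% c("PFS1", "OS1")) "mono_start" else "salvage_start"
  start <- as_date(events[[start_col]])
  prog <- as_date(events$progression_date)
  death <- as_date(events$death_date)
  fup <- as_date(events$last_followup)

  stop_date <- switch(definition,
    PFS1 = prog,
    OS1 = death,
    PFS2 = pmin(prog, death, na.rm = TRUE),
    OS2 = death)
  is_event <- !is.na(stop_date)
  stop_date[!is_event] <- fup[!is_event]

  keep <- !is.na(start) & !is.na(stop_date)
  start <- start[keep]; stop_date <- stop_date[keep]; is_event <- is_event[keep]
  ids <- events$subject_id[keep]
  bad <- stop_date < start
  if (any(bad))
    stop("stop date precedes start for subject(s): ",
         paste(ids[bad], collapse = ", "))
  data.frame(
    subject_id = ids,
    group = if ("group" %in% names(events)) events$group[keep] else NA_character_,
    time = as.numeric(stop_date - start) / DAYS_PER_MONTH,
    event = as.integer(is_event), stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate with median and 95% CI
#'
#' Product-limit estimator of the survival function. The median is the
#' earliest time at which the estimated survival drops to 0.5 or below;
#' its 95% confidence interval uses the log(-log) transform. With no
#' events, or a curve never reaching 0.5, the median is undefined (NA).
#'
#' @param records data frame with `time` (months) and `event` (0/1).
#' @return list of class `km_fit`: `fit` (the [survival::survfit] object),
#'   `median`, `median_ci` (lower, upper), `n`, `n_events`, `status`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0) stop("no records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log-log")
  status <- if (sum(records$event) == 0) "no_events" else "ok"
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  tab <- summary(fit)$table
  ci <- c(lower = unname(tab["0.95LCL"]), upper = unname(tab["0.95UCL"]))
  structure(list(fit = fit, median = med, median_ci = ci,
                 n = nrow(records), n_events = sum(records$event),
                 status = status),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: %d subjects, %d events; median %s months (95%% CI %s-%s)\n",
              x$n, x$n_events,
              ifelse(is.na(x$median), "not reached", format(x$median, digits = 4)),
              format(x$median_ci[1], digits = 4),
              format(x$median_ci[2], digits = 4)))
  invisible(x)
}

#' Two-sided log-rank test
#'
#' Standard log-rank comparison of survival between groups; chi-squared
#' statistic on (number of groups - 1) degrees of freedom.
#'
#' @param records data frame with `time`, `event` and `group`.
#' @return list of class `logrank_result`: statistic, df, p_value.
#' @export
logrank_test <- function(records) {
  groups <- unique(records$group)
  if (length(groups) < 2) stop("log-rank test requires >= 2 groups")
  if (sum(records$event) == 0) stop("log-rank test requires >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  df <- length(sd$n) - 1
  structure(list(statistic = sd$chisq, df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi-squared = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method (all tables
#' with probability no greater than the observed one, at fixed margins)
#' and the conditional maximum-likelihood odds ratio.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list of class `fisher_result`: p_value, odds_ratio, table.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of nonnegative integers")
  ft <- stats::fisher.test(tab)
  structure(list(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate), table = tab),
            class = "fisher_result")
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison: exact p when the combined sample size is
#' at most 20 and there are no ties, normal approximation with continuity
#' and tie correction otherwise. The U statistic counts (x, y) pairs with
#' x preceding y.
#'
#' @param x,y numeric samples.
#' @return list of class `wilcoxon_result`: U, p_value, method.
#' @export
wilcoxon_mw <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  structure(list(U = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation"),
            class = "wilcoxon_result")
}

#' Cohort percentage with the reporting rounding convention
#'
#' Percentages are rounded to the nearest integer, ties away from zero,
#' except when the exact value falls on a half percent (e.g. 12.5), which
#' is kept at one decimal — the convention behind printed values like 73%,
#' 69%, 12.5% and 62.5%.
#'
#' @param n numerator count(s).
#' @param d denominator count.
#' @return numeric percentage(s) on the 0-100 scale.
#' @export
cohort_percent <- function(n, d) {
  if (d <= 0) stop("denominator must be positive")
  pct <- 100 * n / d
  # exact half percents (12.5, 62.5, ...) keep their decimal; everything
  # else is rounded to the nearest whole percent
  exact_half <- abs(pct * 10 - round(pct * 10)) < 1e-9 &
    round(pct * 10) %% 10 == 5
  ifelse(exact_half, round_half_up(pct, 1), round_half_up(pct, 0))
}

#' Summarize best radiologic responses
#'
#' Tallies best responses per patient into CR/PR (objective response), SD
#' and PD, with the disease-control rate defined as CR + PR + SD.
#' Percentages follow [cohort_percent()].
#'
#' @param responses character vector, one best response per patient, each
#'   one of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @return list of class `response_summary`: n_total, table (category, n,
#'   pct), disease_control_n, disease_control_pct.
#' @export
summarize_responses <- function(responses) {
  ok <- c("CR", "PR", "SD", "PD")
  bad <- setdiff(unique(responses), ok)
  if (length(bad))
    stop("unknown response category: ", paste(bad, collapse = ", "))
  n <- length(responses)
  if (n == 0) stop("no responses supplied")
  n_crpr <- sum(responses %in% c("CR", "PR"))
  n_sd <- sum(responses == "SD")
  n_pd <- sum(responses == "PD")
  dc <- n_crpr + n_sd
  structure(list(
    n_total = n,
    table = data.frame(category = c("CR/PR", "SD", "PD"),
                       n = c(n_crpr, n_sd, n_pd),
                       pct = cohort_percent(c(n_crpr, n_sd, n_pd), n),
                       stringsAsFactors = FALSE),
    disease_control_n = dc,
    disease_control_pct = cohort_percent(dc, n)),
    class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("Best responses (n = %d):\n", x$n_total))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-5s %2d (%g%%)\n", x$table$category[i], x$table$n[i],
                x$table$pct[i]))
  cat(sprintf("  disease control %d (%g%%)\n",
              x$disease_control_n, x$disease_control_pct))
  invisible(x)
}
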