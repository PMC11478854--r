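#' 2x2 cohort-outcome contingency table
#'
#' Counts for a two-cohort comparison of a binary outcome: `n1`/`n2` subjects
#' per cohort, of whom `x1`/`x2` experienced the outcome.
#'
#' @param n1,x1 cohort-1 size and outcome count.
#' @param n2,x2 cohort-2 size and outcome count.
#' @return A `contingency_2x2`.
#' @examples
#' ct <- contingency_table(n1 = 453, x1 = 139, n2 = 453, x2 = 67)
#' risk(ct, 1)
#' @export
contingency_table <- function(n1, x1, n2, x2) {
  n1 <- as.integer(n1); x1 <- as.integer(x1)
  n2 <- as.integer(n2); x2 <- as.integer(x2)
  if (n1 < 1 || n2 < 1) stop("cohort sizes must be >= 1", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("outcome counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  structure(list(n1 = n1, x1 = x1, n2 = n2, x2 = x2),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("<contingency_2x2>\n",
      sprintf("  cohort 1: %d / %d (risk %.3f)\n", x$x1, x$n1, x$x1 / x$n1),
      sprintf("  cohort 2: %d / %d (risk %.3f)\n", x$x2, x$n2, x$x2 / x$n2))
  invisible(x)
}

#' Outcome risk (proportion) in one cohort
#' @param table a [contingency_table()].
#' @param cohort 1 or 2.
#' @return `x / n` for the cohort.
#' @export
risk <- function(table, cohort = 1) {
  stopifnot(cohort %in% c(1, 2))
  if (cohort == 1) table$x1 / table$n1 else table$x2 / table$n2
}

z975 <- function(conf_level) stats::qnorm(1 - (1 - conf_level) / 2)

#' Risk difference with Wald CI and pooled two-proportion z-test
#'
#' Point estimate `p1 - p2`; the confidence interval uses the unpooled Wald
#' standard error, while the z statistic uses the pooled proportion
#' `(x1+x2)/(n1+n2)` — the standard pairing in epidemiological software. The
#' p-value is two-sided normal.
#'
#' @param table a [contingency_table()].
#' @param conf_level confidence level (default 0.95).
#' @return List with `estimate`, `conf_low`, `conf_high`, `z`, `p`, and
#'   `degenerate` (`TRUE` when the pooled proportion is 0 or 1, leaving `z`
#'   undefined).
#' @export
risk_difference <- function(table, conf_level = 0.95) {
  p1 <- risk(table, 1); p2 <- risk(table, 2)
  n1 <- table$n1; n2 <- table$n2
  rd <- p1 - p2
  se_unpooled <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zq <- z975(conf_level)
  pooled <- (table$x1 + table$x2) / (n1 + n2)
  degenerate <- pooled %in% c(0, 1)
  z <- if (degenerate) NA_real_ else {
    rd / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  }
  list(estimate = rd,
       conf_low = rd - zq * se_unpooled,
       conf_high = rd + zq * se_unpooled,
       z = z,
       p = if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(z)),
       degenerate = degenerate)
}

#' Risk ratio with log-scale Wald CI
#'
#' `RR = p1 / p2`; the interval is
#' `exp(log RR +/- z * sqrt(1/x1 - 1/n1 + 1/x2 - 1/n2))` (Katz).
#'
#' @inheritParams risk_difference
#' @return List with `estimate`, `conf_low`, `conf_high`, and `infinite`
#'   (`TRUE` when `x2 = 0` so the ratio is unbounded).
#' @export
risk_ratio <- function(table, conf_level = 0.95) {
  p1 <- risk(table, 1); p2 <- risk(table, 2)
  if (table$x2 == 0) {
    return(list(estimate = Inf, conf_low = NA_real_, conf_high = NA_real_,
                infinite = TRUE))
  }
  rr <- p1 / p2
  if (table$x1 == 0) {
    return(list(estimate = 0, conf_low = NA_real_, conf_high = NA_real_,
                infinite = FALSE))
  }
  se <- sqrt(1 / table$x1 - 1 / table$n1 + 1 / table$x2 - 1 / table$n2)
  zq <- z975(conf_level)
  list(estimate = rr,
       conf_low = exp(log(rr) - zq * se),
       conf_high = exp(log(rr) + zq * se),
       infinite = FALSE)
}

#' Odds ratio with log-scale Wald CI
#'
#' `OR = (x1/(n1-x1)) / (x2/(n2-x2))`; the interval is
#' `exp(log OR +/- z * sqrt(1/x1 + 1/(n1-x1) + 1/x2 + 1/(n2-x2)))` (Woolf).
#' No continuity correction is applied: a zero cell is flagged instead.
#'
#' @inheritParams risk_difference
#' @return List with `estimate`, `conf_low`, `conf_high`, `zero_cell`.
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  a <- table$x1; b <- table$n1 - table$x1
  c <- table$x2; d <- table$n2 - table$x2
  if (any(c(a, b, c, d) == 0)) {
    est <- if (c == 0 || b == 0) Inf else 0
    return(list(estimate = est, conf_low = NA_real_, conf_high = NA_real_,
                zero_cell = TRUE))
  }
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- z975(conf_level)
  list(estimate = or,
       conf_low = exp(log(or) - zq * se),
       conf_high = exp(log(or) + zq * se),
       zero_cell = FALSE)
}

#' Full risk-analysis report for a 2x2 table
#'
#' The per-cohort risks plus risk difference (with z and p), risk ratio and
#' odds ratio, each with its 95% CI, as one tidy data.frame. P-values are
#' additionally formatted to 3 decimals with a "0.000" floor in
#' `p_formatted`.
#'
#' @inheritParams risk_difference
#' @return data.frame with columns `measure`, `estimate`, `conf_low`,
#'   `conf_high`, `z`, `p`, `p_formatted`.
#' @export
risk_analysis <- function(table, conf_level = 0.95) {
  rd <- risk_difference(table, conf_level)
  rr <- risk_ratio(table, conf_level)
  or <- odds_ratio(table, conf_level)
  data.frame(
    measure = c("risk_cohort1", "risk_cohort2", "risk_difference",
                "risk_ratio", "odds_ratio"),
    estimate = c(risk(table, 1), risk(table, 2), rd$estimate,
                 rr$estimate, or$estimate),
    conf_low = c(NA, NA, rd$conf_low, rr$conf_low, or$conf_low),
    conf_high = c(NA, NA, rd$conf_high, rr$conf_high, or$conf_high),
    z = c(NA, NA, rd$z, NA, NA),
    p = c(NA, NA, rd$p, NA, NA),
    p_formatted = c(NA, NA, format_p(rd$p), NA, NA),
    stringsAsFactors = FALSE
  )
}

format_p <- function(p) {
  if (is.null(p) || is.na(p)) return(NA_character_)
  sprintf("%.3f", max(p, 0))
}

#' Assemble a survival dataset
#'
#' @param time positive times to event or censoring (days).
#' @param event 1/TRUE = event observed, 0/FALSE = censored.
#' @param group group label per subject (two groups for [log_rank()]).
#' @return data.frame with columns `time`, `event`, `group`.
#' @export
survival_data <- function(time, event, group) {
  time <- as.numeric(time)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  data.frame(time = time, event = as.integer(as.logical(event)),
             group = as.character(group), stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival estimate for one group
#'
#' Product-limit estimator with standard tie handling (all events at a time
#' are processed before censorings at that time leave the risk set).
#' Computed via `survival::survfit`.
#'
#' @param data a [survival_data()] frame.
#' @param group which group to estimate; `NULL` uses all subjects.
#' @param horizon optional time at which to read off the survival
#'   probability (step-function value; last value carried beyond the final
#'   observed time).
#' @return List with `steps` (data.frame `time`, `n_risk`, `n_event`,
#'   `surv`) and `surv_at_horizon` (`NULL` when no horizon given).
#' @export
kaplan_meier <- function(data, group = NULL, horizon = NULL) {
  if (!is.null(group)) {
    data <- data[data$group == group, , drop = FALSE]
    if (nrow(data) == 0) stop("no subjects in group: ", group, call. = FALSE)
  }
  if (nrow(data) == 0) stop("empty survival dataset", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  surv_at <- NULL
  if (!is.null(horizon)) {
    idx <- which(steps$time <= horizon & steps$n_event > 0)
    surv_at <- if (length(idx) == 0) 1 else steps$surv[max(idx)]
  }
  list(steps = steps, surv_at_horizon = surv_at)
}

#' Two-group log-rank test with O/E hazard ratio
#'
#' The standard one-degree-of-freedom log-rank statistic over the shared
#' event times (via `survival::survdiff`), plus the Mantel-Haenszel-style
#' observed/expected hazard ratio `(O1/E1) / (O2/E2)` with a log-scale CI
#' using `sqrt(1/E1 + 1/E2)` as the standard error of the log ratio. Group 1
#' is the first group label in sort order.
#'
#' @param data a [survival_data()] frame with exactly two groups.
#' @param conf_level confidence level for the hazard-ratio CI.
#' @return List with `chisq`, `df`, `p`, `p_formatted`, `observed`,
#'   `expected` (length-2 vectors in group sort order), `hazard_ratio`,
#'   `hr_conf_low`, `hr_conf_high`, and `degenerate` (`TRUE` when either
#'   group has zero expected events, leaving the ratio undefined).
#' @export
log_rank <- function(data, conf_level = 0.95) {
  groups <- sort(unique(data$group))
  if (length(groups) != 2) {
    stop("log-rank comparison needs exactly two groups", call. = FALSE)
  }
  if (sum(data$event) == 0) {
    return(list(chisq = 0, df = 1L, p = 1, p_formatted = format_p(1),
                observed = c(0, 0), expected = c(0, 0),
                hazard_ratio = NA_real_, hr_conf_low = NA_real_,
                hr_conf_high = NA_real_, degenerate = TRUE))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  obs <- as.numeric(fit$obs)
  exp_ <- as.numeric(fit$exp)
  chisq <- as.numeric(fit$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  degenerate <- any(exp_ == 0) || any(obs == 0)
  hr <- if (any(exp_ == 0)) NA_real_ else (obs[1] / exp_[1]) / (obs[2] / exp_[2])
  zq <- z975(conf_level)
  if (!degenerate && is.finite(hr) && hr > 0) {
    se <- sqrt(1 / exp_[1] + 1 / exp_[2])
    lo <- exp(log(hr) - zq * se)
    hi <- exp(log(hr) + zq * se)
  } else {
    lo <- NA_real_; hi <- NA_real_
  }
  list(chisq = chisq, df = 1L, p = p, p_formatted = format_p(p),
       observed = obs, expected = exp_,
       hazard_ratio = hr, hr_conf_low = lo, hr_conf_high = hi,
       degenerate = degenerate)
}

#' Read survival records from CSV (columns `time`, `event`, `group`)
#' @param path CSV path.
#' @return A [survival_data()] frame.
#' @export
read_survival_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("time", "event", "group") %in% names(d)))
  survival_data(d$time, d$event, d$group)
}
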