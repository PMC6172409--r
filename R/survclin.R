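#' Dichotomize samples at the mean expression level
#'
#' High iff the value is greater than or equal to the mean (ties to
#' "high"). Errors when all values coincide, since one group would be
#' empty.
#'
#' @param expr per-sample expression values (named).
#' @return factor with levels `low`, `high`.
#' @export
mean_split <- function(expr) {
  if (length(expr) < 2) stop("need at least 2 samples")
  m <- mean(expr)
  g <- ifelse(expr >= m, "high", "low")
  if (length(unique(g)) < 2)
    stop("all values identical; mean split leaves one group empty")
  factor(g, levels = c("low", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times; at
#' tied times events are processed before censorings. Wraps
#' `survival::survfit`.
#'
#' @param time positive follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame of class `km_curve`: `time` (ascending distinct
#'   event times), `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("empty survival input")
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = FALSE)
  keep <- s$n.event > 0
  out <- data.frame(time = s$time[keep], n_risk = s$n.risk[keep],
                    n_event = s$n.event[keep], surv = s$surv[keep])
  structure(out, class = c("km_curve", "data.frame"))
}

#' Survival rate at a horizon
#'
#' The Kaplan-Meier estimate at the largest event time not exceeding the
#' horizon; 1 when no event occurred by then.
#'
#' @param km a [km_curve()].
#' @param horizon time point (> 0), e.g. 60 months for a 5-year rate.
#' @return survival proportion in `[0, 1]`.
#' @export
survival_rate_at <- function(km, horizon) {
  stopifnot(horizon > 0)
  idx <- which(km$time <= horizon)
  if (length(idx) == 0) return(1)
  km$surv[max(idx)]
}

#' Two-group log-rank test
#'
#' Standard log-rank: observed minus expected events summed over distinct
#' event times with the hypergeometric variance;
#' `chisq = (O - E)^2 / V` on one degree of freedom. Wraps
#' `survival::survdiff`.
#'
#' @param time_a,event_a times and event indicators of group A.
#' @param time_b,event_b same for group B.
#' @return list: `chisq`, `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0)
    stop("both groups must be nonempty")
  if (sum(event_a) + sum(event_b) == 0)
    stop("no events in either group; log-rank undefined")
  df <- data.frame(time = c(time_a, time_b),
                   event = c(event_a, event_b),
                   grp = rep(c("A", "B"), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  list(chisq = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Mean-split survival association of one gene
#'
#' Splits samples into high/low expression at the mean and compares their
#' survival by the log-rank test.
#'
#' @param expr named per-sample expression (linear scale).
#' @param time,event survival data aligned with `expr`.
#' @return list: `group` (factor), `chisq`, `p`, and the two [km_curve()]s
#'   (`km_high`, `km_low`).
#' @export
gene_survival <- function(expr, time, event) {
  g <- mean_split(expr)
  hi <- g == "high"
  lr <- logrank_test(time[hi], event[hi], time[!hi], event[!hi])
  list(group = g, chisq = lr$chisq, p = lr$p,
       km_high = km_curve(time[hi], event[hi]),
       km_low = km_curve(time[!hi], event[!hi]))
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; df = (r - 1)(c - 1). Requires all expected
#' counts positive (i.e. no zero marginals).
#'
#' @param table contingency matrix of counts.
#' @return list: `chisq`, `df`, `p`.
#' @export
chisq_clinical <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
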