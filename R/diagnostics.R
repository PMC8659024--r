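# Screening-test diagnostics: 2x2 confusion tables, point estimates and the
# CI methods that match the printed screening tables (exact Clopper-Pearson
# for proportions, Simel log method for likelihood ratios, Mercaldo logit
# method for predictive values), plus ELISA percent-change arithmetic.

# z = 1.96 exactly (not qnorm(0.975) = 1.959964) for the log/logit methods:
# reproduces published 2-dp bounds computed with the conventional 1.96.
.z_level <- function(level) {
  if (isTRUE(all.equal(level, 0.95))) 1.96 else stats::qnorm(1 - (1 - level) / 2)
}

#' Build a 2x2 confusion table
#'
#' @param tp,fp,tn,fn non-negative counts of true positives, false positives,
#'   true negatives and false negatives.
#' @return A `confusion_table` object with derived totals `n` (all), `n1`
#'   (diseased) and `n0` (non-diseased).
#' @examples
#' confusion_table(tp = 6, fp = 2, tn = 19, fn = 1)
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  x <- as.list(as.integer(counts))
  names(x) <- names(counts)
  x$n1 <- x$tp + x$fn
  x$n0 <- x$tn + x$fp
  x$n <- x$n1 + x$n0
  if (x$n < 1L) stop("confusion table is empty", call. = FALSE)
  structure(x, class = "confusion_table")
}

#' Confusion table from per-subject calls and outcomes
#'
#' @param calls logical vector of screening calls (TRUE = positive).
#' @param truth logical vector of disease outcomes, same length.
#' @return A [confusion_table()].
#' @export
confusion_from_calls <- function(calls, truth) {
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  stopifnot(length(calls) == length(truth), !anyNA(calls), !anyNA(truth))
  confusion_table(
    tp = sum(calls & truth), fp = sum(calls & !truth),
    tn = sum(!calls & !truth), fn = sum(!calls & truth)
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> TP =", x$tp, " FP =", x$fp,
      " TN =", x$tn, " FN =", x$fn, "\n")
  invisible(x)
}

#' Diagnostic point estimates from a 2x2 table
#'
#' Sensitivity, specificity, likelihood ratios, prevalence, predictive values
#' and accuracy. Proportions are on the 0-100 percent scale; likelihood
#' ratios are plain ratios. Statistics whose denominator is zero are `NA`
#' (e.g. the positive likelihood ratio when specificity is 100%), matching
#' the blank cells of conventional screening-report tables rather than
#' printing infinities.
#'
#' @param table a [confusion_table()].
#' @return A tibble with columns `statistic` and `estimate`.
#' @examples
#' point_estimates(confusion_table(tp = 6, fp = 2, tn = 19, fn = 1))
#' @export
point_estimates <- function(table) {
  t <- table
  stopifnot(inherits(t, "confusion_table"))
  sens <- if (t$n1 > 0) t$tp / t$n1 else NA_real_
  spec <- if (t$n0 > 0) t$tn / t$n0 else NA_real_
  plr <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  nlr <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  ppv <- if (t$tp + t$fp > 0) t$tp / (t$tp + t$fp) else NA_real_
  npv <- if (t$tn + t$fn > 0) t$tn / (t$tn + t$fn) else NA_real_
  tibble::tibble(
    statistic = c("sensitivity", "specificity", "plr", "nlr",
                  "prevalence", "ppv", "npv", "accuracy"),
    estimate = c(100 * sens, 100 * spec, plr, nlr,
                 100 * t$n1 / t$n, 100 * ppv, 100 * npv,
                 100 * (t$tp + t$tn) / t$n)
  )
}

#' Exact Clopper-Pearson confidence interval for a proportion
#'
#' Computed from beta quantiles; the lower bound is exactly 0 when `x = 0`
#' and the upper bound exactly 1 when `x = n`.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level.
#' @return Named numeric vector `c(low, high)` on the 0-1 proportion scale.
#' @examples
#' ci_proportion_cp(6, 7)
#' @export
ci_proportion_cp <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, x == round(x), n == round(n))
  a <- 1 - level
  low <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Log-method confidence interval for a likelihood ratio
#'
#' Simel's normal approximation on the log scale: CI = exp(ln LR +- z * SE)
#' with SE(ln PLR) = sqrt(1/TP - 1/n1 + 1/FP - 1/n0) and SE(ln NLR) =
#' sqrt(1/FN - 1/n1 + 1/TN - 1/n0). A zero cell in the SE makes the interval
#' undefined (`NA` bounds).
#'
#' @param table a [confusion_table()].
#' @param which `"plr"` or `"nlr"`.
#' @param level confidence level.
#' @return Named numeric vector `c(low, high)` (ratio scale), `NA` when
#'   undefined.
#' @examples
#' ci_lr(confusion_table(tp = 6, fp = 2, tn = 19, fn = 1), "plr")
#' @export
ci_lr <- function(table, which = c("plr", "nlr"), level = 0.95) {
  t <- table
  stopifnot(inherits(t, "confusion_table"))
  which <- match.arg(which)
  undefined <- c(low = NA_real_, high = NA_real_)
  if (t$n1 == 0 || t$n0 == 0) return(undefined)
  sens <- t$tp / t$n1
  spec <- t$tn / t$n0
  if (which == "plr") {
    if (t$fp == 0 || t$tp == 0) return(undefined)
    lr <- sens / (1 - spec)
    se <- sqrt(1 / t$tp - 1 / t$n1 + 1 / t$fp - 1 / t$n0)
  } else {
    if (t$fn == 0 || t$tn == 0 || spec == 0) return(undefined)
    lr <- (1 - sens) / spec
    se <- sqrt(1 / t$fn - 1 / t$n1 + 1 / t$tn - 1 / t$n0)
  }
  z <- .z_level(level)
  c(low = exp(log(lr) - z * se), high = exp(log(lr) + z * se))
}

#' Logit-method confidence interval for a predictive value
#'
#' Mercaldo's delta-method interval on the logit scale:
#' var(logit PPV) = (1-se)/(se*n1) + sp/((1-sp)*n0) and
#' var(logit NPV) = se/((1-se)*n1) + (1-sp)/(sp*n0), with se/sp the
#' sensitivity and specificity. A variance term whose rate is exactly 0 or 1
#' contributes nothing (its numerator vanishes) and is dropped. The interval
#' is undefined when the predictive value itself is exactly 0 or 1.
#'
#' @inheritParams ci_lr
#' @param which `"ppv"` or `"npv"`.
#' @return Named numeric vector `c(low, high)` on the 0-1 proportion scale,
#'   `NA` when undefined.
#' @examples
#' ci_pv(confusion_table(tp = 6, fp = 2, tn = 19, fn = 1), "ppv")
#' @export
ci_pv <- function(table, which = c("ppv", "npv"), level = 0.95) {
  t <- table
  stopifnot(inherits(t, "confusion_table"))
  which <- match.arg(which)
  undefined <- c(low = NA_real_, high = NA_real_)
  if (t$n1 == 0 || t$n0 == 0) return(undefined)
  sens <- t$tp / t$n1
  spec <- t$tn / t$n0
  pv <- if (which == "ppv") {
    if (t$tp + t$fp == 0) return(undefined)
    t$tp / (t$tp + t$fp)
  } else {
    if (t$tn + t$fn == 0) return(undefined)
    t$tn / (t$tn + t$fn)
  }
  if (pv <= 0 || pv >= 1) return(undefined)
  term <- function(num, denom) if (num == 0) 0 else num / denom
  v <- if (which == "ppv") {
    term(1 - sens, sens * t$n1) + term(spec, (1 - spec) * t$n0)
  } else {
    term(sens, (1 - sens) * t$n1) + term(1 - spec, spec * t$n0)
  }
  z <- .z_level(level)
  lg <- log(pv / (1 - pv)) + c(-1, 1) * z * sqrt(v)
  p <- exp(lg) / (1 + exp(lg))
  c(low = p[1], high = p[2])
}

#' Percent change between paired concentrations
#'
#' round(100 * (end - begin) / begin) to the nearest integer, half away from
#' zero. Undefined (`NA`) when the baseline is missing, undetectable or zero,
#' or the endpoint is missing.
#'
#' @param begin,end numeric vectors of paired concentrations; `NA` encodes
#'   undetectable/missing readings.
#' @return Integer percent-change vector with `NA` where undefined.
#' @examples
#' percent_change(c(1.166, 0.051), c(0.473, 1.402))
#' @export
percent_change <- function(begin, end) {
  stopifnot(length(begin) == length(end))
  out <- rep(NA_real_, length(begin))
  ok <- !is.na(begin) & !is.na(end) & begin > 0
  out[ok] <- round_half_away(100 * (end[ok] - begin[ok]) / begin[ok])
  as.integer(out)
}

#' Full diagnostic report for a screening test
#'
#' Builds the 2x2 table and every statistic with its designated CI method:
#' exact Clopper-Pearson for sensitivity, specificity, prevalence and
#' accuracy; Simel log method for likelihood ratios; Mercaldo logit method
#' for predictive values. Undefined statistics or intervals are `NA` (render
#' as blank cells).
#'
#' @param x either a [confusion_table()] or a logical vector of screening
#'   calls (with `truth` supplied).
#' @param truth logical vector of disease outcomes (when `x` is calls).
#' @param level confidence level.
#' @return A tibble with columns `statistic`, `estimate`, `ci_low`,
#'   `ci_high`, `ci_method`. Proportions (and their bounds) are on the 0-100
#'   percent scale; likelihood ratios on the ratio scale.
#' @examples
#' diagnostic_report(confusion_table(tp = 6, fp = 2, tn = 19, fn = 1))
#' @export
diagnostic_report <- function(x, truth = NULL, level = 0.95) {
  t <- if (inherits(x, "confusion_table")) x else confusion_from_calls(x, truth)
  est <- point_estimates(t)
  cp <- function(x, n) {
    if (n == 0) return(c(low = NA_real_, high = NA_real_))
    100 * ci_proportion_cp(x, n, level)
  }
  ci <- rbind(
    sensitivity = cp(t$tp, t$n1),
    specificity = cp(t$tn, t$n0),
    plr = ci_lr(t, "plr", level),
    nlr = ci_lr(t, "nlr", level),
    prevalence = cp(t$n1, t$n),
    ppv = 100 * ci_pv(t, "ppv", level),
    npv = 100 * ci_pv(t, "npv", level),
    accuracy = cp(t$tp + t$tn, t$n)
  )
  est$ci_low <- unname(ci[est$statistic, "low"])
  est$ci_high <- unname(ci[est$statistic, "high"])
  est$ci_low[is.na(est$estimate)] <- NA_real_
  est$ci_high[is.na(est$estimate)] <- NA_real_
  est$ci_method <- unname(c(
    sensitivity = "clopper_pearson", specificity = "clopper_pearson",
    plr = "simel_log", nlr = "simel_log", prevalence = "clopper_pearson",
    ppv = "mercaldo_logit", npv = "mercaldo_logit",
    accuracy = "clopper_pearson"
  )[est$statistic])
  est
}

#' Format a diagnostic report for display
#'
#' Rounds estimates and bounds to 2 dp (half away from zero), appends `%`
#' for proportion statistics and renders undefined cells blank.
#'
#' @param report tibble from [diagnostic_report()].
#' @return A tibble of character columns `Statistic`, `Value`, `95% CI`.
#' @export
format_diagnostic_report <- function(report) {
  pct <- report$ci_method != "simel_log"
  fmt <- function(v, is_pct) {
    ifelse(is.na(v), "",
           paste0(sprintf("%.2f", round_half_away(v, 2)),
                  ifelse(is_pct, "%", "")))
  }
  ci <- ifelse(
    is.na(report$ci_low), "",
    paste0("From ", sprintf("%.2f", round_half_away(report$ci_low, 2)),
           " to ", sprintf("%.2f", round_half_away(report$ci_high, 2)),
           ifelse(pct, "%", ""))
  )
  tibble::tibble(
    Statistic = report$statistic,
    Value = fmt(report$estimate, pct),
    `95% CI` = ci
  )
}
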