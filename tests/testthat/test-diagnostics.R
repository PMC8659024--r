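test_that("point estimates reproduce the published screening tables", {
  t36 <- week_confusion("week36")
  est <- point_estimates(t36)
  get <- function(s) est$estimate[est$statistic == s]
  expect_equal(round_half_away(get("plr"), 2), 9.00)
  expect_equal(round_half_away(get("ppv"), 2), 75.00)
  expect_equal(round_half_away(get("npv"), 2), 95.00)
  expect_equal(round_half_away(get("accuracy"), 2), 89.29)

  t24 <- week_confusion("week24")
  est24 <- point_estimates(t24)
  get24 <- function(s) est24$estimate[est24$statistic == s]
  expect_equal(round_half_away(get24("sensitivity"), 2), 85.71)
  expect_equal(get24("specificity"), 100)
  expect_equal(round_half_away(get24("nlr"), 2), 0.14)
  expect_true(is.na(get24("plr"))) # FP = 0: blank, not infinity

  degenerate <- confusion_table(tp = 0, fp = 3, tn = 7, fn = 0)
  est0 <- point_estimates(degenerate)
  expect_true(is.na(est0$estimate[est0$statistic == "sensitivity"]))
})

test_that("Clopper-Pearson intervals are exact and match binom.test", {
  expect_equal(round_half_away(100 * ci_proportion_cp(1, 7), 2),
               c(low = 0.36, high = 57.87))
  expect_equal(round_half_away(100 * ci_proportion_cp(21, 21), 2),
               c(low = 83.89, high = 100.00))
  expect_identical(ci_proportion_cp(0, 5)[["low"]], 0)
  expect_identical(ci_proportion_cp(5, 5)[["high"]], 1)
  expect_error(ci_proportion_cp(8, 5))

  # independent cross-check against stats::binom.test
  withr::with_seed(5, {
    for (rep in 1:25) {
      n <- sample(1:60, 1)
      x <- sample(0:n, 1)
      expect_equal(
        unname(ci_proportion_cp(x, n)),
        as.numeric(binom.test(x, n)$conf.int),
        tolerance = 1e-10
      )
    }
  })

  # interval contains x/n; width shrinks as n grows at fixed x/n
  widths <- vapply(c(1, 2, 4, 8, 16), function(k) {
    ci <- ci_proportion_cp(2 * k, 8 * k)
    expect_true(ci["low"] <= 0.25 && 0.25 <= ci["high"])
    unname(diff(ci))
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("log-method likelihood-ratio intervals match printed bounds", {
  expect_equal(round_half_away(ci_lr(week_confusion("week36"), "plr"), 2),
               c(low = 2.33, high = 34.80))
  expect_equal(round_half_away(ci_lr(week_confusion("week36"), "nlr"), 2),
               c(low = 0.03, high = 0.97))
  expect_equal(round_half_away(ci_lr(week_confusion("week24"), "nlr"), 2),
               c(low = 0.02, high = 0.88))
  expect_equal(round_half_away(ci_lr(week_confusion("week11"), "nlr"), 2),
               c(low = 0.63, high = 1.16))
  # zero cells: undefined, not infinite
  expect_true(all(is.na(ci_lr(week_confusion("week24"), "plr"))))
  perfect <- confusion_table(tp = 7, fp = 0, tn = 21, fn = 0)
  expect_true(all(is.na(ci_lr(perfect, "nlr"))))
})

test_that("logit-method predictive-value intervals match printed bounds", {
  t36 <- week_confusion("week36")
  expect_equal(round_half_away(100 * ci_pv(t36, "ppv"), 2),
               c(low = 43.69, high = 92.06))
  expect_equal(round_half_away(100 * ci_pv(t36, "npv"), 2),
               c(low = 75.48, high = 99.15))
  # specificity = 1 drops its variance term rather than dividing by zero
  expect_equal(round_half_away(100 * ci_pv(week_confusion("week24"), "npv"), 2),
               c(low = 77.38, high = 99.23))
  expect_equal(round_half_away(100 * ci_pv(week_confusion("week11"), "npv"), 2),
               c(low = 72.12, high = 82.57))
  # PPV exactly 100%: interval undefined (blank cell)
  expect_true(all(is.na(ci_pv(week_confusion("week24"), "ppv"))))
})

test_that("percent change reproduces the paired-ELISA arithmetic", {
  expect_equal(percent_change(1.166, 0.473), -59L)
  expect_equal(percent_change(0.051, 1.402), 2649L)
  expect_true(is.na(percent_change(NA, 0.659))) # undetectable baseline
  expect_true(is.na(percent_change(0.253, NA))) # missing endpoint
  expect_true(is.na(percent_change(0, 1)))
  expect_equal(percent_change(c(1.166, NA), c(0.473, 1)), c(-59L, NA))
})

test_that("diagnostic_report assembles statistics with their CI methods", {
  cw <- calls_from_counts(tp = 1, fp = 0, tn = 21, fn = 6)
  rep11 <- diagnostic_report(cw$calls, cw$truth)
  get <- function(s, col) rep11[[col]][rep11$statistic == s]
  expect_equal(round_half_away(get("sensitivity", "estimate"), 2), 14.29)
  expect_equal(round_half_away(get("npv", "estimate"), 2), 77.78)
  expect_equal(round_half_away(get("accuracy", "estimate"), 2), 78.57)
  expect_equal(get("sensitivity", "ci_method"), "clopper_pearson")
  expect_equal(get("nlr", "ci_method"), "simel_log")
  expect_equal(get("npv", "ci_method"), "mercaldo_logit")

  all_right <- diagnostic_report(rep(c(TRUE, FALSE), c(7, 21)),
                                 rep(c(TRUE, FALSE), c(7, 21)))
  for (s in c("sensitivity", "specificity", "accuracy")) {
    expect_equal(all_right$estimate[all_right$statistic == s], 100)
  }

  fmt <- format_diagnostic_report(diagnostic_report(week_confusion("week24")))
  expect_equal(fmt$Value[fmt$Statistic == "accuracy"], "96.43%")
  expect_equal(fmt$`95% CI`[fmt$Statistic == "accuracy"],
               "From 81.65 to 99.91%")
  expect_equal(fmt$Value[fmt$Statistic == "plr"], "") # blank cell
  expect_equal(fmt$`95% CI`[fmt$Statistic == "ppv"], "")
})

test_that("accuracy equals prevalence-weighted sensitivity/specificity", {
  withr::with_seed(13, {
    for (rep in 1:50) {
      t <- confusion_table(tp = sample(1:20, 1), fp = sample(1:20, 1),
                           tn = sample(1:20, 1), fn = sample(1:20, 1))
      est <- point_estimates(t)
      get <- function(s) est$estimate[est$statistic == s] / 100
      expect_equal(get("accuracy"),
                   get("prevalence") * get("sensitivity") +
                     (1 - get("prevalence")) * get("specificity"),
                   tolerance = 1e-12)
    }
  })
})
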