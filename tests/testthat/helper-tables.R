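# Published screening-study inputs used as fixtures: the per-week 2x2
# screening counts (weeks 11/24/36 of pregnancy, n = 28, 7 preeclampsia
# cases) with the published statistics, and the paired ELISA podocin
# concentrations with their printed percent-change column ("undetectable"
# and missing readings encoded as NA).

week_tables <- list(
  week11 = list(
    counts = c(tp = 1, fp = 0, tn = 21, fn = 6),
    expected = tibble::tribble(
      ~statistic, ~estimate, ~ci_low, ~ci_high,
      "sensitivity", 14.29, 0.36, 57.87,
      "specificity", 100.00, 83.89, 100.00,
      "plr", NA, NA, NA,
      "nlr", 0.86, 0.63, 1.16,
      "prevalence", 25.00, 10.69, 44.87,
      "ppv", 100.00, NA, NA,
      "npv", 77.78, 72.12, 82.57,
      "accuracy", 78.57, 59.05, 91.70
    )
  ),
  week24 = list(
    counts = c(tp = 6, fp = 0, tn = 21, fn = 1),
    expected = tibble::tribble(
      ~statistic, ~estimate, ~ci_low, ~ci_high,
      "sensitivity", 85.71, 42.13, 99.64,
      "specificity", 100.00, 83.89, 100.00,
      "plr", NA, NA, NA,
      "nlr", 0.14, 0.02, 0.88,
      "prevalence", 25.00, 10.69, 44.87,
      "ppv", 100.00, NA, NA,
      "npv", 95.45, 77.38, 99.23,
      "accuracy", 96.43, 81.65, 99.91
    )
  ),
  week36 = list(
    counts = c(tp = 6, fp = 2, tn = 19, fn = 1),
    expected = tibble::tribble(
      ~statistic, ~estimate, ~ci_low, ~ci_high,
      "sensitivity", 85.71, 42.13, 99.64,
      "specificity", 90.48, 69.62, 98.83,
      "plr", 9.00, 2.33, 34.80,
      "nlr", 0.16, 0.03, 0.97,
      "prevalence", 25.00, 10.69, 44.87,
      "ppv", 75.00, 43.69, 92.06,
      "npv", 95.00, 75.48, 99.15,
      "accuracy", 89.29, 71.77, 97.73
    )
  )
)

week_confusion <- function(week) {
  cts <- week_tables[[week]]$counts
  mrmtag::confusion_table(tp = cts["tp"], fp = cts["fp"],
                          tn = cts["tn"], fn = cts["fn"])
}

elisa_table <- tibble::tribble(
  ~patient, ~begin, ~end, ~printed_change,
  1, 1.166, 0.473, -59,
  2, 0.321, 0.878, 174,
  3, 2.128, 1.588, -25,
  4, 0.625, 0.693, 11,
  5, 0.490, 0.895, 83,
  6, 1.318, 0.997, -24,
  7, NA, 0.659, NA,
  8, 1.301, 0.439, -66,
  9, 0.051, 1.402, 2649,
  10, 0.591, 0.659, 12,
  11, NA, 0.608, NA,
  12, 0.895, 0.321, -64,
  13, NA, 0.017, NA,
  14, 0.253, NA, NA,
  15, NA, 0.321, NA,
  16, 0.287, 1.334, 365,
  17, 0.051, 0.321, 529,
  18, NA, 0.152, NA,
  19, NA, NA, NA,
  20, 0.270, 0.101, -63,
  21, 0.338, 6.976, 1964,
  22, 0.321, NA, NA,
  23, 1.081, 0.220, -80,
  24, 0.659, 0.811, 23,
  25, 0.726, 0.405, -44,
  26, 0.186, 0.118, -37,
  27, NA, NA, NA,
  28, 1.284, NA, NA
)

# The six published MRM transitions for the podocin marker peptide
# MIAAEAEK (native, Met-oxidized and TPP-derivatized forms), as reported by
# the instrument after automatic optimization.
observed_transitions <- tibble::tribble(
  ~precursor_mz, ~product_mz, ~printed_label,
  862.45, 347.20, "y3",
  862.45, 618.30, "y6",
  862.45, 547.28, "y5",
  878.43, 261.13, "b2",
  576.78, 637.30, "y3",
  576.78, 308.20, "reporter"
)

# Helper: calls/truth vectors realizing a 2x2 table.
calls_from_counts <- function(tp, fp, tn, fn) {
  list(
    calls = c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn)),
    truth = c(rep(TRUE, tp + fn), rep(FALSE, fp + tn))
  )
}
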