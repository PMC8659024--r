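# Synthetic MRM chromatograms: Gaussian peak on a noisy baseline, S/N-based
# detection, limit-of-detection estimation and linear calibration.

#' Simulation parameters for a synthetic MRM trace
#'
#' The model is a single Gaussian elution peak on a constant baseline with
#' additive white noise: intensity(t) = baseline +
#' amount * response_factor * dnorm(t; rt, peak_sigma) + N(0, noise_sd).
#' `response_factor` is the tag-dependent response (intensity-seconds per
#' mol): a fixed-charge tag raises it by orders of magnitude, which is the
#' mechanism behind the femtomole-to-attomole detection-limit gain.
#'
#' @param amount analyte amount on column (mol).
#' @param response_factor intensity response per mol.
#' @param rt peak retention time (s).
#' @param peak_sigma Gaussian peak width sigma (s).
#' @param noise_sd baseline noise standard deviation (intensity units).
#' @param baseline constant baseline level (intensity units, >= 0).
#' @param duration trace length (s).
#' @param sample_interval sampling interval (s), must be < `peak_sigma`.
#' @param seed integer RNG seed; every trace is reproducible from it.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(amount, response_factor, rt = 30, peak_sigma = 2,
                       noise_sd = 1, baseline = 10, duration = 60,
                       sample_interval = 0.25, seed = 1L) {
  stopifnot(
    amount >= 0, response_factor > 0, rt > 0, peak_sigma > 0, noise_sd >= 0,
    baseline >= 0, duration > 0, sample_interval > 0,
    sample_interval < peak_sigma
  )
  structure(
    list(
      amount = amount, response_factor = response_factor, rt = rt,
      peak_sigma = peak_sigma, noise_sd = noise_sd, baseline = baseline,
      duration = duration, sample_interval = sample_interval,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Simulate an MRM chromatogram
#'
#' @param params a [sim_params()] object.
#' @return A tibble with columns `time` (s, strictly increasing) and
#'   `intensity`, carrying the generating parameters as attribute `params`.
#' @examples
#' trace <- simulate_trace(sim_params(amount = 1e-15, response_factor = 1e16))
#' @export
simulate_trace <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  times <- seq(0, params$duration, by = params$sample_interval)
  signal <- params$baseline + params$amount * params$response_factor *
    stats::dnorm(times, mean = params$rt, sd = params$peak_sigma)
  noise <- if (params$noise_sd > 0) {
    withr::with_seed(params$seed, stats::rnorm(length(times), 0, params$noise_sd))
  } else {
    numeric(length(times))
  }
  out <- tibble::tibble(time = times, intensity = signal + noise)
  attr(out, "params") <- params
  out
}

.split_window <- function(trace, peak_window) {
  stopifnot(is.numeric(peak_window), length(peak_window) == 2L,
            peak_window[1] < peak_window[2])
  inside <- trace$time >= peak_window[1] & trace$time <= peak_window[2]
  if (!any(inside)) stop("empty peak window", call. = FALSE)
  if (sum(!inside) < 20L) {
    stop("need at least 20 points outside the peak window", call. = FALSE)
  }
  list(inside = trace$intensity[inside], outside = trace$intensity[!inside])
}

#' Estimate signal-to-noise ratio of a chromatographic peak
#'
#' S/N = (apex - baseline) / noise. The apex is the maximum of a boxcar-
#' smoothed trace inside the peak window (chromatographic S/N is
#' conventionally read off a lightly smoothed signal, otherwise the
#' max-statistic of the raw noise inflates the apex); the baseline is the
#' median and the noise 1.4826 x MAD of the raw out-of-window points (robust
#' to the peak tail leaking past the window edge).
#'
#' @param trace chromatogram tibble from [simulate_trace()] (or any tibble
#'   with `time` and `intensity`).
#' @param peak_window numeric length-2 vector, time interval containing the
#'   peak; at least 20 points must lie outside it.
#' @param smooth odd boxcar width in points for the apex estimate (default 5,
#'   about one quarter peak sigma at the default sampling; 1 disables
#'   smoothing).
#' @return The S/N ratio (scalar).
#' @export
estimate_snr <- function(trace, peak_window, smooth = 5L) {
  stopifnot(smooth >= 1L)
  parts <- .split_window(trace, peak_window)
  noise <- stats::mad(parts$outside) # constant = 1.4826 by default
  if (noise == 0) stop("noise indeterminate: zero MAD outside peak window",
                       call. = FALSE)
  smoothed <- if (smooth > 1L) {
    as.numeric(stats::filter(trace$intensity, rep(1 / smooth, smooth),
                             sides = 2))
  } else {
    trace$intensity
  }
  inside <- trace$time >= peak_window[1] & trace$time <= peak_window[2]
  apex <- max(smoothed[inside], na.rm = TRUE)
  (apex - stats::median(parts$outside)) / noise
}

#' S/N-threshold peak detection
#'
#' A peak is called detected when the estimated S/N reaches the threshold;
#' the conventional detection-limit criterion is S/N >= 3.
#'
#' @inheritParams estimate_snr
#' @param threshold minimum S/N (default 3).
#' @return Logical scalar.
#' @export
detect_peak <- function(trace, peak_window, threshold = 3.0, smooth = 5L) {
  estimate_snr(trace, peak_window, smooth = smooth) >= threshold
}

#' Limit of detection from a dilution series
#'
#' Simulates `replicates` traces at each amount (descending) and calls the
#' LOD as the smallest amount in the contiguous run, starting from the
#' largest amount, in which every replicate is detected. Scanning stops at
#' the first amount with any failed replicate, so an isolated lucky
#' detection further down the series cannot lower the LOD.
#'
#' @param amounts numeric vector of amounts (mol); sorted descending
#'   internally.
#' @param params_template a [sim_params()] object; its `amount` and `seed`
#'   are overridden per simulation.
#' @param replicates replicate traces per amount.
#' @param seed master seed; per-trace seeds are derived from it.
#' @param peak_window time window for detection; defaults to rt +- 2 sigma.
#' @param threshold S/N detection threshold.
#' @return A list of class `mrm_lod` with `lod` (the amount, or `NA` when
#'   nothing is detected) and `results`, a tibble with one row per amount
#'   (`amount`, `n_detected`, `all_detected`).
#' @export
lod_from_series <- function(amounts, params_template, replicates = 3L,
                            seed = 1L, peak_window = NULL, threshold = 3.0) {
  stopifnot(inherits(params_template, "sim_params"), replicates >= 1L,
            length(amounts) >= 1L)
  amounts <- sort(amounts, decreasing = TRUE)
  if (is.null(peak_window)) {
    peak_window <- params_template$rt +
      c(-2, 2) * params_template$peak_sigma
  }
  seeds <- withr::with_seed(
    as.integer(seed),
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(amounts) * replicates),
           nrow = length(amounts))
  )
  n_detected <- integer(length(amounts))
  stopped <- FALSE
  for (i in seq_along(amounts)) {
    p <- params_template
    p$amount <- amounts[i]
    det <- vapply(seq_len(replicates), function(j) {
      p$seed <- seeds[i, j]
      detect_peak(simulate_trace(p), peak_window, threshold)
    }, NA)
    n_detected[i] <- sum(det)
    if (!all(det) && !stopped) {
      stopped <- TRUE
      stop_at <- i
    }
  }
  all_det <- n_detected == replicates
  run_end <- if (stopped) stop_at - 1L else length(amounts)
  lod <- if (run_end >= 1L) amounts[run_end] else NA_real_
  structure(
    list(
      lod = lod,
      results = tibble::tibble(amount = amounts, n_detected = n_detected,
                               all_detected = all_det)
    ),
    class = "mrm_lod"
  )
}

#' @export
print.mrm_lod <- function(x, ...) {
  cat("<mrm_lod> LOD:",
      if (is.na(x$lod)) "none detected" else format(x$lod, digits = 4), "\n")
  print(x$results)
  invisible(x)
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of apex intensity on amount; the amount-to-signal
#' response of the assay is linear over the working range, so slope,
#' intercept and R-squared summarize the calibration.
#'
#' @param points tibble (or data frame) with columns `amount` and
#'   `intensity`; at least two distinct amounts are required.
#' @return An `mrm_calibration` object with elements `slope`, `intercept`,
#'   `r_squared`, `fit` (the underlying `lm`) and `data`; supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' fit_calibration(data.frame(amount = 1:5, intensity = 2 * (1:5) + 1))
#' @export
fit_calibration <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("amount", "intensity") %in% names(points)))
  if (length(unique(points$amount)) < 2L) {
    stop("calibration requires at least two distinct amounts", call. = FALSE)
  }
  fit <- stats::lm(intensity ~ amount, data = points)
  # summary() warns on an exactly collinear (noise-free) calibration line
  smry <- suppressWarnings(summary(fit))
  structure(
    list(
      slope = unname(stats::coef(fit)[["amount"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = smry$r.squared,
      fit = fit,
      data = points
    ),
    class = "mrm_calibration"
  )
}

#' @export
print.mrm_calibration <- function(x, ...) {
  cat("<mrm_calibration>\n",
      "  slope:     ", format(x$slope, digits = 6), "\n",
      "  intercept: ", format(x$intercept, digits = 6), "\n",
      "  R-squared: ", format(x$r_squared, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x an `mrm_calibration` object.
#' @param ... unused.
#' @return One row per model term with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.mrm_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' Glance at a calibration fit
#'
#' @inheritParams tidy.mrm_calibration
#' @return One-row tibble with `r.squared`, `sigma`, `n`.
#' @export
glance.mrm_calibration <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$fit))$sigma,
    n = nrow(x$data)
  )
}
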