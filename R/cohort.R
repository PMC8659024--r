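# Seeded synthetic screening cohort: disease status, per-timepoint LC-MS
# screening calls with configurable sensitivity/specificity, and paired
# ELISA concentrations, so the diagnostics pipeline is testable end-to-end
# without any study data.

#' Default per-timepoint screening performance
#'
#' Three screening timepoints (gestational weeks 11, 24 and 36) with the
#' detection sensitivity/specificity a urine-sediment MRM screen achieves at
#' each: low early-pregnancy sensitivity with perfect specificity, high
#' late-pregnancy sensitivity with near-perfect specificity.
#'
#' @return A tibble with columns `week`, `sensitivity`, `specificity`.
#' @export
default_timepoints <- function() {
  tibble::tibble(
    week = c(11, 24, 36),
    sensitivity = c(1 / 7, 6 / 7, 6 / 7),
    specificity = c(1, 1, 19 / 21)
  )
}

#' Generate a synthetic screening cohort
#'
#' Disease status is Bernoulli(`prevalence`); at each timepoint the screening
#' call is Bernoulli(sensitivity) for diseased subjects and
#' Bernoulli(1 - specificity) for non-diseased. Paired ELISA concentrations
#' (begin/end of pregnancy) are log-normal with group-specific parameters;
#' readings below `undetectable_floor` become `NA` (undetectable). The whole
#' cohort is reproducible from `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param prevalence disease prevalence, strictly between 0 and 1.
#' @param timepoints tibble with `week`, `sensitivity`, `specificity`
#'   (default [default_timepoints()]).
#' @param elisa_meanlog,elisa_sdlog named numeric vectors with elements
#'   `control` and `disease`: log-normal parameters of the ELISA
#'   concentrations (concentration units as reported by the assay).
#' @param undetectable_floor concentrations below this are reported
#'   undetectable (`NA`).
#' @param seed integer RNG seed.
#' @return A tibble in the cohort schema: `subject_id`, `timepoint_week`,
#'   `pe_outcome`, `lcms_call`, `elisa_begin`, `elisa_end` (one row per
#'   subject x timepoint; ELISA columns repeat within subject).
#' @examples
#' generate_cohort(n_subjects = 28, prevalence = 0.25, seed = 7)
#' @export
generate_cohort <- function(n_subjects = 28L, prevalence = 0.25,
                            timepoints = default_timepoints(),
                            elisa_meanlog = c(control = -0.7, disease = -0.2),
                            elisa_sdlog = c(control = 1.0, disease = 1.0),
                            undetectable_floor = 0.05, seed = 1L) {
  stopifnot(
    n_subjects >= 2L, prevalence > 0, prevalence < 1,
    all(c("week", "sensitivity", "specificity") %in% names(timepoints)),
    all(timepoints$sensitivity >= 0 & timepoints$sensitivity <= 1),
    all(timepoints$specificity >= 0 & timepoints$specificity <= 1),
    undetectable_floor >= 0,
    all(c("control", "disease") %in% names(elisa_meanlog)),
    all(c("control", "disease") %in% names(elisa_sdlog))
  )
  withr::with_seed(as.integer(seed), {
    diseased <- stats::rbinom(n_subjects, 1L, prevalence) == 1L
    grp <- ifelse(diseased, "disease", "control")
    begin <- stats::rlnorm(n_subjects, elisa_meanlog[grp], elisa_sdlog[grp])
    end <- stats::rlnorm(n_subjects, elisa_meanlog[grp], elisa_sdlog[grp])
    begin[begin < undetectable_floor] <- NA_real_
    end[end < undetectable_floor] <- NA_real_
    rows <- purrr::map(seq_len(nrow(timepoints)), function(i) {
      p_call <- ifelse(diseased, timepoints$sensitivity[i],
                       1 - timepoints$specificity[i])
      tibble::tibble(
        subject_id = seq_len(n_subjects),
        timepoint_week = timepoints$week[i],
        pe_outcome = as.integer(diseased),
        lcms_call = stats::rbinom(n_subjects, 1L, p_call),
        elisa_begin = begin,
        elisa_end = end
      )
    })
    dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id,
                   .data$timepoint_week)
  })
}

#' Write / read a cohort CSV
#'
#' Schema `subject_id,timepoint_week,pe_outcome,lcms_call,elisa_begin,
#' elisa_end`; undetectable/missing ELISA readings are written as the token
#' `undetectable` and read back as `NA`.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- dplyr::mutate(
    cohort,
    dplyr::across(
      dplyr::all_of(c("elisa_begin", "elisa_end")),
      ~ifelse(is.na(.x), "undetectable", format(.x, digits = 6, trim = TRUE))
    )
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_integer(),
      timepoint_week = readr::col_double(),
      pe_outcome = readr::col_integer(),
      lcms_call = readr::col_integer(),
      elisa_begin = readr::col_character(),
      elisa_end = readr::col_character()
    )
  )
  parse_conc <- function(v) {
    v[tolower(v) %in% c("undetectable", "na", "-", "")] <- NA_character_
    as.numeric(v)
  }
  dplyr::mutate(
    x,
    elisa_begin = parse_conc(.data$elisa_begin),
    elisa_end = parse_conc(.data$elisa_end)
  )
}

#' Evaluate screening performance at one timepoint
#'
#' Filters the cohort to one gestational week and runs
#' [diagnostic_report()] on its calls against outcomes.
#'
#' @param cohort cohort tibble (schema of [generate_cohort()]).
#' @param week the timepoint to evaluate.
#' @param level confidence level.
#' @return The diagnostic-report tibble.
#' @export
evaluate_cohort <- function(cohort, week, level = 0.95) {
  sub <- dplyr::filter(cohort, .data$timepoint_week == week)
  if (nrow(sub) == 0) stop("no records at week ", week, call. = FALSE)
  diagnostic_report(sub$lcms_call == 1L, sub$pe_outcome == 1L, level = level)
}

#' ELISA percent change per subject
#'
#' One row per subject with the begin/end concentrations and the integer
#' percent change ([percent_change()]); `NA` where undefined.
#'
#' @param cohort cohort tibble with `subject_id`, `elisa_begin`, `elisa_end`.
#' @return A tibble `subject_id`, `elisa_begin`, `elisa_end`, `pct_change`.
#' @export
elisa_changes <- function(cohort) {
  per_subject <- dplyr::distinct(
    tibble::as_tibble(cohort),
    .data$subject_id, .data$elisa_begin, .data$elisa_end
  )
  dplyr::mutate(
    per_subject,
    pct_change = percent_change(.data$elisa_begin, .data$elisa_end)
  )
}
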