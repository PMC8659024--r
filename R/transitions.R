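# MRM transition list construction, CSV round-trip and annotation of
# observed (instrument-optimized) transitions against theory.

#' Build a modified peptide variant
#'
#' Variants name the modification states monitored in an MRM method:
#' `"native"` (none), `"ox"` (oxidation on every methionine), `"cam"`
#' (carbamidomethyl on every cysteine), `"tpp"` (fixed-charge TPP tag on the
#' C-terminal lysine). Combinations are joined with `+`, e.g. `"tpp+ox"`.
#'
#' @param sequence peptide sequence string.
#' @param variant variant label.
#' @return A [peptide()] object.
#' @examples
#' peptide_variant("MIAAEAEK", "tpp")
#' @export
peptide_variant <- function(sequence, variant = "native") {
  residues <- .check_sequence(sequence)
  parts <- setdiff(strsplit(variant, "+", fixed = TRUE)[[1]], "native")
  mods <- list()
  for (part in parts) {
    if (part == "ox") {
      pos <- which(residues == "M")
      if (length(pos) == 0) {
        stop("variant 'ox' requested but '", sequence,
             "' contains no methionine", call. = FALSE)
      }
      mod <- "oxidation"
    } else if (part == "cam") {
      pos <- which(residues == "C")
      if (length(pos) == 0) {
        stop("variant 'cam' requested but '", sequence,
             "' contains no cysteine", call. = FALSE)
      }
      mod <- "carbamidomethyl"
    } else if (part == "tpp") {
      if (residues[length(residues)] != "K") {
        stop("variant 'tpp' requires a C-terminal lysine; '", sequence,
             "' ends in '", residues[length(residues)], "'", call. = FALSE)
      }
      pos <- length(residues)
      mod <- "tpp"
    } else {
      stop("unknown variant component '", part, "'", call. = FALSE)
    }
    for (p in pos) mods[[length(mods) + 1L]] <- list(position = p, mod = mod)
  }
  mod_df <- if (length(mods) > 0) {
    data.frame(
      position = vapply(mods, `[[`, 0L, "position"),
      mod = vapply(mods, `[[`, "", "mod")
    )
  } else NULL
  peptide(sequence, mods = mod_df)
}

#' Build an MRM transition list
#'
#' Enumerates b/y fragment ions for each requested variant and precursor
#' charge, keeps the `top_n` longest fragments per series (longer fragments
#' are usually the more selective MRM products), and — for fixed-charge-tagged
#' variants — appends the tag's reporter transition. Product ions are singly
#' charged.
#'
#' @param sequence peptide sequence string.
#' @param variants character vector of variant labels (see
#'   [peptide_variant()]).
#' @param precursor_charges integer vector of precursor charge states.
#' @param series fragment series to enumerate, subset of `c("b", "y")`.
#' @param top_n fragments kept per series (by descending fragment length).
#' @return A tibble with columns `peptide`, `variant`, `precursor_mz`,
#'   `precursor_charge`, `product_mz`, `product_charge`, `ion_label`, ordered
#'   by variant, charge, series and descending fragment index, with no
#'   duplicate (precursor_mz, product_mz, ion_label) triples.
#' @examples
#' build_transitions("MIAAEAEK", variants = "tpp", precursor_charges = 2)
#' @export
build_transitions <- function(sequence, variants = "native",
                              precursor_charges = 1L,
                              series = c("b", "y"), top_n = 3L) {
  stopifnot(top_n >= 1L)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  n <- nchar(sequence)
  rows <- purrr::map(variants, function(v) {
    pep <- peptide_variant(sequence, v)
    reporter_tags <- unique(vapply(
      Filter(function(m) m$mod$fixed_charge > 0 && !is.null(m$mod$reporter),
             pep$mods),
      function(m) m$mod$name, ""
    ))
    purrr::map(sort(as.integer(precursor_charges)), function(z) {
      prec <- precursor_mz(pep, z)
      frag <- purrr::map(series, function(s) {
        idx <- sort(seq_len(n - 1L), decreasing = TRUE)
        idx <- utils::head(idx, top_n)
        tibble::tibble(
          peptide = sequence, variant = v,
          precursor_mz = prec, precursor_charge = z,
          product_mz = vapply(idx, function(i) fragment_mz(pep, s, i, 1L), 0),
          product_charge = 1L,
          ion_label = paste0(s, idx)
        )
      })
      rep <- purrr::map(reporter_tags, function(tag) {
        tibble::tibble(
          peptide = sequence, variant = v,
          precursor_mz = prec, precursor_charge = z,
          product_mz = reporter_mz(tag), product_charge = 1L,
          ion_label = "reporter"
        )
      })
      dplyr::bind_rows(c(frag, rep))
    })
  })
  out <- dplyr::bind_rows(rows)
  dplyr::distinct(out, .data$precursor_mz, .data$product_mz, .data$ion_label,
                  .keep_all = TRUE)
}

#' Annotate observed transitions against theory
#'
#' Matches each observed (e.g. instrument-optimized) transition to the nearest
#' theoretical ion of any supported variant within `tolerance` on both the
#' precursor and the product m/z. Ties are broken by smallest total absolute
#' difference, then lower fragment index. Instrument-reported values on
#' unit-resolution triple quadrupoles commonly deviate a few hundredths of an
#' m/z from theory, hence the generous default tolerance.
#'
#' @param observed tibble with columns `precursor_mz` and `product_mz`
#'   (extra columns are carried through).
#' @param sequence peptide sequence string the observations belong to.
#' @param tolerance_mz match tolerance in m/z, applied to precursor and
#'   product independently (default 0.1).
#' @param variants variant labels to consider; defaults to every applicable
#'   combination of native, ox, cam and tpp for the sequence.
#' @param precursor_charges precursor charge states considered.
#' @return The observed tibble with columns `matched`, `variant`, `ion_label`,
#'   `theoretical_precursor_mz`, `theoretical_product_mz`, `precursor_delta`,
#'   `product_delta` appended (NA where unmatched).
#' @export
annotate_observed <- function(observed, sequence, tolerance_mz = 0.1,
                              variants = NULL, precursor_charges = 1:3) {
  stopifnot(tolerance_mz >= 0)
  observed <- tibble::as_tibble(observed)
  stopifnot(all(c("precursor_mz", "product_mz") %in% names(observed)))
  if (is.null(variants)) variants <- applicable_variants(sequence)
  theory <- build_transitions(
    sequence, variants = variants, precursor_charges = precursor_charges,
    series = c("b", "y"), top_n = nchar(sequence)
  )
  theory$ion_index <- suppressWarnings(
    as.integer(sub("^[by]", "", theory$ion_label))
  )
  ann <- purrr::map(seq_len(nrow(observed)), function(i) {
    dp <- abs(theory$precursor_mz - observed$precursor_mz[i])
    df <- abs(theory$product_mz - observed$product_mz[i])
    ok <- which(dp <= tolerance_mz & df <= tolerance_mz)
    if (length(ok) == 0) {
      return(tibble::tibble(
        matched = FALSE, variant = NA_character_, ion_label = NA_character_,
        theoretical_precursor_mz = NA_real_, theoretical_product_mz = NA_real_,
        precursor_delta = NA_real_, product_delta = NA_real_
      ))
    }
    ord <- order(dp[ok] + df[ok], theory$ion_index[ok], na.last = TRUE)
    j <- ok[ord[1]]
    tibble::tibble(
      matched = TRUE, variant = theory$variant[j],
      ion_label = theory$ion_label[j],
      theoretical_precursor_mz = theory$precursor_mz[j],
      theoretical_product_mz = theory$product_mz[j],
      precursor_delta = observed$precursor_mz[i] - theory$precursor_mz[j],
      product_delta = observed$product_mz[i] - theory$product_mz[j]
    )
  })
  dplyr::bind_cols(observed, dplyr::bind_rows(ann))
}

#' Variant labels applicable to a sequence
#'
#' All combinations of ox (needs Met), cam (needs Cys) and tpp (needs
#' C-terminal Lys) that the sequence supports, plus `"native"`.
#'
#' @param sequence peptide sequence string.
#' @return Character vector of variant labels.
#' @export
applicable_variants <- function(sequence) {
  residues <- .check_sequence(sequence)
  singles <- character(0)
  if (any(residues == "M")) singles <- c(singles, "ox")
  if (any(residues == "C")) singles <- c(singles, "cam")
  if (residues[length(residues)] == "K") singles <- c(singles, "tpp")
  combos <- unlist(lapply(seq_along(singles), function(k) {
    apply(utils::combn(singles, k), 2, paste, collapse = "+")
  }))
  c("native", combos)
}

#' Write / read a transition list CSV
#'
#' Fixed dialect for bit-exact round-trips: header
#' `peptide,variant,precursor_mz,precursor_charge,product_mz,ion_label`,
#' UTF-8, `.` decimal separator, m/z printed to 4 dp.
#'
#' @param transitions tibble from [build_transitions()].
#' @param path output path.
#' @return `write_transitions()` returns `path` invisibly;
#'   `read_transitions()` returns the transition tibble.
#' @export
write_transitions <- function(transitions, path) {
  out <- tibble::tibble(
    peptide = transitions$peptide,
    variant = transitions$variant,
    precursor_mz = sprintf("%.4f", transitions$precursor_mz),
    precursor_charge = transitions$precursor_charge,
    product_mz = sprintf("%.4f", transitions$product_mz),
    ion_label = transitions$ion_label
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      peptide = readr::col_character(),
      variant = readr::col_character(),
      precursor_mz = readr::col_double(),
      precursor_charge = readr::col_integer(),
      product_mz = readr::col_double(),
      ion_label = readr::col_character()
    )
  )
}
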