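# Monoisotopic mass arithmetic for peptides with site-localized modifications,
# including fixed-charge tags. All masses in Da, all m/z in Thomson.

# Monoisotopic element masses (Da). Electron mass is neglected for cations:
# the resulting error (~5.5e-4 Da) is far below the +-0.1 m/z matching
# tolerance used throughout.
.ELEMENT_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.PROTON_MASS <- 1.007276

# Elemental compositions of the 20 standard amino-acid residues (as residues,
# i.e. minus one water relative to the free amino acid).
.RESIDUE_COMP <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.WATER_COMP <- c(H = 2, O = 1)

#' Add elemental compositions
#'
#' Compositions are named integer vectors mapping element symbols to signed
#' counts. Addition is element-wise; deltas (modification differences) may be
#' signed, physical species must end up non-negative.
#'
#' @param ... named numeric vectors (element -> count).
#' @return A single named numeric vector with zero-count elements dropped.
#' @examples
#' comp_add(c(C = 2, H = 3, N = 1, O = 1), c(H = 2, O = 1))
#' @export
comp_add <- function(...) {
  parts <- list(...)
  out <- numeric(0)
  for (p in parts) {
    if (length(p) == 0) next
    stopifnot(!is.null(names(p)), all(nzchar(names(p))))
    for (el in names(p)) out[el] <- (if (el %in% names(out)) out[[el]] else 0) + p[[el]]
  }
  out[out != 0]
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp named numeric vector (element -> count).
#' @return Mass in Da.
#' @examples
#' comp_mass(c(H = 2, O = 1)) # water, 18.01056
#' @export
comp_mass <- function(comp) {
  if (length(comp) == 0) return(0)
  unknown <- setdiff(names(comp), names(.ELEMENT_MASS))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(.ELEMENT_MASS[names(comp)] * comp)
}

# ---- modifications -----------------------------------------------------------

new_modification <- function(name, delta, fixed_charge = 0L, site = "",
                             reporter = NULL, reporter_charge = 0L) {
  stopifnot(is.character(name), length(name) == 1L, fixed_charge >= 0L)
  structure(
    list(
      name = name, delta = delta, fixed_charge = as.integer(fixed_charge),
      site = site, reporter = reporter,
      reporter_charge = as.integer(reporter_charge)
    ),
    class = "modification"
  )
}

# Built-in modifications:
#  * tpp: condensation of 2,4,6-triphenylpyrylium with the lysine epsilon-amine
#    forms an N-alkyl-2,4,6-triphenylpyridinium cation; the pyrylium C23H17O+
#    adds and water leaves taking two amine hydrogens, net peptide delta
#    +C23H15 with one permanent positive charge. Its reporter ion is
#    protonated 2,4,6-triphenylpyridine (C23H17N + H+).
#  * oxidation: +O on methionine.
#  * carbamidomethyl: +C2H3NO on cysteine (iodoacetamide alkylation).
.BUILTIN_MODS <- list(
  tpp = new_modification(
    "tpp", c(C = 23, H = 15), fixed_charge = 1L, site = "K",
    reporter = c(C = 23, H = 17, N = 1), reporter_charge = 0L
  ),
  oxidation = new_modification("oxidation", c(O = 1), site = "M"),
  carbamidomethyl = new_modification(
    "carbamidomethyl", c(C = 2, H = 3, N = 1, O = 1), site = "C"
  )
)

#' Built-in and user-defined modification definitions
#'
#' Returns the modification registry as a tibble. Built-ins are the TPP
#' fixed-charge tag (`tpp`, +C23H15, charge +1, lysine), methionine oxidation
#' (`oxidation`, +O) and cysteine carbamidomethylation (`carbamidomethyl`,
#' +C2H3NO).
#'
#' @param extra optional named list of modification objects (from
#'   [read_modifications()]) merged over the built-ins.
#' @return A tibble with columns `name`, `delta_mass`, `fixed_charge`, `site`,
#'   `has_reporter`.
#' @export
mod_definitions <- function(extra = NULL) {
  mods <- .mod_registry(extra)
  tibble::tibble(
    name = vapply(mods, `[[`, "", "name"),
    delta_mass = vapply(mods, function(m) comp_mass(m$delta), 0),
    fixed_charge = vapply(mods, `[[`, 0L, "fixed_charge"),
    site = vapply(mods, `[[`, "", "site"),
    has_reporter = vapply(mods, function(m) !is.null(m$reporter), NA)
  )
}

.mod_registry <- function(extra = NULL) {
  mods <- .BUILTIN_MODS
  if (!is.null(extra)) mods[names(extra)] <- extra
  mods
}

.resolve_mod <- function(mod, extra = NULL) {
  if (inherits(mod, "modification")) return(mod)
  registry <- .mod_registry(extra)
  key <- tolower(as.character(mod))
  if (!key %in% names(registry)) {
    stop("unknown modification '", mod, "'", call. = FALSE)
  }
  registry[[key]]
}

#' Read modification definitions from a YAML config file
#'
#' Each entry needs `name`, `delta` (element -> signed count map) and
#' optionally `fixed_charge`, `site` (residue letters the modification may
#' occupy), `reporter` (element map for a reporter ion species) and
#' `reporter_charge` (intrinsic charge of the reporter species; 0 means the
#' reporter is protonated to +1).
#'
#' @param path path to a YAML file holding a list of modification entries.
#' @return Named list of modification objects, usable as `extra` in
#'   [mod_definitions()] and as `mods` entries in [peptide()].
#' @export
read_modifications <- function(path) {
  entries <- yaml::read_yaml(path)
  # YAML 1.1 parses bare N/Y keys as booleans; map them back to the elements
  fix_elements <- function(x) {
    if (is.null(x)) return(NULL)
    x <- unlist(x)
    names(x)[names(x) == "FALSE"] <- "N"
    names(x)[names(x) == "TRUE"] <- "Y"
    x
  }
  mods <- lapply(entries, function(e) {
    stopifnot(!is.null(e$name), !is.null(e$delta))
    new_modification(
      name = e$name,
      delta = fix_elements(e$delta),
      fixed_charge = e$fixed_charge %||% 0L,
      site = e$site %||% "",
      reporter = fix_elements(e$reporter),
      reporter_charge = e$reporter_charge %||% 0L
    )
  })
  stats::setNames(mods, tolower(vapply(mods, `[[`, "", "name")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- peptides ----------------------------------------------------------------

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) {
    stop("zero-length peptide sequence", call. = FALSE)
  }
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(.RESIDUE_COMP))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  residues
}

#' Construct a peptide with site-localized modifications
#'
#' @param sequence single peptide string over the 20 standard residue letters.
#' @param mods optional data frame with columns `position` (1-based residue
#'   index) and `mod` (modification name or object). Each position may carry at
#'   most one modification, and the residue must satisfy the modification's
#'   site rule (e.g. TPP only on lysine).
#' @param extra_mods optional registry extension from [read_modifications()].
#' @return A `peptide` object.
#' @examples
#' peptide("MIAAEAEK", mods = data.frame(position = 8, mod = "tpp"))
#' @export
peptide <- function(sequence, mods = NULL, extra_mods = NULL) {
  residues <- .check_sequence(sequence)
  mod_list <- list()
  if (!is.null(mods) && nrow(as.data.frame(mods)) > 0) {
    mods <- as.data.frame(mods)
    stopifnot(all(c("position", "mod") %in% names(mods)))
    if (anyDuplicated(mods$position)) {
      stop("at most one modification per site", call. = FALSE)
    }
    for (i in seq_len(nrow(mods))) {
      pos <- as.integer(mods$position[[i]])
      m <- .resolve_mod(mods$mod[[i]], extra_mods)
      if (pos < 1L || pos > length(residues)) {
        stop("modification position ", pos, " outside sequence", call. = FALSE)
      }
      if (nzchar(m$site) && !grepl(residues[pos], m$site, fixed = TRUE)) {
        stop("modification '", m$name, "' not allowed on residue '",
             residues[pos], "' at position ", pos, call. = FALSE)
      }
      mod_list[[length(mod_list) + 1L]] <- list(position = pos, mod = m)
    }
  }
  structure(
    list(sequence = sequence, residues = residues, mods = mod_list),
    class = "peptide"
  )
}

.as_peptide <- function(x) {
  if (inherits(x, "peptide")) x else peptide(x)
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$sequence, "\n", sep = "")
  for (m in x$mods) {
    cat("  ", m$mod$name, " @ ", m$position,
        " (", x$residues[m$position], ")\n", sep = "")
  }
  invisible(x)
}

#' Total fixed charge carried by a peptide's modifications
#'
#' @param x a [peptide()] or bare sequence string.
#' @return Integer fixed charge (0 for unmodified peptides).
#' @export
fixed_charge <- function(x) {
  x <- .as_peptide(x)
  sum(vapply(x$mods, function(m) m$mod$fixed_charge, 0L))
}

#' Full elemental composition of a peptide
#'
#' Residue compositions plus one water plus all modification deltas. For a
#' fixed-charge species this is the composition of the cation's atoms.
#'
#' @inheritParams fixed_charge
#' @return Named numeric vector (element -> count).
#' @export
peptide_composition <- function(x) {
  x <- .as_peptide(x)
  comp <- .WATER_COMP
  for (r in x$residues) comp <- comp_add(comp, .RESIDUE_COMP[[r]])
  for (m in x$mods) comp <- comp_add(comp, m$mod$delta)
  comp
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue masses + water + modification deltas. For fixed-charge
#' species this is the mass of the cation's atoms (protonation beyond the
#' fixed charge is handled by [precursor_mz()] / [fragment_mz()]).
#'
#' @inheritParams fixed_charge
#' @return Mass in Da.
#' @examples
#' neutral_mass("MIAAEAEK")
#' @export
neutral_mass <- function(x) {
  comp_mass(peptide_composition(.as_peptide(x)))
}

#' Precursor m/z at a given total charge
#'
#' Protons are added only beyond the fixed charge already carried by the
#' peptide's modifications: m/z = (M + (z - f) * 1.007276) / z where f is the
#' fixed charge.
#'
#' @inheritParams fixed_charge
#' @param total_charge total charge state z (>= 1 and >= the fixed charge).
#' @return m/z in Thomson.
#' @examples
#' precursor_mz("MIAAEAEK", 1)
#' @export
precursor_mz <- function(x, total_charge) {
  x <- .as_peptide(x)
  z <- as.integer(total_charge)
  if (z < 1L) stop("total_charge must be >= 1", call. = FALSE)
  f <- fixed_charge(x)
  if (z < f) stop("fewer charges than fixed charges", call. = FALSE)
  (neutral_mass(x) + (z - f) * .PROTON_MASS) / z
}

#' Fragment ion m/z (b and y series)
#'
#' y_i is the C-terminal i residues plus water; b_i is the N-terminal i
#' residues. Site-localized modifications are carried by the fragment that
#' contains their residue; protons are added only beyond the fragment's fixed
#' charge.
#'
#' @inheritParams precursor_mz
#' @param series `"b"` or `"y"`.
#' @param index fragment length, 1 to length(peptide) - 1.
#' @return m/z in Thomson.
#' @examples
#' fragment_mz("MIAAEAEK", "y", 6, 1)
#' @export
fragment_mz <- function(x, series, index, total_charge = 1L) {
  x <- .as_peptide(x)
  series <- match.arg(series, c("b", "y"))
  n <- length(x$residues)
  index <- as.integer(index)
  if (index < 1L || index > n - 1L) {
    stop("fragment index must be between 1 and ", n - 1L, call. = FALSE)
  }
  positions <- if (series == "y") (n - index + 1L):n else 1L:index
  comp <- if (series == "y") .WATER_COMP else numeric(0)
  for (p in positions) comp <- comp_add(comp, .RESIDUE_COMP[[x$residues[p]]])
  f_frag <- 0L
  for (m in x$mods) {
    if (m$position %in% positions) {
      comp <- comp_add(comp, m$mod$delta)
      f_frag <- f_frag + m$mod$fixed_charge
    }
  }
  z <- as.integer(total_charge)
  if (z < 1L) stop("total_charge must be >= 1", call. = FALSE)
  if (z < f_frag) stop("fewer charges than fixed charges", call. = FALSE)
  (comp_mass(comp) + (z - f_frag) * .PROTON_MASS) / z
}

#' Reporter ion m/z of a fixed-charge tag
#'
#' The TPP tag's reporter is protonated 2,4,6-triphenylpyridine (C23H17N +
#' H+). If a tag's reporter composition already carries an intrinsic charge,
#' no proton is added.
#'
#' @param tag modification name or object (must define a reporter).
#' @param extra_mods optional registry extension.
#' @return m/z in Thomson (singly charged).
#' @examples
#' reporter_mz("tpp")
#' @export
reporter_mz <- function(tag, extra_mods = NULL) {
  m <- .resolve_mod(tag, extra_mods)
  if (is.null(m$reporter) || length(m$reporter) == 0) {
    stop("modification '", m$name, "' has no reporter ion defined",
         call. = FALSE)
  }
  mass <- comp_mass(m$reporter)
  (mass + (1L - m$reporter_charge) * .PROTON_MASS) / 1
}

#' Round half away from zero
#'
#' Display rounding used for m/z (2 dp) and percent-change (integer) values;
#' base `round()` rounds half to even, which does not match the printed-table
#' convention.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny eps absorbs binary representation error in values like x.xx5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' @rdname round_half_away
#' @export
round_mz <- function(x, digits = 2) round_half_away(x, digits)

proton_mass <- function() .PROTON_MASS
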