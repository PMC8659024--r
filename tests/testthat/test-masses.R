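test_that("neutral mass matches independent residue-summation oracle", {
  expect_equal(neutral_mass("G"), 75.03203, tolerance = 1e-7)
  expect_equal(neutral_mass("MIAAEAEK"), oracle_peptide_mass("MIAAEAEK"),
               tolerance = 1e-7)
  expect_equal(neutral_mass("MIAAEAEK"), 861.42658, tolerance = 1e-7)
  # TPP tag on the C-terminal lysine: net +C23H15, electron mass neglected
  tpp <- peptide("MIAAEAEK", mods = data.frame(position = 8, mod = "tpp"))
  expect_equal(neutral_mass(tpp), 1152.54396, tolerance = 1e-3)
  expect_equal(fixed_charge(tpp), 1L)

  withr::with_seed(11, {
    for (i in 1:300) {
      s <- random_peptide()
      expect_equal(neutral_mass(s), oracle_peptide_mass(s), tolerance = 1e-6)
    }
  })
})

test_that("sequence and modification validation errors are informative", {
  expect_error(neutral_mass("AAKBB"), "B")
  expect_error(neutral_mass(""), "zero-length")
  expect_error(peptide("MIAAEAEK", data.frame(position = 1, mod = "tpp")),
               "not allowed")
  expect_error(
    peptide("MIAAEAEK",
            data.frame(position = c(8, 8), mod = c("tpp", "tpp"))),
    "one modification per site"
  )
  expect_error(peptide("AK", data.frame(position = 5, mod = "tpp")),
               "outside")
  expect_error(peptide("AK", data.frame(position = 2, mod = "nosuchmod")),
               "unknown modification")
})

test_that("precursor m/z reproduces printed transition precursors", {
  expect_equal(precursor_mz("MIAAEAEK", 1), 862.434, tolerance = 1e-3)
  ox <- peptide_variant("MIAAEAEK", "ox")
  expect_equal(round_mz(precursor_mz(ox, 1)), 878.43)
  tpp <- peptide_variant("MIAAEAEK", "tpp")
  expect_equal(round_mz(precursor_mz(tpp, 2)), 576.78)
  # protons only beyond the fixed charge
  expect_error(precursor_mz(tpp, 0), "must be >= 1")
  expect_equal(precursor_mz(tpp, 1), neutral_mass(tpp)) # z = f: no proton
  two_tag <- peptide("KAK", data.frame(position = c(1, 3),
                                       mod = c("tpp", "tpp")))
  expect_error(precursor_mz(two_tag, 1), "fewer charges than fixed")
})

test_that("fragment m/z reproduces printed products and carries mods", {
  expect_equal(fragment_mz("MIAAEAEK", "y", 6, 1),
               oracle_fragment_mz("MIAAEAEK", "y", 6), tolerance = 1e-6)
  expect_equal(round_mz(fragment_mz("MIAAEAEK", "y", 6, 1)), 618.31)
  ox <- peptide_variant("MIAAEAEK", "ox")
  expect_equal(round_mz(fragment_mz(ox, "b", 2, 1)), 261.13)
  # oxidation sits on Met1: y-ions are unshifted
  expect_equal(fragment_mz(ox, "y", 3, 1), fragment_mz("MIAAEAEK", "y", 3, 1))
  tpp <- peptide_variant("MIAAEAEK", "tpp")
  expect_equal(round_mz(fragment_mz(tpp, "y", 3, 1)), 637.30)
  # the tagged y3 carries the fixed charge: no proton added
  expect_equal(fragment_mz(tpp, "y", 3, 1),
               oracle_fragment_mz("MIAAEAEK", "y", 3,
                                  delta = neutral_mass(tpp) -
                                    neutral_mass("MIAAEAEK"),
                                  fixed = TRUE),
               tolerance = 1e-3)
  # but b-ions upstream of the tag are plain protonated fragments
  expect_equal(fragment_mz(tpp, "b", 2, 1), fragment_mz("MIAAEAEK", "b", 2, 1))
  expect_error(fragment_mz("MIAAEAEK", "y", 8, 1), "between 1 and 7")
  expect_error(fragment_mz("MIAAEAEK", "y", 0, 1), "between 1 and 7")
  expect_error(fragment_mz(tpp, "y", 3, 0), "must be >= 1")
})

test_that("reporter ion m/z is the protonated tag pyridine", {
  expect_equal(reporter_mz("tpp"), 308.143, tolerance = 1e-3)
  expect_error(reporter_mz("oxidation"), "no reporter")
})

test_that("custom modifications load from YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "- name: toy_tag",
    "  delta: {C: 2, H: 2}",
    "  fixed_charge: 1",
    "  site: K",
    "  reporter: {C: 6, H: 6, N: 1}",
    "  reporter_charge: 1"
  ), path)
  extra <- read_modifications(path)
  defs <- mod_definitions(extra)
  expect_true("toy_tag" %in% defs$name)
  # intrinsically charged reporter: composition mass / 1, no proton
  expect_equal(reporter_mz("toy_tag", extra_mods = extra),
               comp_mass(c(C = 6, H = 6, N = 1)))
  pep <- peptide("AK", data.frame(position = 2, mod = "toy_tag"),
                 extra_mods = extra)
  expect_equal(fixed_charge(pep), 1L)
})

test_that("b/y complementarity: b_i + y_(n-i) = precursor(z=1) + proton", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      s <- random_peptide()
      n <- nchar(s)
      prec <- precursor_mz(s, 1)
      for (i in seq_len(n - 1)) {
        expect_equal(
          fragment_mz(s, "b", i, 1) + fragment_mz(s, "y", n - i, 1),
          prec + 1.007276,
          tolerance = 1e-6
        )
      }
    }
  })
})

test_that("positive-delta modifications strictly increase neutral mass", {
  base <- neutral_mass("MCAAEAEK")
  for (v in c("ox", "cam", "tpp")) {
    expect_gt(neutral_mass(peptide_variant("MCAAEAEK", v)), base)
  }
})

test_that("half-away-from-zero rounding matches display convention", {
  expect_equal(round_half_away(c(0.5, 1.5, -0.5, 2.675), 0), c(1, 2, -1, 3))
  expect_equal(round_half_away(2.675, 2), 2.68) # binary-representation case
  expect_equal(round_mz(576.775), 576.78)
})
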