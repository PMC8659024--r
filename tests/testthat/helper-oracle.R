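# Independent oracle for peptide mass arithmetic: incremental summation over
# a frozen monoisotopic residue-mass table (standard amino-acid table, 5 dp
# or better), kept deliberately separate from the package's element-counting
# path.

ORACLE_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276

oracle_peptide_mass <- function(sequence, delta = 0) {
  sum(ORACLE_RESIDUE[strsplit(sequence, "")[[1]]]) + ORACLE_WATER + delta
}

# y_i: C-terminal i residues + water; b_i: N-terminal i residues.
# Singly protonated m/z, optional mass delta and fixed-charge flag.
oracle_fragment_mz <- function(sequence, series, index, delta = 0,
                               fixed = FALSE) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  part <- if (series == "y") res[(n - index + 1):n] else res[1:index]
  mass <- sum(ORACLE_RESIDUE[part]) + if (series == "y") ORACLE_WATER else 0
  mass + delta + if (fixed) 0 else ORACLE_PROTON
}

random_peptide <- function(min_len = 2, max_len = 30) {
  n <- sample(min_len:max_len, 1)
  paste(sample(names(ORACLE_RESIDUE), n, replace = TRUE), collapse = "")
}
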