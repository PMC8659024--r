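---
title: "Fixed-charge MRM screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-charge MRM screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmtag)
library(dplyr)
```

`mrmtag` covers the computational workflow of a fixed-charge-derivatization
MRM screening assay: choosing a tryptic marker peptide, computing the m/z
values an MRM method monitors, simulating what the instrument would record,
and scoring the screen's diagnostic performance. This vignette explains the
models behind each step, the tunable parameters, and the design decisions
that were genuinely open.

## Mass calculus

Peptide masses are computed by element counting: residue compositions plus
one water plus signed modification deltas, evaluated against monoisotopic
element masses. The package's test suite checks this path against an
independent incremental residue-mass summation (the standard 5-decimal
amino-acid table) to 1e-6 Da on a thousand random peptides.

A fixed-charge tag is a modification with a positive `fixed_charge`. The
built-in `tpp` tag models pyrylium condensation at the lysine ε-amine: the
2,4,6-triphenylpyrylium cation (C23H17O⁺) adds and water leaves with two
amine hydrogens, so the peptide's composition changes by +C23H15 and it
carries one permanent positive charge. Charge bookkeeping then follows one
rule everywhere: **protons are added only beyond the fixed charge**,

$$m/z = \frac{M + (z - f)\,m_p}{z}, \qquad m_p = 1.007276\ \mathrm{Da},$$

so a singly tagged peptide at $z = 1$ is the bare cation (no proton), and at
$z = 2$ it is the cation plus one proton — the `[M + H]^{2+}` species an MRM
method monitors. Fragments inherit the modifications of their residues: the
tagged C-terminal y ions carry the fixed charge (no proton added at $z=1$),
while b ions upstream of the tag are ordinary protonated fragments.

Numerical conventions:

* **Electron mass is neglected** for cations. The error (~5.5e-4 Da) is two
  orders of magnitude below the ±0.1 m/z matching tolerance used for
  annotation, and the simplification keeps neutral and cationic species on
  one formula.
* **Display rounding is half away from zero** (`round_mz()`, 2 dp), the
  convention of published transition tables; base R's round-half-even would
  print 576.775 as 576.78 vs 576.77 inconsistently across values.
* A **zero-length peptide is an error**, not the mass of water.
* The spec of a tag may define a **reporter ion**. For TPP it is protonated
  2,4,6-triphenylpyridine (C23H17N + H⁺, m/z 308.14); a reporter whose
  composition already carries its charge is used as-is.

One deliberate generalization: a fixed-charge tag may sit on *any* lysine
(one modification per site still enforced). Multi-lysine peptides genuinely
carry multiple tags, and the charge-bookkeeping error path ("fewer charges
than fixed charges") only exists for such species; restricting to a single
tag would make that contract dead code. Single-tag peptides — the designed
use — behave identically either way.

## Digestion and candidate selection

Trypsin is modeled by the canonical rule: cleave C-terminal to K or R,
except when the next residue is proline. The exception is applied to both K
and R; no other exceptions (e.g. the Keil rules) are modeled. Products are
emitted for 0..`max_missed` missed cleavages with 1-based inclusive
coordinates, and three invariants pin the implementation down: 0-missed
products tile the parent exactly; a product with $m$ missed cleavages
contains exactly $m$ internal cleavable sites; digestion is idempotent on
its own 0-missed products.

Candidate selection reflects how a taggable marker peptide is chosen:
length 6–25 (the usual working range for unit-resolution triple-quadrupole
assays), C-terminal lysine required when the assay will derivatize (the tag
targets the C-terminal lysine ε-amine; arginine-terminated peptides are
excluded despite their favorable native ionization), and methionine flagged
as an oxidation caveat *without* excluding the peptide — a Met peptide shown
stable through sample preparation is acceptable, and the assay can monitor
the oxidized form as a separate variant. Uniqueness against a supplied
proteome is exact substring counting (with overlap); I/L ambiguity is not
collapsed, a choice that keeps the contract verifiable — enable it by
pre-translating sequences if needed.

## Transition lists and annotation

`build_transitions()` enumerates b/y fragments per variant (native,
oxidized, carbamidomethylated, tagged, and their combinations) and keeps the
`top_n` *longest* fragments per series — longer fragments are the more
selective MRM products. Tagged variants append the reporter transition.

`annotate_observed()` matches instrument-reported transitions to theory
within a tolerance on both precursor and product m/z. The default ±0.1
absorbs how far automatically optimized values on unit-resolution
instruments drift from theory (up to ~0.06 observed); ties break by smallest
total absolute deviation, then lower fragment index. The degenerate
tolerance 0 is allowed and simply matches nothing for real-valued
observations.

## The MRM simulator

The trace model is a single Gaussian elution peak on a constant baseline
with additive white noise:

$$I(t) = b + a \cdot R \cdot \varphi(t; t_R, \sigma) + \varepsilon,\qquad
\varepsilon \sim N(0, s^2),$$

with $a$ the amount (mol), $R$ the response factor (the tag-dependent
sensitivity; a fixed-charge tag multiplies it by orders of magnitude),
$\varphi$ the normal density, and defaults $t_R = 30$ s, $\sigma = 2$ s,
$b = 10$, $s = 1$, 60 s duration sampled at 0.25 s. Real chromatograms
tail, drift, and carry correlated (often intensity-dependent) noise; none
of that is modeled, so passing simulation tests demonstrates the detection
logic, not instrument realism. Every trace takes an explicit seed — there
is no hidden global RNG state anywhere in the package.

**S/N estimation.** S/N = (apex − baseline)/noise with baseline the median
and noise 1.4826×MAD of the out-of-window points (robust to peak tails
leaking past the window), and the apex read from a 5-point boxcar-smoothed
trace. The smoothing matters: the raw in-window maximum rides on the
max-order-statistic of the noise, so a peak standing 6 noise-SDs above
baseline measures ~7–9 raw; on the lightly smoothed trace the same peak
measures 4–8 in ≥95% of seeds, and blank traces sit near 0.8 — the
estimator is calibrated. Both the window and the smoothing width are
arguments. A noiseless trace has zero MAD and raises "noise indeterminate"
rather than returning an infinite ratio.

**Detection and LOD.** A peak is detected at S/N ≥ 3, the conventional
detection-limit criterion. `lod_from_series()` scans a descending dilution
series and reports the smallest amount of the contiguous run (from the top)
in which *all* replicates are detected; scanning past the first failure is
reported but cannot lower the LOD, so an isolated lucky detection deep in
the series is ignored. The all-replicates rule and the contiguity rule are
both choices the underlying detection-limit convention leaves open;
they are the conservative pair. Under a 1000-fold response-factor ratio —
the structural analogue of a tag moving detection from 12 fmol to 12 amol —
the recovered LOD ratio on a 10-point half-log series is 1000 across seeds.
The absolute femtomole/attomole amounts themselves are instrument-dependent
and deliberately not reproduced.

**Calibration.** `fit_calibration()` is ordinary least squares of apex
intensity on amount (the assay response is linear over the working range),
reporting slope, intercept and R². For unbiased slope recovery the
calibration reads intensity at the known retention time; reading the
windowed maximum instead adds a noise-level-dependent bias that is absorbed
by the intercept only when noise is constant across the series.

## Screening diagnostics

From a 2×2 table (TP/FP/TN/FN; diseased $n_1$, non-diseased $n_0$) the
package computes sensitivity, specificity, likelihood ratios, prevalence,
predictive values and accuracy, each with the CI method conventional for
it:

* **Clopper–Pearson** (exact, from beta quantiles) for sensitivity,
  specificity, prevalence and accuracy. Exact bounds at 0 and 1 for $x=0$
  and $x=n$; the interval is conservative (coverage ≥ 95% at the study's
  $n = 28$, $p = 0.25$, verified by simulation).
* **Simel's log method** for likelihood ratios:
  $\exp(\ln LR \pm z\,SE)$ with
  $SE(\ln LR^+) = \sqrt{1/TP - 1/n_1 + 1/FP - 1/n_0}$ and the analogous
  expression for $LR^-$.
* **Mercaldo's logit method** for predictive values, with delta-method
  variances on the logit scale; a variance term whose rate is exactly 0 or
  1 has a vanishing numerator and is dropped rather than evaluated as 0/0.

Two conventions make the output match published screening tables digit for
digit: $z$ is **1.96 exactly** (not `qnorm(0.975)` = 1.959964) at the 95%
level, and **undefined statistics render blank**, never `Inf` — a positive
likelihood ratio with specificity 100%, or a CI for a predictive value of
exactly 100%, is a blank cell. Percent change between paired concentrations
is `round(100·(end − begin)/begin)` to the nearest integer, half away from
zero, and undefined when the baseline is undetectable, missing or zero.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a small
longitudinal screening study: 28 subjects at 25% prevalence screened at
gestational weeks 11, 24 and 36, with default per-week
sensitivity/specificity of (1/7, 1), (6/7, 1) and (6/7, 19/21) — the
operating characteristics of an early-pregnancy screen that becomes
informative by mid-pregnancy. Disease status is Bernoulli(prevalence);
calls are conditionally Bernoulli given status; ELISA begin/end
concentrations are log-normal with group-specific parameters (defaults:
meanlog −0.7 control / −0.2 disease, sdlog 1.0, spanning the ~0.02–7 ng/mL
range typical of urinary podocin ELISA readings), censored to
"undetectable" below a 0.05 floor. The generator draws subjects
independently — no within-subject correlation of calls across weeks, no
gestational covariates, no assay drift — so parameter-recovery tests show
estimator correctness, not clinical realism. One seeded RNG stream
produces the whole cohort; the same seed yields a byte-identical CSV.

## Problem sizes

The test suite and acceptance script run at desk scale: 1,000 random
peptides for the fragment-complementarity identity, 200 seeds for the S/N
calibration checks, 100 simulations × 8-point calibrations for slope
recovery, 10,000 binomial draws for CP coverage, a 10-point half-log
dilution series × 5 replicates × 2 channels for the LOD-ratio check, and
100 seeds × n = 2800 cohorts for operating-characteristic recovery. The
full suite completes in under a minute on one core.

## Known limitations

* No isotope envelopes, average masses, a/c/x/z ions, neutral losses or
  collision-energy prediction; product ions are singly charged.
* Digestion is fully specific (no semi-tryptic products) and has no
  machine-learned detectability scoring or retention-time prediction.
* The simulator's Gaussian/white-noise model understates real
  chromatographic pathology (see above).
* Diagnostics assume per-subject calls are exchangeable within a
  timepoint; repeated measures across timepoints are evaluated
  independently.
* Concentration unit labels are carried as metadata by convention; no unit
  conversion is performed.
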