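---
title: "Assessing structural universality in dissolved organic matter by FT-ICR-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing structural universality in dissolved organic matter by FT-ICR-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fticrdom)
library(dplyr)
```

## The scientific problem

Dissolved organic matter (DOM) in natural waters is a mixture of tens of
thousands of compounds. Ultrahigh-resolution mass spectrometry resolves the
mixture into exact ion masses and, through constrained enumeration, into
molecular formulas — but a formula is not a structure: each formula is
backed by an unknown number of isomers. Two samples can share thousands of
formulas and still be structurally different. The analysis this package
implements asks the sharper question: when two environments share a
molecular formula, do they also share the *structures* behind it?

The measurable proxy for structure is the fragmentation fingerprint. DOM
ions fragment almost exclusively by losing CO~2~ (decarboxylation), H~2~O,
CH~3~OH and combinations thereof, so the relative intensities of those
neutral-loss fragments encode the functional-group makeup of the isomer
mixture behind a precursor. If two samples contain the same compounds, a
regression of one sample's relative fragment intensities on the other's
must have slope 1; the deviation Δsl = |1 − slope| and the Bray–Curtis
dissimilarity of the fragment-intensity vectors quantify structural
difference on a continuous scale, with replicate analyses of one sample
defining the noise floor.

## Pipeline stages and their models

### Masses, formulas, classes

All masses derive from one table of CODATA/IUPAC monoisotopic constants
(`dom_masses()`). Ions are singly charged \[M−H\]^−^; the default ion mass
convention is `neutral − 1.00727646` Da (the proton mass), with an
equivalent explicit electron-count form selectable so the convention is
always visible in output headers. DBE uses trivalent N and P, the standard
convention for negative-mode DOM work; it is configurable because some
groups prefer pentavalent P for phosphate esters.

Compound classes follow the modified aromaticity index
$$\mathrm{AI_{mod}} = \frac{1 + C - 0.5\,O - S - 0.5\,(N+P+H)}{C - 0.5\,O - S - N - P},$$
with degenerate (non-positive) numerators or denominators defined as 0 so
that oxygen-rich aliphatics cannot receive spurious aromatic labels. The
class bounds treat the polyphenol band as $0.5 \le \mathrm{AI_{mod}} <
0.666$: the boundary set is the only internally consistent reading of the
usual shorthand, with condensed aromatics taking strict priority at
$\ge 0.666$.

### Calibration

Internal calibration fits the systematic mass error, on the ppm scale, as
a linear function of m/z (`ppm = a + b·mz`) over matched reference masses
and inverts it. The functional form is the standard choice for FT-ICR
spectra, where residual errors after external calibration are smooth in
m/z; order 0 (constant offset) is selectable. At least three matched
references are required and the residual max |ppm| is compared against a
0.06 ppm gate — a spectrum failing the gate is flagged, not silently
corrected. Fragmentation scans cannot use a generic reference list (only
one nominal mass is isolated), so the predicted exact masses of the
window's precursors and their neutral-loss fragments serve as references —
a bootstrap that works because the loss masses are known exactly.

### Formula assignment

Candidates for a measured m/z are every composition in the box C~1–60~,
N~0–4~, S~0–2~, P~0–1~, O/C ≤ 1, H/C ≥ 0.3, with hydrogen closed by
chemistry (H ≤ 2C + N + P + 2, i.e. DBE ≥ 0) and DBE forced integer (which
subsumes the nitrogen rule for even-electron ions). The enumerator solves
H directly from the residual mass per heteroatom combination, so its cost
is the heteroatom grid (~10^5 combinations), not the full box; an
independent brute-force oracle in the test suite checks exact equivalence.

Tie-breaking deserves a note. At sub-ppm tolerances the dangerous
degeneracies are *compositional mass splits*, the worst being the
0.163 mDa exchange C~5~H~−5~O~6~ ↔ N~4~PS~2~, which places a
heteroatom-saturated candidate within tolerance of most CHO peaks above
~400 Da. Random mass jitter reorders the two candidates' ppm distances
about half the time, so "smallest |error| wins" misassigns a large
fraction of heavy peaks. The implemented ladder therefore treats
candidates whose |ppm| differ by less than a tie band (default: the
tolerance itself) as indistinguishable at the instrument's accuracy and
ranks them by heteroatom parsimony, then by ¹³C₁ companion-intensity
evidence (the expected companion/parent ratio is `c·0.0107/0.9893`, so the
carbon number is testable when a companion peak is present), then by ppm,
then lexicographically. This mirrors how practitioners actually resolve
such splits and is fully deterministic.

Isotopologue verification computes the expected ¹³C₁/¹⁵N₁ position from
the *theoretical* parent ion mass plus the isotope mass difference (one
jitter term instead of two), flags matches within tolerance, and applies a
×/÷3 plausibility band around the binomial intensity expectation. A peak
already carrying a monoisotopic assignment is reclaimed as an isotopologue
only when the isotope spacing explains its mass strictly better than the
assignment does.

### Fragmentation statistics

`I_Tot` for a precursor is its own peak intensity plus its nine major-loss
fragment intensities; every relative intensity is a share of that total,
so shares sum to exactly 1 and absent fragments are explicit zeros (this
keeps samples aligned for regression without imputation). Ambiguous
attributions — one fragment mass explicable by two (precursor, loss) pairs
within tolerance — are excluded by default; proportional splitting is
available but exclusion is conservative and reproducible. CO and other
minor losses are annotated but never enter `I_Tot`.

The common detection limit addresses a censoring asymmetry: a fragment
visible in a high-dynamic-range sample may be undetectable in a weaker
one, and treating that as a structural difference would be wrong. Per
precursor, the limit is the minimum precursor S/N across samples, and any
fragment share below `noise/limit` in *any* sample is zeroed in *all*
samples. The censored table feeds the cross-sample comparisons; the
carboxyl estimator deliberately uses the uncensored table, because zeroing
small high-multiplicity fragments would bias the intensity-weighted
multiplicity mean downward.

The paired regression is ordinary least squares of sample B's shares on
sample A's, with pairs ordered lexicographically (the first label is
always the abscissa — OLS is direction-asymmetric, so the convention is
fixed). At most one point may be excluded, and only if its externally
studentized residual exceeds 4; both raw and screened fits are reported,
so no exclusion is silent. Bray–Curtis dissimilarity is computed at three
levels — all assigned formulas, the common-formula intersection
(renormalized over that subset by default, so the level is a
self-contained composition; a flag disables this), and fragments of common
formulas. The two-vector form is the package's own arithmetic; matrices go
through `vegan::vegdist`, the same tool a practitioner would use, and the
two routes are cross-checked against a brute-force oracle in the tests.

### Isomeric diversity

The carboxyl content of a precursor can be estimated two independent ways:
from its fragmentation pattern, as the intensity-weighted mean CO~2~
multiplicity $c_{frag} = \sum_k k I_k / \sum_k I_k$ (combined losses count
only their CO~2~ content; the precursor counts at multiplicity 0), and
from its composition alone, by a linear model $a\,O + b\,\mathrm{DBE} +
c_0$ capped at ⌊O/2⌋ (two oxygens per carboxyl group — the cap is
chemistry, not tuning). A single structure would make the two estimates
disagree idiosyncratically; a formula backed by $n$ isomers averages over
them, shrinking the disagreement like $1/\sqrt{n}$. The correlation
between the two estimates across formulas is therefore a relative
isomeric-diversity index, and the residual dispersion yields a lower
bound $n_{min} = \lceil(\sigma_{single}/\sigma_{residual})^2\rceil$.
$\sigma_{single}$ — the per-isomer carboxyl dispersion — is known for
synthetic data (the generator's realized per-isomer standard deviation)
and must be supplied by the user for real data; because measurement noise
inflates $\sigma_{residual}$, the bound errs low, which is the safe
direction for a minimum. Multiplying by the number of common formulas
turns it into a minimum count of distinct compounds in the shared
background. The compositional model's functional form is deliberately
pluggable: for real data its coefficients must come from external
calibration, and every report prints the model in force.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's claims are validated.

* **Full-range spectra.** Formulas are drawn as CH~2~ homologous series
  seeded per compound class from an enumerated CHO(N) pool, with the class
  mixture defaulting to a DOM-like composition dominated by highly
  unsaturated compounds. Intensities follow a Gaussian envelope over m/z
  centered at 370 Da (width 110 Da) — the bell shape of real DOM spectra —
  times per-formula and per-sample log-normal factors (`abundance_sd =
  0.3`) that create realistic formula-level compositional differences
  between samples. 60% of formulas are common to all samples by default;
  the rest occur in random subsets. ¹³C₁ companions are emitted at the
  binomial abundance expectation, noise peaks at 10% of the formula count
  from the envelope's lower tail, and S/N is intensity over a fixed noise
  floor.
* **Mass error.** Random jitter is a zero-mean normal with SD 0.2 ppm
  *truncated at ±2 SD*, plus a configurable systematic offset. The
  truncation is deliberate: post-calibration FT-ICR errors are bounded (a
  peak far outside the accuracy band would have failed calibration), and
  an unbounded Gaussian would place ~1.2% of peaks outside any 0.5 ppm
  tolerance by construction, making "near-complete recovery" impossible
  for reasons that have nothing to do with assignment quality.
* **Fragmentation profiles.** Each formula is backed by
  `isomers_per_formula` isomers whose carboxyl counts scatter (SD 0.5)
  around the compositional expectation, truncated to the physically
  representable range. An isomer with count $k$ keeps a fixed precursor
  survivor share (25%) and distributes its fragment mass over
  decarboxylation multiplicities as a binomial whose success probability
  is solved so the intensity-weighted mean multiplicity equals $k$
  exactly; within a multiplicity class, mass is split over the losses the
  formula can actually perform, so physical availability never biases the
  mean. The emitted profile is the average of per-isomer Dirichlet draws
  (concentration 500), times 5% multiplicative intensity noise — so isomer
  averaging, its $1/\sqrt{n}$ signature, and the replicate noise floor all
  emerge from the construction rather than being asserted.
* **Divergence knob.** `profile_divergence` (δ) interpolates each sample's
  mean profile between a shared global profile (δ = 0: structurally
  identical samples) and independent per-sample profiles (δ = 1). The
  universality contrast, its monotone destruction with δ, and the
  replicate band are all expressible through this one parameter.
* **Determinism.** Every random draw derives from the config seed through
  fixed sub-seed arithmetic, so identical (seed, config) pairs give
  bit-identical output, and a `run` index redraws only measurement noise —
  two runs are analytical replicates of the same sample.

What the generator does *not* emulate: resolution-limited peak shape and
coalescence, space-charge effects, ion suppression, polyisotopic patterns
beyond ¹³C₁, and real DOM's full compositional density (thousands of
formulas per 100 Da). Passing tests therefore demonstrate the correctness
and statistical behavior of the pipeline under controlled conditions, not
instrument-level performance on deposited spectra.

## Numerical choices and edge cases

* Candidate enumeration sorts by |ppm| with the formula string as the
  final deterministic key; peak-order permutation cannot change results.
* `AI_mod` returns 0 (not NA, not negative) on degenerate denominators.
* Bray–Curtis on two all-zero vectors, regressions with degenerate
  abscissa variance, normalization of empty or zero-intensity sets, and
  windows without precursors all raise errors rather than returning
  NaN.
* Isolation windows are centered on the intensity-weighted mean m/z of a
  nominal mass's common-formula cluster, because DOM mass defects put the
  ions 0.1–0.2 Da above the integer mass and a 0.4 Da window centered on
  the integer would miss them.
* Printed-mass comparisons use R's round-half-even at 5 decimals.

## Problem sizes

The test suite validates the oracle equivalence of the enumerator on 100
random masses at 1 ppm, assignment and attribution recovery on a
500-formula two-sample scenario, the universality contrast on 20 replicate
fragmentation runs of a 250-formula scenario, and the isomer-diversity
properties on 300-formula scenarios over the isomer grid {1, 3, 10, 30,
100} (three seeds) and recovery targets {4, 25, 100} (five seeds). These
sizes give stable statistics for every claim while keeping the default
suite comfortably runnable on a laptop.

## Known limitations

* The assignment tie-break ladder is tuned for DOM-like samples where
  heteroatom-rich compositions are rare; for N/S-rich matrices (e.g.
  wastewater effluent) the tie band should be narrowed.
* The carboxyl composition model is a calibration stand-in; its
  coefficients carry no meaning outside the data they were fitted to.
* `min_isomers` is a lower bound, and a conservative one: any unmodeled
  noise shrinks it further. It should never be read as an isomer count.
* Fragment attribution assumes the precursor list is complete; an
  unassigned real precursor in the window will leave its fragments
  unattributed rather than misassigned.
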