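# fticrdom

Structural analysis of natural dissolved organic matter (DOM) from
ultrahigh-resolution mass spectrometry. DOM is among the most complex
molecular mixtures known: a single negative-mode FT-ICR-MS scan of a marine
or freshwater extract resolves thousands of ion masses, each mapping to an
elemental formula that is itself a blend of many structural isomers. A
striking observation about this mixture is that a large component of it is
*molecularly universal* — the same formulas occur across unconnected aquatic
environments, and when those shared formulas are fragmented, their neutral
losses appear at the same relative intensities everywhere, implying shared
structures, not just shared compositions.

`fticrdom` implements the complete computational chain behind that kind of
analysis, for people working with centroided FT-ICR-MS peak lists of DOM
(or any complex organic mixture measured as singly charged
\[M−H\]<sup>−</sup> ions):

* **Peak-list handling** — tab-separated peak tables (`mz`, `intensity`,
  `snr`), S/N ≥ 5 filtering, internal calibration against a reference mass
  list with a ppm-linear error model and a 0.06 ppm quality gate.
* **Molecular formula assignment** — constrained enumeration over
  C₀–₆₀H₀–∞N₀–₄O₀–cS₀–₂P₀–₁ with O/C ≤ 1, H/C ≥ 0.3, integer DBE ≥ 0;
  deterministic tie-breaking (composition parsimony within the instrument's
  mass accuracy, ¹³C₁ companion evidence); isotopologue verification with a
  binomial intensity plausibility check; compound classes from the modified
  aromaticity index
  AI_mod = (1 + C − ½O − S − ½(N+P+H)) / (C − ½O − S − N − P).
* **Fragmentation analysis** — neutral-loss prediction for the major loss
  set {CO₂, 2CO₂, 3CO₂, H₂O, CO₂+H₂O, 2CO₂+H₂O, CH₃OH, CO₂+CH₃OH,
  2CO₂+CH₃OH}, internal calibration of fragmentation scans against the
  predicted fragment masses, attribution of fragment peaks to
  (precursor, loss) pairs by exact mass difference inside 0.4 Da isolation
  windows, relative fragment intensities I_F/I_Tot, and a common detection
  limit across samples with symmetric censoring.
* **Universality statistics** — paired OLS regression of relative fragment
  intensities between samples with the slope deviation Δsl = |1 − slope|
  (Δsl = 0 means structurally indistinguishable), and Bray–Curtis
  dissimilarity BC = Σ|x−y| / Σ(x+y) at three compositional levels: all
  assigned formulas, common formulas, and fragments of common formulas.
* **Isomeric diversity** — two independent carboxyl-group estimates per
  formula (intensity-weighted decarboxylation multiplicity from the
  fragmentation pattern, and a compositional model a·O + b·DBE + c₀ capped
  at ⌊O/2⌋), their correlation as a diversity index, and a central-limit
  lower bound on isomers per formula,
  n_min = ⌈(σ_single / σ_residual)²⌉.
* **Synthetic data** — a fully seeded spectrum generator with ground truth
  (CH₂ homologous series under a bell-shaped intensity envelope,
  isotopologues, noise peaks, ppm offsets, per-isomer fragmentation
  profiles), so the entire pipeline is testable without instrument data.

Everything is data-frame-first: functions take and return tibbles, fitted
objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

```r
library(fticrdom)
library(dplyr)

# a two-environment scenario with shared fragmentation structures
cfg <- generator_config(seed = 5, n_formulae = 300,
                        sample_ids = c("A", "B", "C"))
fr   <- generate_fullrange(cfg)
asg  <- fr$peaks |> snr_filter() |> assign_formulas() |> verify_isotopologues()
wins <- select_windows(asg, k_windows = 12)
frag <- lapply(wins, \(w) list(window = w,
                               peaks = generate_fragmentation(fr, w)$peaks))
report <- run_dom_pipeline(fr$peaks, frag = frag, calibration_refs = NULL,
                           sigma_single = 0.5,
                           carboxyl_model = cfg$carboxyl_model)
report
#> <dom_report>
#>   samples: A, B, C
#>   assigned formulas per sample: 262, 265, 273
#>   common formulas: 192 (shares 73/72/70%)
#>   pairwise slope deviation delta_sl: 0.0071-0.0220 (r 0.993-0.996)
#>   Bray-Curtis all_formulae     max 0.309
#>   Bray-Curtis common_formulae  max 0.192
#>   Bray-Curtis fragments        max 0.035
```

Reading the output: the three samples share 192 molecular formulas, and
their *formula-level* compositions differ substantially (Bray–Curtis up to
31% over all formulas, 19% over the common ones — the samples carry the
same molecules at different abundances). The *structural* level tells the
opposite story: regression slopes of relative fragment intensities sit
within ~2% of the identity line and the fragment-level Bray–Curtis is 3.5%,
at the analytical noise floor. That contrast — large compositional
dissimilarity, vanishing structural dissimilarity — is the signature of a
universal structural background. Raising the generator's
`profile_divergence` above 0 destroys it, and `autoplot()` on the
regression and dissimilarity objects draws the corresponding figures.

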