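#' Exact masses of neutral molecules and deprotonated ions
#'
#' `neutral_mass()` sums monoisotopic atomic masses over the element counts of
#' a formula, adding the isotope mass differences for any thirteen-C or
#' fifteen-N substitutions. `ion_mass()` gives the m/z of the singly charged
#' deprotonated ion \eqn{[M-H]^-}, the species under which DOM molecules are
#' detected in negative-mode electrospray.
#'
#' By default the deprotonated ion mass is `neutral_mass - proton mass`
#' (1.00727646 Da), i.e. the electron gained by the anion is folded into the
#' proton-removal step. Setting `electron_correction = TRUE` uses the explicit
#' convention `neutral - H_atom + electron`, which is numerically identical;
#' the flag exists so the convention in use is always explicit in output
#' headers (the 0.00055 Da electron mass matters at sub-ppm accuracy).
#'
#' @param f Formulas: strings or a counts table (see [as_formula()]).
#' @param electron_correction Use the `neutral - 1.00782503 + m_e` form.
#' @return Numeric vector of masses in Da.
#' @examples
#' neutral_mass(c("CO2", "H2O"))  # 43.98983, 18.01056
#' ion_mass("C18H22O8")           # 365.12419
#' @export
neutral_mass <- function(f) {
  f <- as_formula(f)
  m <- dom_masses()
  f$c * m$C + f$h * m$H + f$n * m$N + f$o * m$O + f$s * m$S + f$p * m$P +
    f$c13 * m$d13C + f$n15 * m$d15N
}

#' @rdname neutral_mass
#' @export
ion_mass <- function(f, electron_correction = FALSE) {
  f <- as_formula(f)
  if (any(f$h < 1L)) {
    abort("cannot form [M-H]- ion: formula has no hydrogen to abstract")
  }
  m <- dom_masses()
  if (electron_correction) {
    neutral_mass(f) - m$H + m$electron
  } else {
    neutral_mass(f) - m$proton
  }
}

#' Double-bond equivalents
#'
#' Rings-plus-double-bonds of the neutral molecule,
#' `DBE = 1 + C - H/2 + N/2 + P/2`, with nitrogen and phosphorus counted as
#' trivalent (the usual convention for negative-mode DOM work). May be
#' negative for impossible compositions; callers decide plausibility.
#'
#' @inheritParams neutral_mass
#' @param n_valence,p_valence Valences used for N and P (default 3). DBE is
#'   computed as `1 + c - h/2 + (v_N - 2) n/2 + (v_P - 2) p/2`.
#' @return Numeric vector (unitless; integer-valued for chemically valid
#'   even-electron compositions).
#' @examples
#' dbe("C6H6")  # 4
#' @export
dbe <- function(f, n_valence = 3, p_valence = 3) {
  f <- as_formula(f)
  1 + f$c - f$h / 2 + (n_valence - 2) * f$n / 2 + (p_valence - 2) * f$p / 2
}

#' Modified aromaticity index
#'
#' Formula-level aromaticity score in which half the oxygen and half the
#' combined N, P and H are treated as non-contributing to the pi system:
#' \deqn{AI_{mod} = \frac{1 + C - 0.5\,O - S - 0.5\,(N + P + H)}
#'                       {C - 0.5\,O - S - N - P}.}
#' When the denominator or the numerator is not positive the index is defined
#' as 0, which prevents oxygen-rich aliphatic compositions from receiving
#' spurious aromatic scores. Thresholds at 0.5 and 0.666 separate
#' polyphenol-like and condensed-aromatic compositions (see
#' [classify_formula()]).
#'
#' @inheritParams neutral_mass
#' @return Numeric vector in `[0, ...)`, 0 for degenerate compositions.
#' @examples
#' ai_mod("C6H6")  # 0.667
#' @export
ai_mod <- function(f) {
  f <- as_formula(f)
  num <- 1 + f$c - 0.5 * f$o - f$s - 0.5 * (f$n + f$p + f$h)
  den <- f$c - 0.5 * f$o - f$s - f$n - f$p
  out <- ifelse(den <= 0 | num <= 0, 0, num / den)
  out
}

#' Compound-class labels for molecular formulas
#'
#' Assigns each formula to exactly one of six mutually exclusive molecular
#' categories used to map DOM composition, based on the modified aromaticity
#' index and the H/C and O/C ratios:
#'
#' * `black_carbon` — combustion-derived polycyclic aromatics:
#'   `AI_mod >= 0.666`, no N, S or P;
#' * `polyphenol_o_rich` — `0.5 <= AI_mod < 0.666` and `O/C > 0.5`;
#' * `polyphenol_o_poor` — `0.5 <= AI_mod < 0.666` and `O/C <= 0.5`;
#' * `highly_unsaturated` — `AI_mod < 0.5`, `H/C < 1.5`, `O/C < 0.9`;
#' * `aliphatic` — `1.5 <= H/C <= 2.0`, `O/C < 0.9`, no N;
#' * `other` — anything else.
#'
#' Rules are applied in this order; the first match wins, so condensed
#' aromatics with heteroatoms fall through to the polyphenol or unsaturated
#' classes rather than `black_carbon`.
#'
#' @inheritParams neutral_mass
#' @return Factor vector with the six class levels.
#' @examples
#' classify_formula(c("C9H6O6", "C18H22O8", "C18H30O6"))
#' @export
classify_formula <- function(f) {
  f <- as_formula(f)
  if (any(f$c < 1L)) abort("classification requires at least one carbon")
  ai <- ai_mod(f)
  hc <- f$h / f$c
  oc <- f$o / f$c
  lab <- case_when(
    ai >= 0.666 & f$n == 0L & f$s == 0L & f$p == 0L ~ "black_carbon",
    ai >= 0.5 & ai < 0.666 & oc > 0.5 ~ "polyphenol_o_rich",
    ai >= 0.5 & ai < 0.666 & oc <= 0.5 ~ "polyphenol_o_poor",
    ai < 0.5 & hc < 1.5 & oc < 0.9 ~ "highly_unsaturated",
    hc >= 1.5 & hc <= 2.0 & oc < 0.9 & f$n == 0L ~ "aliphatic",
    .default = "other"
  )
  factor(lab, levels = dom_classes())
}

#' @rdname classify_formula
#' @export
dom_classes <- function() {
  c("black_carbon", "polyphenol_o_rich", "polyphenol_o_poor",
    "highly_unsaturated", "aliphatic", "other")
}
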