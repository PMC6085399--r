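#' Carboxyl-group count from a fragmentation pattern
#'
#' The intensity-weighted mean decarboxylation multiplicity of a precursor's
#' major signals: each signal carries the CO2 multiplicity `k` of its neutral
#' loss (the precursor and pure H2O/CH3OH losses have `k = 0`; combined
#' losses count only their CO2 content), and
#' `c_frag = sum(k * I_k) / sum(I_k)` over all major signals including the
#' precursor. The estimate is invariant to uniform intensity scaling and
#' bounded by the largest CO2 multiplicity in the loss table (3).
#'
#' @param rel Relative-intensity table (one or more samples/precursors).
#' @param losses Loss table supplying the `n_co2` weights.
#' @return Tibble `sample_id` (if present), `precursor_formula`, `c_frag`.
#' @examples
#' rel <- tibble::tibble(
#'   precursor_formula = "C18H22O8",
#'   loss_label = c("precursor", "CO2", "2CO2"),
#'   rel_intensity = c(0.5, 0.25, 0.25)
#' )
#' carboxyl_from_fragments(rel)  # c_frag = 0.75
#' @export
carboxyl_from_fragments <- function(rel, losses = neutral_loss_table()) {
  stopifnot(all(c("precursor_formula", "loss_label", "rel_intensity") %in%
                  names(rel)))
  w <- setNames(losses$n_co2, losses$label)
  w <- c(w, precursor = 0L)
  df <- rel[rel$loss_label %in% names(w), , drop = FALSE]
  has_sample <- "sample_id" %in% names(df)
  if (!has_sample) df$sample_id <- ""
  out <- df %>%
    group_by(.data$sample_id, .data$precursor_formula) %>%
    summarise(
      total = sum(.data$rel_intensity),
      c_frag = sum(w[.data$loss_label] * .data$rel_intensity),
      .groups = "drop"
    )
  if (any(out$total <= 0)) {
    abort("all intensities are zero for at least one precursor")
  }
  out$c_frag <- out$c_frag / out$total
  out$total <- NULL
  if (!has_sample) out$sample_id <- NULL
  out
}

#' Carboxyl-group count from formula composition alone
#'
#' A structure-free estimate of the carboxyl number from the elemental
#' composition: the default model is linear in the oxygen count and the
#' double-bond equivalents, `c_formula = a * O + b * DBE + c0`, truncated at
#' zero and capped at `floor(O / 2)` — a carboxyl group contains two oxygen
#' atoms, so the composition bounds the count regardless of the fitted
#' coefficients. The functional form is deliberately simple and pluggable: its
#' coefficients should be calibrated against known structures (or, for
#' synthetic data, against generator ground truth via
#' [fit_carboxyl_model()]); the model in force is recorded in the returned
#' attribute and printed by downstream reports.
#'
#' @param f Formulas (strings or counts table).
#' @param a,b,c0 Model coefficients (defaults `a = 0.5, b = 0, c0 = 0`).
#' @return Numeric vector of carboxyl estimates (>= 0), with the model
#'   parameters attached as attribute `model`.
#' @export
carboxyl_from_formula <- function(f, a = 0.5, b = 0, c0 = 0) {
  f <- as_formula(f)
  est <- pmin(pmax(0, a * f$o + b * dbe(f) + c0), f$o %/% 2L)
  attr(est, "model") <- c(a = a, b = b, c0 = c0)
  est
}

#' @rdname carboxyl_from_formula
#' @param formulas Character vector of formulas with known carboxyl counts.
#' @param counts Known (mean) carboxyl counts, aligned with `formulas`.
#' @return `fit_carboxyl_model()`: a named vector `c(a, b, c0)` from an
#'   ordinary least-squares fit of `counts ~ O + DBE`, with the residual
#'   RMSE as attribute `rmse`.
#' @export
fit_carboxyl_model <- function(formulas, counts) {
  f <- as_formula(formulas)
  stopifnot(length(counts) == nrow(f))
  fit <- lm(counts ~ o + d, data = data.frame(counts = counts, o = f$o,
                                              d = dbe(f)))
  out <- c(a = unname(coef(fit)["o"]), b = unname(coef(fit)["d"]),
           c0 = unname(coef(fit)["(Intercept)"]))
  attr(out, "rmse") <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' Isomeric-diversity index
#'
#' Pearson correlation between the fragmentation-based ([
#' carboxyl_from_fragments()]) and the composition-based
#' ([carboxyl_from_formula()]) carboxyl estimates across formulas. Each
#' detected formula signal averages over all isomers behind it, so with more
#' isomers per formula the idiosyncrasies of individual structures average
#' out and the two independent estimates agree better: the correlation rises
#' with isomeric richness and serves as a relative diversity index between
#' samples.
#'
#' @param estimates Tibble with columns `c_frag` and `c_formula` (one row
#'   per formula; see [carboxyl_estimates()]).
#' @return Scalar Pearson correlation.
#' @export
diversity_index <- function(estimates) {
  stopifnot(all(c("c_frag", "c_formula") %in% names(estimates)))
  if (nrow(estimates) < 10) {
    abort("diversity_index() needs estimates for at least 10 formulas")
  }
  if (sd(estimates$c_frag) == 0 || sd(estimates$c_formula) == 0) {
    abort("zero variance in a carboxyl estimate; correlation undefined")
  }
  cor(estimates$c_frag, estimates$c_formula)
}

#' Per-formula carboxyl estimate pairs
#'
#' Convenience constructor joining the two independent carboxyl estimates
#' for every (sample, precursor formula) with relative fragment intensities.
#'
#' @param rel Relative-intensity table.
#' @param model Coefficients for the composition model (named vector
#'   `c(a, b, c0)`).
#' @param losses Loss table.
#' @return Tibble `sample_id` (if present), `precursor_formula`, `c_frag`,
#'   `c_formula`, `residual` (`c_frag - c_formula`).
#' @export
carboxyl_estimates <- function(rel, model = c(a = 0.5, b = 0, c0 = 0),
                               losses = neutral_loss_table()) {
  est <- carboxyl_from_fragments(rel, losses)
  est$c_formula <- as.numeric(carboxyl_from_formula(
    est$precursor_formula, a = model[["a"]], b = model[["b"]],
    c0 = model[["c0"]]
  ))
  est$residual <- est$c_frag - est$c_formula
  est
}

#' Minimum number of isomers behind a formula
#'
#' Central-limit reasoning turns the *agreement* of the two carboxyl
#' estimates into a lower bound on isomer multiplicity: if a single isomer's
#' carboxyl count scatters around the compositional expectation with
#' standard deviation `sigma_single`, the detected signal of a formula
#' averaging `n` independent isomers scatters with `sigma_single / sqrt(n)`.
#' Hence `n_min = ceiling((sigma_single / sigma_residual)^2)`, where
#' `sigma_residual` is the standard deviation of the observed
#' `c_frag - c_formula` residuals across formulas. Because measurement noise
#' inflates `sigma_residual`, the bound is conservative (a minimum, not an
#' estimate).
#'
#' @param estimates Estimate table (see [carboxyl_estimates()]).
#' @param sigma_single Per-isomer carboxyl standard deviation. Known for
#'   synthetic data from the generator configuration; must be supplied by
#'   the user for real data.
#' @param cap Value returned (with a warning) when the residuals have zero
#'   variance.
#' @return Integer `n_min >= 1`.
#' @export
min_isomers <- function(estimates, sigma_single, cap = 1e6) {
  stopifnot(is.numeric(sigma_single), sigma_single > 0)
  resid <- estimates$c_frag - estimates$c_formula
  s <- sd(resid)
  if (!is.finite(s) || s == 0) {
    warn("zero residual dispersion; returning the configured cap")
    return(as.integer(cap))
  }
  max(1L, as.integer(ceiling((sigma_single / s)^2)))
}

#' Minimum number of distinct compounds
#'
#' Scales the per-formula minimum isomer number by the count of molecular
#' formulas common to the compared samples, giving a lower bound on the
#' number of distinct compounds in the shared molecular background.
#'
#' @param n_min_isomers Minimum isomers per formula (>= 1).
#' @param n_common Number of common formulas (>= 1).
#' @return `n_min_isomers * n_common`.
#' @examples
#' min_compounds(10, 2531)  # 25310
#' @export
min_compounds <- function(n_min_isomers, n_common) {
  stopifnot(n_min_isomers >= 1)
  if (n_common < 1) abort("need at least one common formula")
  as.numeric(n_min_isomers) * as.numeric(n_common)
}

#' Per-sample diversity summary
#'
#' Runs the full isomer-diversity chain for each sample in a
#' relative-intensity table: carboxyl estimate pairs, their correlation
#' (diversity index), the minimum isomer number, and the minimum compound
#' number given `n_common` common formulas.
#'
#' @inheritParams carboxyl_estimates
#' @inheritParams min_isomers
#' @param n_common Number of common formulas used to scale to compound
#'   numbers.
#' @return Tibble: `sample_id`, `n_formulae`, `r_estimates`,
#'   `sigma_residual`, `n_min_isomers`, `n_min_compounds`.
#' @export
estimate_diversity <- function(rel, sigma_single, n_common,
                               model = c(a = 0.5, b = 0, c0 = 0),
                               losses = neutral_loss_table()) {
  est <- carboxyl_estimates(rel, model = model, losses = losses)
  if (!"sample_id" %in% names(est)) est$sample_id <- ""
  purrr::map_dfr(split(est, est$sample_id), function(d) {
    nmi <- min_isomers(d, sigma_single)
    tibble(
      sample_id = d$sample_id[1],
      n_formulae = nrow(d),
      r_estimates = diversity_index(d),
      sigma_residual = sd(d$residual),
      n_min_isomers = nmi,
      n_min_compounds = min_compounds(nmi, n_common)
    )
  })
}
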