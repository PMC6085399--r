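#' Internal mass calibration against a reference list
#'
#' Matches known reference masses to peaks, fits a systematic mass-error model
#' that is linear in m/z on the ppm scale,
#' `ppm(mz) = a + b * mz`, and applies the inverse correction
#' `mz_cal = mz / (1 + ppm(mz) * 1e-6)` to every peak. This is the standard
#' internal-calibration step for FT-ICR spectra, here applied to centroided
#' peak lists.
#'
#' At least three matched references are required. The fit order is
#' configurable: `order = 0` fits a constant ppm offset, `order = 1` (default)
#' adds the slope term. Calibration quality is judged by the maximum absolute
#' residual ppm error over the matched references; a spectrum whose residual
#' exceeds `max_ppm` is flagged as failed (`passed = FALSE`) but still
#' returned, so callers choose whether to abort.
#'
#' @param pl A single-sample peak list.
#' @param reference_masses Numeric vector of exact reference m/z values (Da).
#' @param match_tol_ppm Search tolerance for pairing references with peaks
#'   (ppm, default 1); must be wider than the expected post-calibration error
#'   and narrower than the local peak spacing.
#' @param max_ppm Acceptance threshold on the residual max |ppm| (default
#'   0.06).
#' @param order 0 (offset only) or 1 (offset + slope in m/z).
#' @return A list with elements `peaks` (the corrected peak list) and
#'   `calibration`, an object of class `dom_calibration` with [tidy()] (one
#'   row per matched reference: reference mass, matched m/z, raw and residual
#'   ppm error) and [glance()] (offset, slope, n matched, max residual |ppm|,
#'   `passed`) methods.
#' @examples
#' refs <- ion_mass(c("C15H22O8", "C18H22O8", "C20H26O9"))
#' pl <- peaklist(tibble::tibble(
#'   mz = refs * (1 + 0.3e-6), intensity = rep(1, 3), snr = rep(100, 3)
#' ))
#' internal_calibrate(pl, refs)$calibration
#' @export
internal_calibrate <- function(pl, reference_masses, match_tol_ppm = 1,
                               max_ppm = 0.06, order = 1) {
  pl <- peaklist(pl)
  stopifnot(is.numeric(reference_masses), length(reference_masses) > 0)
  if ("sample_id" %in% names(pl) && length(unique(pl$sample_id)) > 1) {
    abort("internal_calibrate() works on one sample at a time")
  }
  refs <- sort(unique(reference_masses))
  idx <- vapply(refs, function(r) {
    j <- which.min(abs(pl$mz - r))
    if (length(j) == 0) return(NA_integer_)
    if (abs(pl$mz[j] - r) / r * 1e6 <= match_tol_ppm) j else NA_integer_
  }, integer(1))
  matched <- !is.na(idx)
  if (sum(matched) < 3) {
    abort(sprintf(
      "calibration failed: only %d of %d reference masses matched within %g ppm (need >= 3)",
      sum(matched), length(refs), match_tol_ppm
    ))
  }
  ref <- refs[matched]
  obs <- pl$mz[idx[matched]]
  ppm_err <- (obs - ref) / ref * 1e6
  fit <- if (order >= 1) lm(ppm_err ~ ref) else lm(ppm_err ~ 1)
  cf <- coef(fit)
  if (any(!is.finite(cf))) abort("calibration fit did not converge")
  a <- unname(cf[1])
  b <- if (order >= 1) unname(cf[2]) else 0
  correct <- function(mz) mz / (1 + (a + b * mz) * 1e-6)
  out <- pl
  out$mz <- correct(pl$mz)
  resid_ppm <- (correct(obs) - ref) / ref * 1e6
  cal <- structure(
    list(
      offset_ppm = a, slope_ppm_per_da = b, order = order,
      n_matched = length(ref), n_reference = length(refs),
      reference = tibble(
        reference_mz = ref, matched_mz = obs,
        raw_ppm = ppm_err, residual_ppm = resid_ppm
      ),
      max_abs_ppm = max(abs(resid_ppm)),
      max_ppm_threshold = max_ppm,
      passed = max(abs(resid_ppm)) <= max_ppm
    ),
    class = "dom_calibration"
  )
  list(peaks = out, calibration = cal)
}

#' @export
print.dom_calibration <- function(x, ...) {
  cat(sprintf(
    "<dom_calibration> %d/%d references matched; offset %.4f ppm, slope %.2e ppm/Da\n  residual max |ppm| = %.4f (threshold %.3g) -> %s\n",
    x$n_matched, x$n_reference, x$offset_ppm, x$slope_ppm_per_da,
    x$max_abs_ppm, x$max_ppm_threshold, if (x$passed) "PASS" else "FLAGGED"
  ))
  invisible(x)
}

#' @export
tidy.dom_calibration <- function(x, ...) x$reference

#' @export
glance.dom_calibration <- function(x, ...) {
  tibble(
    offset_ppm = x$offset_ppm, slope_ppm_per_da = x$slope_ppm_per_da,
    order = x$order, n_matched = x$n_matched,
    max_abs_ppm = x$max_abs_ppm, passed = x$passed
  )
}

#' Default reference masses for DOM internal calibration
#'
#' A reference list built from abundant CH2 homologous series of typical DOM
#' compositions (CHO only, even-electron \eqn{[M-H]^-} ions), spanning the
#' requested mass range. Real studies use instrument-specific lists; this
#' default exists so the calibration machinery is usable out of the box on
#' synthetic spectra.
#'
#' @param mass_min,mass_max Mass range to cover (Da).
#' @return Sorted numeric vector of reference m/z values.
#' @export
default_reference_masses <- function(mass_min = 150, mass_max = 800) {
  # three CH2 series anchored on common DOM cores
  seeds <- c("C8H8O5", "C10H12O6", "C13H16O8")
  out <- unlist(lapply(seeds, function(s) {
    f <- as_formula(s)
    k <- 0:40
    tbl <- tibble(
      c = f$c + k, h = f$h + 2L * k, n = 0L, o = f$o,
      s = 0L, p = 0L, c13 = 0L, n15 = 0L
    )
    ion_mass(tbl)
  }))
  sort(out[out >= mass_min & out <= mass_max])
}
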