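# Independent brute-force oracles. These deliberately share no code with the
# package internals: masses are restated, loops are explicit, and hydrogen is
# probed over a range instead of being solved in closed form.

ORACLE_MASS <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163
)
ORACLE_PROTON <- 1.007276466621

# every composition in the constraint box whose [M-H]- mass is within
# tol_ppm of mz; returns a sorted vector of "c/h/n/o/s/p" keys
oracle_enumerate <- function(mz, tol_ppm) {
  M <- mz + ORACLE_PROTON
  out <- character()
  for (c_ in 1:min(60, floor(M / ORACLE_MASS["C"]))) {
    for (n_ in 0:4) {
      for (s_ in 0:2) {
        for (p_ in 0:1) {
          base <- c_ * ORACLE_MASS["C"] + n_ * ORACLE_MASS["N"] +
            s_ * ORACLE_MASS["S"] + p_ * ORACLE_MASS["P"]
          if (base > M) next
          o_max <- min(c_, floor((M - base) / ORACLE_MASS["O"]))
          for (o_ in 0:o_max) {
            rem <- M - base - o_ * ORACLE_MASS["O"]
            h_guess <- rem / ORACLE_MASS["H"]
            for (h_ in unique(c(floor(h_guess), ceiling(h_guess)))) {
              if (h_ < 1) next
              if (h_ < 0.3 * c_) next
              if (h_ > 2 * c_ + n_ + p_ + 2) next
              dbe_ <- 1 + c_ - h_ / 2 + n_ / 2 + p_ / 2
              if (dbe_ < 0 || abs(dbe_ - round(dbe_)) > 1e-9) next
              ion <- base + o_ * ORACLE_MASS["O"] + h_ * ORACLE_MASS["H"] -
                ORACLE_PROTON
              if (abs(ion - mz) / mz * 1e6 <= tol_ppm) {
                out <- c(out, paste(c_, h_, n_, o_, s_, p_, sep = "/"))
              }
            }
          }
        }
      }
    }
  }
  sort(unique(out))
}

candidate_keys <- function(cand) {
  sort(paste(cand$c, cand$h, cand$n, cand$o, cand$s, cand$p, sep = "/"))
}

oracle_bray_curtis <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# assignment table built straight from generator truth (bypasses the
# assignment stage when a test targets downstream statistics only)
truth_assigned <- function(fullrange) {
  tr <- fullrange$truth
  ab <- tr$abundance[tr$abundance$present, ]
  idx <- match(ab$formula, tr$formulas$formula)
  tibble::tibble(
    sample_id = ab$sample_id,
    mz = tr$formulas$ion_mz[idx],
    intensity = ab$base_intensity,
    snr = ab$base_intensity / tr$config$noise_floor,
    formula = ab$formula,
    error_ppm = 0,
    is_isotopologue = FALSE
  )
}

# relative intensities for a set of windows, straight from generator output
windows_rel <- function(fullrange, assigned, windows, run = 1) {
  purrr::map_dfr(windows, function(w) {
    fg <- generate_fragmentation(fullrange, w, run = run)
    prec <- window_precursors(assigned, w)
    suppressWarnings(
      relative_intensities(attribute_fragments(fg$peaks, prec))
    )
  })
}
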