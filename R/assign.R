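#' Elemental constraints for formula assignment
#'
#' The constraint box inside which candidate formulas are enumerated for
#' singly charged \eqn{[M-H]^-} ions: element ranges C 0–60, N 0–4, S 0–2,
#' P 0–1, hydrogen bounded only through chemistry (`h <= 2c + n + p + 2`,
#' i.e. DBE >= 0), O/C <= 1 and H/C >= 0.3. Candidates must additionally have
#' integer, non-negative DBE (which excludes nitrogen-rule violations for
#' even-electron ions).
#'
#' @param c_max,n_max,s_max,p_max Upper element counts.
#' @param oc_max Maximum O/C ratio.
#' @param hc_min Minimum H/C ratio.
#' @param tol_ppm Assignment tolerance (ppm) on the ion m/z.
#' @param mass_min,mass_max Accepted ion m/z window (Da).
#' @return A `dom_constraints` list, including a pre-computed heteroatom grid
#'   reused across peaks.
#' @export
assignment_constraints <- function(c_max = 60, n_max = 4, s_max = 2,
                                   p_max = 1, oc_max = 1, hc_min = 0.3,
                                   tol_ppm = 0.5,
                                   mass_min = 150, mass_max = 2000) {
  stopifnot(c_max >= 1, n_max >= 0, s_max >= 0, p_max >= 0,
            oc_max > 0, hc_min >= 0, tol_ppm > 0, mass_min < mass_max)
  m <- dom_masses()
  grid <- expand.grid(
    c = seq_len(c_max), n = 0:n_max, o = 0:floor(oc_max * c_max),
    s = 0:s_max, p = 0:p_max, KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[grid$o <= oc_max * grid$c, , drop = FALSE]
  grid$base <- grid$c * m$C + grid$n * m$N + grid$o * m$O +
    grid$s * m$S + grid$p * m$P
  structure(
    list(
      c_max = c_max, n_max = n_max, s_max = s_max, p_max = p_max,
      oc_max = oc_max, hc_min = hc_min, tol_ppm = tol_ppm,
      mass_min = mass_min, mass_max = mass_max,
      grid = as_tibble(grid)
    ),
    class = "dom_constraints"
  )
}

#' @export
print.dom_constraints <- function(x, ...) {
  cat(sprintf(
    "<dom_constraints> C1-%d N0-%d S0-%d P0-%d, O/C <= %g, H/C >= %g, tol %g ppm, m/z %g-%g\n",
    x$c_max, x$n_max, x$s_max, x$p_max, x$oc_max, x$hc_min, x$tol_ppm,
    x$mass_min, x$mass_max
  ))
  invisible(x)
}

#' Enumerate candidate formulas for one measured m/z
#'
#' Every elemental composition inside the constraint box whose \eqn{[M-H]^-}
#' ion mass lies within `tol_ppm` of the measured m/z. For each heteroatom
#' combination `(c, n, o, s, p)` the hydrogen count is solved directly from
#' the residual mass (at sub-ppm tolerances at most one integer H count can
#' match), then ratio, DBE-integrality and DBE >= 0 filters are applied.
#'
#' @param mz Measured ion m/z (Da, scalar).
#' @param constraints A [assignment_constraints()] object.
#' @param tol_ppm Override of the constraint tolerance.
#' @return Tibble with columns `formula`, `c,h,n,o,s,p`, `ion_mz`,
#'   `error_ppm`, sorted by `abs(error_ppm)`; zero rows when nothing matches.
#' @examples
#' enumerate_candidates(365.12419, assignment_constraints())
#' @export
enumerate_candidates <- function(mz, constraints = assignment_constraints(),
                                 tol_ppm = constraints$tol_ppm) {
  stopifnot(is.numeric(mz), length(mz) == 1, mz > 0)
  if (mz < constraints$mass_min || mz > constraints$mass_max) {
    abort(sprintf("m/z %g outside the configured window %g-%g Da",
                  mz, constraints$mass_min, constraints$mass_max))
  }
  m <- dom_masses()
  M <- mz + m$proton           # neutral monoisotopic mass
  g <- constraints$grid
  g <- g[g$base <= M, , drop = FALSE]
  h <- round((M - g$base) / m$H)
  keep <- h >= 1 & h >= constraints$hc_min * g$c & h <= 2 * g$c + g$n + g$p + 2
  g <- g[keep, , drop = FALSE]
  h <- h[keep]
  dbe_val <- 1 + g$c - h / 2 + g$n / 2 + g$p / 2
  keep <- dbe_val >= 0 & abs(dbe_val - round(dbe_val)) < 1e-9
  g <- g[keep, , drop = FALSE]
  h <- h[keep]
  ion <- g$base + h * m$H - m$proton
  err <- (ion - mz) / mz * 1e6
  keep <- abs(err) <= tol_ppm
  g <- g[keep, , drop = FALSE]
  out <- tibble(
    c = as.integer(g$c), h = as.integer(h[keep]), n = as.integer(g$n),
    o = as.integer(g$o), s = as.integer(g$s), p = as.integer(g$p),
    c13 = 0L, n15 = 0L,
    ion_mz = ion[keep], error_ppm = err[keep]
  )
  out$formula <- format_formula(out)
  out <- out[order(abs(out$error_ppm), out$formula), , drop = FALSE]
  select(out, "formula", all_of(c("c", "h", "n", "o", "s", "p")),
         "ion_mz", "error_ppm")
}

# deterministic tie-break among in-tolerance candidates. Candidates whose
# |error_ppm| lies within `tie_ppm` of the best are indistinguishable at the
# instrument's mass accuracy (random jitter routinely reorders them), so raw
# ppm distance must not decide between them; within such a tie set the
# ladder is: (1) fewest heteroatoms N+S+P (composition parsimony, the
# standard resolution of sub-ppm mass splits such as the 0.163 mDa
# C5H-5O6/N4PS2 exchange), (2) best-matching 13C1 companion intensity when
# a companion peak is present, (3) smallest |error_ppm|, (4) formula string.
.pick_candidate <- function(cand, companion_ratio, tie_ppm) {
  m <- dom_masses()
  appm <- abs(cand$error_ppm)
  tied <- appm - min(appm) <= tie_ppm
  cand <- cand[tied, , drop = FALSE]
  appm <- appm[tied]
  het <- cand$n + cand$s + cand$p
  iso_score <- if (is.na(companion_ratio)) {
    rep(0, nrow(cand))
  } else {
    expected <- cand$c * m$abundance_13C / (1 - m$abundance_13C)
    round(abs(log(companion_ratio / expected)), 2)
  }
  ord <- order(het, iso_score, appm, cand$formula)
  cand[ord[1], , drop = FALSE]
}

#' Assign molecular formulas to a calibrated peak list
#'
#' Runs [enumerate_candidates()] on every peak of an S/N-filtered, internally
#' calibrated full-range peak list and keeps the best candidate under a
#' deterministic tie-break ladder. Candidates whose absolute ppm errors
#' differ by less than `tie_ppm` are treated as indistinguishable at the
#' instrument's mass accuracy; within that tie set the winner has the fewest
#' heteroatoms (N+S+P), then — when a putative thirteen-C1 companion peak is
#' present 1.0033548 Da above the peak — the candidate whose carbon number
#' best explains the companion's intensity, then the smallest ppm error,
#' then the formula string. Peaks outside the mass window or with no
#' in-tolerance candidate stay unassigned (`formula = NA`).
#'
#' @param pl Peak list (single- or multi-sample; assignment is per peak and
#'   independent of sample structure).
#' @param constraints [assignment_constraints()].
#' @param tol_ppm Tolerance override (ppm).
#' @param tie_ppm Width of the ppm tie band within which composition
#'   parsimony outranks raw mass distance (default: the tolerance itself).
#' @return The peak list with columns `formula`, `error_ppm`,
#'   `compound_class`, `n_candidates`, `is_isotopologue` (FALSE here; see
#'   [verify_isotopologues()]) and `parent_formula` (NA here).
#' @export
assign_formulas <- function(pl, constraints = assignment_constraints(),
                            tol_ppm = constraints$tol_ppm,
                            tie_ppm = tol_ppm) {
  pl <- peaklist(pl)
  m <- dom_masses()
  n <- nrow(pl)
  formula <- rep(NA_character_, n)
  error_ppm <- rep(NA_real_, n)
  n_candidates <- integer(n)
  grp <- if ("sample_id" %in% names(pl)) pl$sample_id else rep("", n)
  for (i in seq_len(n)) {
    mz <- pl$mz[i]
    if (mz < constraints$mass_min || mz > constraints$mass_max) next
    cand <- enumerate_candidates(mz, constraints, tol_ppm)
    n_candidates[i] <- nrow(cand)
    if (nrow(cand) == 0) next
    # look for a 13C1 companion within the same sample for tie-breaking
    companion_ratio <- NA_real_
    iso_mz <- mz + m$d13C
    j <- which(grp == grp[i] & abs(pl$mz - iso_mz) / iso_mz * 1e6 <= tol_ppm)
    if (length(j) > 0 && pl$intensity[i] > 0) {
      companion_ratio <- pl$intensity[j[which.min(abs(pl$mz[j] - iso_mz))]] /
        pl$intensity[i]
    }
    best <- .pick_candidate(cand, companion_ratio, tie_ppm)
    formula[i] <- best$formula
    error_ppm[i] <- best$error_ppm
  }
  out <- pl
  out$formula <- formula
  out$error_ppm <- error_ppm
  out$compound_class <- factor(NA_character_, levels = dom_classes())
  ok <- !is.na(formula)
  if (any(ok)) out$compound_class[ok] <- classify_formula(formula[ok])
  out$n_candidates <- n_candidates
  out$is_isotopologue <- FALSE
  out$parent_formula <- NA_character_
  out
}

#' Flag isotopologue peaks against assigned parents
#'
#' Scans an assignment table for peaks sitting one thirteen-C–twelve-C
#' (1.0033548 Da) or one fifteen-N–fourteen-N (0.9970349 Da) mass difference
#' above an assigned monoisotopic parent in the same sample. The expected
#' isotopologue m/z is computed from the parent's *theoretical* ion mass
#' plus the isotope spacing; peaks matching within `tol_ppm` are flagged as
#' isotopologues and inherit the parent formula with one isotope
#' substitution. Unassigned peaks are always candidates; a peak that already
#' carries a monoisotopic assignment is reclaimed as an isotopologue when
#' the isotope explanation fits its mass strictly better than the
#' assignment does (heteroatom-rich compositions frequently shadow
#' thirteen-C1 peaks within tolerance). A candidate thirteen-C1 peak must
#' also be plausible in intensity: the expected ratio to the parent is
#' `c * 0.0107 / (1 - 0.0107)`; peaks further than a factor
#' `intensity_factor` from that are left unflagged with a warning.
#'
#' @param assigned Output of [assign_formulas()].
#' @param tol_ppm Match tolerance (ppm).
#' @param intensity_factor Allowed multiplicative deviation from the binomial
#'   isotope-abundance expectation (default 3).
#' @return The table with `is_isotopologue`, `parent_formula`, `formula`
#'   updated for flagged peaks.
#' @export
verify_isotopologues <- function(assigned, tol_ppm = 0.5,
                                 intensity_factor = 3) {
  stopifnot(all(c("mz", "intensity", "formula", "is_isotopologue") %in%
                  names(assigned)))
  m <- dom_masses()
  out <- assigned
  grp <- if ("sample_id" %in% names(out)) out$sample_id else rep("", nrow(out))
  for (s in unique(grp)) {
    rows <- which(grp == s)
    parents <- rows[!is.na(out$formula[rows]) & !out$is_isotopologue[rows]]
    if (length(parents) == 0) next
    pf <- as_formula(out$formula[parents])
    parent_exact <- ion_mass(pf)
    open <- rows[is.na(out$formula[rows])]
    # assigned peaks stay candidates: an isotope spacing that explains the
    # mass better than the assignment overrides it
    for (i in c(open, parents)) {
      own_ppm <- if (is.na(out$formula[i])) Inf else abs(out$error_ppm[i])
      for (iso in c("c13", "n15")) {
        delta <- if (iso == "c13") m$d13C else m$d15N
        elig <- if (iso == "c13") pf$c >= 1L else pf$n >= 1L
        expect_mz <- parent_exact + delta
        ppm <- abs(out$mz[i] - expect_mz) / expect_mz * 1e6
        hits <- which(elig & ppm <= tol_ppm & ppm < own_ppm &
                        parents != i)
        if (length(hits) == 0) next
        hit <- hits[which.min(ppm[hits])]
        if (iso == "c13") {
          expected_ratio <- pf$c[hit] * m$abundance_13C / (1 - m$abundance_13C)
          obs_ratio <- out$intensity[i] / out$intensity[parents[hit]]
          if (obs_ratio > expected_ratio * intensity_factor ||
              obs_ratio < expected_ratio / intensity_factor) {
            warn(sprintf(
              "peak at m/z %.5f matches a 13C1 spacing of %s but its intensity ratio %.3g is outside %g-fold of the expected %.3g; not flagged",
              out$mz[i], out$formula[parents[hit]], obs_ratio,
              intensity_factor, expected_ratio
            ))
            next
          }
        }
        isof <- as_formula(out$formula[parents[hit]])
        isof[[iso]] <- isof[[iso]] + 1L
        out$formula[i] <- format_formula(isof)
        out$is_isotopologue[i] <- TRUE
        out$parent_formula[i] <- format_formula(pf[hit, ])
        out$error_ppm[i] <- (out$mz[i] - expect_mz[hit]) / expect_mz[hit] * 1e6
        break
      }
    }
  }
  out
}

#' Formulas common to all samples
#'
#' The intersection of assigned monoisotopic formula sets across samples,
#' with each sample's share: the percentage of its own formulas that belong
#' to the intersection.
#'
#' @param assigned Multi-sample assignment table (needs `sample_id`,
#'   `formula`, `is_isotopologue`).
#' @return List with `formulas` (character vector, sorted) and `shares`
#'   (tibble: `sample_id`, `n_formulae`, `n_common`, `share_pct`).
#' @export
common_formulae <- function(assigned) {
  stopifnot(all(c("sample_id", "formula") %in% names(assigned)))
  df <- assigned[!is.na(assigned$formula) & !assigned$is_isotopologue, ]
  sets <- lapply(split(df$formula, df$sample_id), unique)
  if (length(sets) < 2) {
    abort("common_formulae() needs assignments from at least 2 samples")
  }
  common <- sort(Reduce(intersect, sets))
  shares <- tibble(
    sample_id = names(sets),
    n_formulae = unname(vapply(sets, length, integer(1))),
    n_common = length(common)
  )
  shares$share_pct <- 100 * shares$n_common / shares$n_formulae
  list(formulas = common, shares = shares)
}
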