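#' Choose isolation windows for fragmentation experiments
#'
#' Picks `k_windows` nominal masses inside `mass_region` for precursor
#' isolation. Candidate nominal masses must carry at least one formula common
#' to all samples; windows are then chosen greedily to cover as many compound
#' classes and CH2 series as possible, preferring higher summed
#' common-formula intensity and, on ties, the lower nominal mass. The default
#' region sits around 370 Da where DOM signal intensity peaks, which yields
#' the most detailed fragmentation fingerprints.
#'
#' @param assigned Multi-sample assignment table.
#' @param k_windows Number of windows (0 gives an empty list).
#' @param mass_region Length-2 numeric range of nominal masses.
#' @param width Isolation width (Da).
#' @return List of [isolation_window()] objects.
#' @export
select_windows <- function(assigned, k_windows = 6,
                           mass_region = c(350, 400), width = 0.4) {
  if (k_windows == 0) return(list())
  n_samples <- length(unique(assigned$sample_id))
  common <- if (n_samples >= 2) {
    common_formulae(assigned)$formulas
  } else {
    unique(assigned$formula[!is.na(assigned$formula) &
                              !assigned$is_isotopologue])
  }
  df <- assigned[!is.na(assigned$formula) & !assigned$is_isotopologue &
                   assigned$formula %in% common, , drop = FALSE]
  df <- df[df$mz >= mass_region[1] & df$mz <= mass_region[2], ]
  if (nrow(df) == 0) {
    abort("no common formulas in the requested mass region")
  }
  df$nominal <- round(df$mz)
  df$compound_class <- as.character(classify_formula(df$formula))
  cand <- df %>%
    group_by(.data$nominal) %>%
    summarise(total_intensity = sum(.data$intensity),
              center = sum(.data$mz * .data$intensity) /
                sum(.data$intensity),
              classes = list(unique(.data$compound_class)),
              .groups = "drop")
  picked <- integer()
  covered <- character()
  while (length(picked) < k_windows && length(picked) < nrow(cand)) {
    remaining <- setdiff(seq_len(nrow(cand)), picked)
    gain <- vapply(remaining, function(i) {
      length(setdiff(cand$classes[[i]], covered))
    }, integer(1))
    ord <- remaining[order(-gain, -cand$total_intensity[remaining],
                           cand$nominal[remaining])]
    picked <- c(picked, ord[1])
    covered <- union(covered, cand$classes[[ord[1]]])
  }
  # center each window on the ion cluster of its nominal mass (DOM mass
  # defects put the ions 0.1-0.2 Da above the integer mass)
  lapply(cand$center[picked], isolation_window, width = width)
}

#' Run the full DOM structural-universality analysis
#'
#' Orchestrates the pipeline end to end: per-sample internal calibration and
#' S/N filtering of the full-range spectra, formula assignment with
#' isotopologue verification, the common-formula intersection, per-window
#' fragment calibration/attribution and relative intensities with symmetric
#' detection-limit censoring, paired regressions over all sample pairs, the
#' three-level Bray-Curtis dissimilarity, and (when `sigma_single` is given)
#' the isomer-diversity estimates.
#'
#' @param peaks Multi-sample full-range peak list.
#' @param frag Optional list of fragmentation experiments, each a list with
#'   elements `window` ([isolation_window()]) and `peaks` (multi-sample
#'   fragmentation peak list). When NULL the fragment-level sections are
#'   omitted with a warning.
#' @param constraints [assignment_constraints()].
#' @param losses Loss table.
#' @param calibration_refs Reference masses for full-range calibration; NULL
#'   skips calibration (e.g. for already-calibrated input).
#' @param min_snr S/N threshold.
#' @param attr_tol_ppm Fragment attribution tolerance (ppm).
#' @param censor Apply [censor_below_common_limit()].
#' @param noise_snr Analytical noise level for censoring, in S/N units.
#' @param sigma_single Per-isomer carboxyl SD for [min_isomers()]; NULL
#'   skips the diversity section.
#' @param carboxyl_model Coefficients of the compositional carboxyl model.
#' @return A `dom_report` list: `assigned`, `counts`, `common`,
#'   `calibrations`, `rel_intensities`, `regressions`, `dissimilarity`,
#'   `diversity` (NULL when skipped), and `settings`.
#' @export
run_dom_pipeline <- function(peaks, frag = NULL,
                             constraints = assignment_constraints(),
                             losses = neutral_loss_table(),
                             calibration_refs = default_reference_masses(),
                             min_snr = 5, attr_tol_ppm = 1,
                             censor = TRUE, noise_snr = 1,
                             sigma_single = NULL,
                             carboxyl_model = c(a = 0.5, b = 0, c0 = 0)) {
  peaks <- peaklist(peaks)
  if (!"sample_id" %in% names(peaks)) peaks$sample_id <- "sample1"
  samples <- sort(unique(peaks$sample_id))

  calibrations <- list()
  cal_peaks <- purrr::map_dfr(samples, function(s) {
    pl <- peaks[peaks$sample_id == s, ]
    if (!is.null(calibration_refs)) {
      res <- internal_calibrate(pl, calibration_refs)
      calibrations[[s]] <<- res$calibration
      res$peaks
    } else {
      pl
    }
  })
  filtered <- snr_filter(cal_peaks, min_snr = min_snr)
  assigned <- verify_isotopologues(
    assign_formulas(filtered, constraints),
    tol_ppm = constraints$tol_ppm
  )
  counts <- assigned %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_peaks = dplyr::n(),
      n_assigned = sum(!is.na(.data$formula) & !.data$is_isotopologue),
      n_isotopologues = sum(.data$is_isotopologue),
      n_unassigned = sum(is.na(.data$formula)),
      assignment_rate = .data$n_assigned / .data$n_peaks,
      .groups = "drop"
    )
  common <- if (length(samples) >= 2) common_formulae(assigned) else {
    warn("single sample: common-formula and pairwise sections are empty")
    NULL
  }

  rel <- NULL
  rel_raw <- NULL
  frag_cals <- list()
  if (!is.null(frag)) {
    rel_parts <- list()
    snr_parts <- list()
    for (k in seq_along(frag)) {
      win <- frag[[k]]$window
      fpl <- peaklist(frag[[k]]$peaks)
      precursors <- window_precursors(assigned, win)
      if (length(precursors) == 0) {
        warn(sprintf("window %g: no assigned precursors; skipped", win$center))
        next
      }
      for (s in unique(fpl$sample_id)) {
        spl <- fpl[fpl$sample_id == s, ]
        cal <- tryCatch(
          calibrate_fragment_spectrum(spl, precursors, losses),
          error = function(e) NULL
        )
        if (!is.null(cal)) {
          frag_cals[[paste(win$center, s)]] <- cal$calibration
          spl <- cal$peaks
        }
        rec <- attribute_fragments(spl, precursors, losses,
                                   tol_ppm = attr_tol_ppm)
        rel_k <- tryCatch(relative_intensities(rec, losses),
                          error = function(e) NULL)
        if (is.null(rel_k)) next
        rel_parts[[length(rel_parts) + 1]] <- rel_k
        prec_rows <- rec[!is.na(rec$loss_label) &
                           rec$loss_label == "precursor", ]
        if (nrow(prec_rows) > 0) {
          snr_parts[[length(snr_parts) + 1]] <-
            select(prec_rows, "sample_id", "precursor_formula", "snr")
        }
      }
    }
    if (length(rel_parts) > 0) {
      rel_raw <- bind_rows(rel_parts)
      rel <- rel_raw
      if (censor && length(snr_parts) > 0) {
        rel <- censor_below_common_limit(rel, bind_rows(snr_parts),
                                         noise_snr = noise_snr)
      }
    }
  } else {
    warn("no fragmentation data: fragment-level statistics omitted")
  }

  regressions <- NULL
  dissimilarity <- NULL
  diversity <- NULL
  if (!is.null(common)) {
    if (!is.null(rel)) {
      rel_common <- rel[rel$precursor_formula %in% common$formulas, ]
      if (length(unique(rel_common$sample_id)) >= 2 &&
          nrow(rel_common) > 0) {
        regressions <- all_pairs_regression(rel_common)
      }
      dissimilarity <- dissimilarity_levels(assigned,
                                            rel = if (nrow(rel_common) > 0)
                                              rel_common else NULL,
                                            common = common$formulas)
      if (!is.null(sigma_single) && nrow(rel_common) > 0) {
        # carboxyl estimation uses the uncensored fragmentation patterns:
        # the detection-limit censoring exists for cross-sample fragment
        # comparability and would systematically bias the intensity-weighted
        # multiplicity mean
        rel_div <- rel_raw[rel_raw$precursor_formula %in% common$formulas, ]
        diversity <- tryCatch(
          estimate_diversity(
            rel_div, sigma_single = sigma_single,
            n_common = length(common$formulas), model = carboxyl_model,
            losses = losses
          ),
          error = function(e) {
            warn(paste0("diversity estimation skipped: ",
                        conditionMessage(e)))
            NULL
          }
        )
      }
    } else {
      dissimilarity <- suppressWarnings(
        dissimilarity_levels(assigned, rel = NULL, common = common$formulas)
      )
    }
  }

  structure(
    list(
      assigned = assigned, counts = counts, common = common,
      calibrations = calibrations, frag_calibrations = frag_cals,
      rel_intensities = rel, regressions = regressions,
      dissimilarity = dissimilarity, diversity = diversity,
      settings = list(
        constraints = constraints, min_snr = min_snr,
        attr_tol_ppm = attr_tol_ppm, censor = censor,
        noise_snr = noise_snr, carboxyl_model = carboxyl_model,
        sigma_single = sigma_single
      )
    ),
    class = "dom_report"
  )
}

#' @export
print.dom_report <- function(x, ...) {
  cat("<dom_report>\n")
  cat(sprintf("  samples: %s\n", paste(x$counts$sample_id, collapse = ", ")))
  cat(sprintf("  assigned formulas per sample: %s\n",
              paste(x$counts$n_assigned, collapse = ", ")))
  if (!is.null(x$common)) {
    cat(sprintf("  common formulas: %d (shares %s%%)\n",
                length(x$common$formulas),
                paste(sprintf("%.0f", x$common$shares$share_pct),
                      collapse = "/")))
  }
  if (!is.null(x$regressions)) {
    cat(sprintf("  pairwise slope deviation delta_sl: %.4f-%.4f (r %.3f-%.3f)\n",
                min(x$regressions$delta_sl), max(x$regressions$delta_sl),
                min(x$regressions$r), max(x$regressions$r)))
  }
  if (!is.null(x$dissimilarity)) {
    for (lv in names(x$dissimilarity$levels)) {
      m <- x$dissimilarity$levels[[lv]]
      cat(sprintf("  Bray-Curtis %-16s max %.3f\n", lv, max(m)))
    }
  }
  if (!is.null(x$diversity)) {
    cat(sprintf("  diversity r(c_frag, c_formula): %s\n",
                paste(sprintf("%.3f", x$diversity$r_estimates),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes the report's tables under a directory: assignment table, common
#' formulas and shares, relative intensities, regressions and dissimilarity
#' in TSV, plus a JSON summary mirroring [print.dom_report()].
#'
#' @param report A `dom_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dom_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) {
      readr::write_tsv(df, file.path(dir, paste0(name, ".tsv")))
    }
  }
  w(report$assigned, "assignments")
  w(report$counts, "counts")
  if (!is.null(report$common)) {
    w(report$common$shares, "common_shares")
    writeLines(report$common$formulas, file.path(dir, "common_formulae.txt"))
  }
  w(report$rel_intensities, "relative_intensities")
  w(report$regressions, "regressions")
  if (!is.null(report$dissimilarity)) {
    w(tidy(report$dissimilarity), "dissimilarity")
  }
  w(report$diversity, "diversity")
  summary <- list(
    n_common = if (!is.null(report$common))
      length(report$common$formulas) else NA,
    counts = report$counts,
    settings = list(
      min_snr = report$settings$min_snr,
      attr_tol_ppm = report$settings$attr_tol_ppm,
      censor = report$settings$censor
    )
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
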