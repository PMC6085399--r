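#' Neutral-loss table
#'
#' The losses observed in collision-induced fragmentation of DOM ions. The
#' nine *major* losses — CO2, 2CO2, 3CO2, H2O, CO2+H2O, 2CO2+H2O, CH3OH,
#' CO2+CH3OH, 2CO2+CH3OH — define the signal set entering relative-intensity
#' statistics (`I_Tot` = precursor + these nine). Carbon monoxide and a
#' second water are carried as minor losses: they are annotated when matched
#' but excluded from `I_Tot`. `n_co2` records the decarboxylation multiplicity
#' of each loss (combined losses count only their CO2 content), the weight
#' used by the carboxyl-group estimator.
#'
#' @return Tibble with columns `label`, `formula`, `exact_mass` (Da),
#'   `is_major`, `n_co2`.
#' @examples
#' neutral_loss_table()
#' @export
neutral_loss_table <- function() {
  tbl <- tibble(
    label = c("CO2", "2CO2", "3CO2", "H2O", "CO2+H2O", "2CO2+H2O",
              "CH3OH", "CO2+CH3OH", "2CO2+CH3OH", "CO", "2H2O"),
    formula = c("CO2", "C2O4", "C3O6", "H2O", "CH2O3", "C2H2O5",
                "CH4O", "C2H4O3", "C3H4O5", "CO", "H4O2"),
    is_major = c(rep(TRUE, 9), FALSE, FALSE),
    n_co2 = c(1L, 2L, 3L, 0L, 1L, 2L, 0L, 1L, 2L, 0L, 0L)
  )
  tbl$exact_mass <- neutral_mass(tbl$formula)
  tbl
}

#' Predict fragment ions of a precursor under a loss table
#'
#' Subtracts each neutral loss from the precursor composition; a loss applies
#' only when the precursor supplies all its atoms and at least one hydrogen
#' remains on the fragment (the ion keeps the \eqn{[M-H]^-} charge carrier).
#' The fragment ion m/z is the precursor ion m/z minus the exact loss mass.
#'
#' @param precursor A single formula (string or one-row counts table).
#' @param losses A loss table (see [neutral_loss_table()]).
#' @return Tibble: `loss_label`, `loss_mass`, `applicable`, and for
#'   applicable losses `fragment_formula` and `fragment_mz`.
#' @examples
#' predict_fragments("C9H6O6")
#' @export
predict_fragments <- function(precursor, losses = neutral_loss_table()) {
  pf <- as_formula(precursor)
  if (nrow(pf) != 1) abort("predict_fragments() takes one precursor")
  pmz <- ion_mass(pf)
  lf <- as_formula(losses$formula)
  ok <- formula_contains(pf[rep(1, nrow(lf)), ], lf) &
    (pf$h - lf$h) >= 1L
  frag_formula <- rep(NA_character_, nrow(lf))
  if (any(ok)) {
    frag_formula[ok] <- format_formula(
      formula_subtract(pf[rep(1, sum(ok)), ], lf[ok, , drop = FALSE])
    )
  }
  tibble(
    loss_label = losses$label,
    loss_mass = losses$exact_mass,
    is_major = losses$is_major,
    applicable = ok,
    fragment_formula = frag_formula,
    fragment_mz = ifelse(ok, pmz - losses$exact_mass, NA_real_)
  )
}

#' Isolation-window helper
#'
#' @param center Nominal m/z at which ions were isolated.
#' @param width Window width in Da (instrument default 0.4).
#' @return A list of class `dom_window`.
#' @export
isolation_window <- function(center, width = 0.4) {
  stopifnot(is.numeric(center), length(center) == 1, width > 0)
  structure(list(center = center, width = width), class = "dom_window")
}

#' Precursors falling inside an isolation window
#'
#' All assigned monoisotopic formulas whose ion m/z lies within
#' `center ± width/2`, pooled across samples (a formula seen in any sample is
#' a candidate precursor in all of them).
#'
#' @param assigned Assignment table (from [assign_formulas()]).
#' @param window An [isolation_window()].
#' @return Character vector of precursor formulas (sorted, unique).
#' @export
window_precursors <- function(assigned, window) {
  df <- assigned[!is.na(assigned$formula) & !assigned$is_isotopologue, ]
  if (nrow(df) == 0) return(character())
  mz <- ion_mass(df$formula)
  sel <- abs(mz - window$center) <= window$width / 2
  sort(unique(df$formula[sel]))
}

# predicted reference table for one window: precursor ions plus all
# applicable fragments of every precursor
.predicted_ions <- function(precursors, losses) {
  stopifnot(length(precursors) > 0)
  out <- purrr::map_dfr(precursors, function(p) {
    pred <- predict_fragments(p, losses)
    pred <- pred[pred$applicable, , drop = FALSE]
    bind_rows(
      tibble(precursor_formula = p, loss_label = "precursor",
             is_major = TRUE, predicted_mz = ion_mass(p)),
      tibble(precursor_formula = p, loss_label = pred$loss_label,
             is_major = pred$is_major, predicted_mz = pred$fragment_mz)
    )
  })
  out[order(out$predicted_mz), , drop = FALSE]
}

#' Calibrate a fragmentation spectrum against predicted fragment masses
#'
#' Fragmentation scans cannot be calibrated with a generic reference list
#' because only one nominal mass was isolated. Instead, the exact masses of
#' all potentially occurring ions — each precursor and each applicable
#' neutral-loss fragment — are used as the internal reference list, and the
#' same ppm-linear correction as for full-range spectra is fitted.
#'
#' @param frag Single-sample fragmentation peak list.
#' @param precursors Character vector of precursor formulas in the window.
#' @param losses Loss table.
#' @param match_tol_ppm,max_ppm,order Passed to [internal_calibrate()].
#' @return As [internal_calibrate()]: list of `peaks` and `calibration`.
#' @export
calibrate_fragment_spectrum <- function(frag, precursors,
                                        losses = neutral_loss_table(),
                                        match_tol_ppm = 1, max_ppm = 0.06,
                                        order = 1) {
  if (length(precursors) == 0) abort("no precursor formulas supplied")
  refs <- .predicted_ions(precursors, losses)$predicted_mz
  internal_calibrate(frag, refs, match_tol_ppm = match_tol_ppm,
                     max_ppm = max_ppm, order = order)
}

#' Attribute fragment peaks to (precursor, neutral loss) pairs
#'
#' Matches every peak of a calibrated fragmentation spectrum to the predicted
#' ion masses of the window's precursors by exact mass difference. A peak
#' explained by exactly one (precursor, loss) pair within `tol_ppm` is
#' attributed; a peak with two or more explanations is flagged ambiguous and,
#' under the default `ambiguous = "exclude"` policy, kept out of downstream
#' statistics (`ambiguous = "split"` divides its intensity across the
#' explanations in proportion to the precursor peak intensities). Peaks with
#' no explanation are returned unattributed.
#'
#' @param frag Fragmentation peak list (may hold several samples).
#' @param precursors Character vector of precursor formulas.
#' @param losses Loss table.
#' @param tol_ppm Attribution tolerance on the fragment m/z (ppm).
#' @param ambiguous `"exclude"` (default) or `"split"`.
#' @return Tibble: sample_id (if present), `mz`, `intensity`, `snr`,
#'   `precursor_formula`, `loss_label`, `is_major`, `predicted_mz`,
#'   `error_ppm`, `ambiguous`; unattributed peaks have `NA` in the
#'   attribution columns.
#' @export
attribute_fragments <- function(frag, precursors,
                                losses = neutral_loss_table(),
                                tol_ppm = 1,
                                ambiguous = c("exclude", "split")) {
  ambiguous <- arg_match(ambiguous)
  frag <- peaklist(frag)
  if (length(precursors) == 0) abort("no precursor formulas supplied")
  pred <- .predicted_ions(precursors, losses)
  if (nrow(frag) == 0) {
    return(mutate(frag, precursor_formula = character(),
                  loss_label = character(), is_major = logical(),
                  predicted_mz = numeric(), error_ppm = numeric(),
                  ambiguous = logical()))
  }
  grp <- if ("sample_id" %in% names(frag)) frag$sample_id else rep("", nrow(frag))
  res <- vector("list", nrow(frag))
  for (i in seq_len(nrow(frag))) {
    ppm <- abs(frag$mz[i] - pred$predicted_mz) / pred$predicted_mz * 1e6
    hits <- which(ppm <= tol_ppm)
    base <- frag[i, , drop = FALSE]
    if (length(hits) == 0) {
      res[[i]] <- mutate(base, precursor_formula = NA_character_,
                         loss_label = NA_character_, is_major = NA,
                         predicted_mz = NA_real_, error_ppm = NA_real_,
                         ambiguous = FALSE)
    } else if (length(hits) == 1) {
      res[[i]] <- mutate(base,
        precursor_formula = pred$precursor_formula[hits],
        loss_label = pred$loss_label[hits],
        is_major = pred$is_major[hits],
        predicted_mz = pred$predicted_mz[hits],
        error_ppm = (frag$mz[i] - pred$predicted_mz[hits]) /
          pred$predicted_mz[hits] * 1e6,
        ambiguous = FALSE)
    } else if (ambiguous == "exclude") {
      res[[i]] <- mutate(base,
        precursor_formula = paste(unique(pred$precursor_formula[hits]),
                                  collapse = "|"),
        loss_label = paste(pred$loss_label[hits], collapse = "|"),
        is_major = NA, predicted_mz = NA_real_, error_ppm = NA_real_,
        ambiguous = TRUE)
    } else {
      # split intensity in proportion to the precursor peak intensities
      prec_int <- vapply(pred$precursor_formula[hits], function(p) {
        j <- which(grp == grp[i] &
                     abs(frag$mz - ion_mass(p)) / ion_mass(p) * 1e6 <= tol_ppm)
        if (length(j) == 0) 0 else max(frag$intensity[j])
      }, numeric(1))
      w <- if (sum(prec_int) > 0) prec_int / sum(prec_int) else
        rep(1 / length(hits), length(hits))
      res[[i]] <- purrr::map_dfr(seq_along(hits), function(k) {
        mutate(base,
          intensity = base$intensity * w[k],
          precursor_formula = pred$precursor_formula[hits[k]],
          loss_label = pred$loss_label[hits[k]],
          is_major = pred$is_major[hits[k]],
          predicted_mz = pred$predicted_mz[hits[k]],
          error_ppm = (frag$mz[i] - pred$predicted_mz[hits[k]]) /
            pred$predicted_mz[hits[k]] * 1e6,
          ambiguous = TRUE)
      })
    }
  }
  bind_rows(res)
}

#' Relative fragment intensities I_F / I_Tot
#'
#' For each (sample, precursor): `I_Tot` is the precursor peak intensity plus
#' the intensities of its nine major-loss fragments; each signal's relative
#' intensity is its intensity over `I_Tot`, so the precursor share plus the
#' nine fragment shares sums to exactly 1. Fragments not detected contribute
#' 0 and appear as explicit zero rows, which keeps samples aligned for
#' regression and dissimilarity analysis. Ambiguously attributed peaks and
#' minor losses are excluded from `I_Tot`.
#'
#' Precursors whose own peak is absent in a sample cannot be normalized and
#' are dropped from that sample with a warning.
#'
#' @param records Attribution table from [attribute_fragments()].
#' @param losses Loss table (defines the major-loss set).
#' @return Tibble: `sample_id` (if present), `precursor_formula`,
#'   `loss_label` (`"precursor"` plus each major loss), `intensity`,
#'   `rel_intensity`.
#' @export
relative_intensities <- function(records, losses = neutral_loss_table()) {
  major <- c("precursor", losses$label[losses$is_major])
  df <- records[!is.na(records$precursor_formula) & !records$ambiguous &
                  records$loss_label %in% major, , drop = FALSE]
  if (nrow(df) == 0) abort("no unambiguous attributed signals to normalize")
  has_sample <- "sample_id" %in% names(df)
  if (!has_sample) df$sample_id <- ""
  df <- df %>%
    group_by(.data$sample_id, .data$precursor_formula, .data$loss_label) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop")
  # complete grid: every major signal for every (sample, precursor)
  grid <- tidyr::expand_grid(
    distinct(df, .data$sample_id, .data$precursor_formula),
    loss_label = major
  )
  out <- left_join(grid, df,
                   by = c("sample_id", "precursor_formula", "loss_label"))
  out$intensity[is.na(out$intensity)] <- 0
  out <- out %>%
    group_by(.data$sample_id, .data$precursor_formula) %>%
    mutate(i_tot = sum(.data$intensity)) %>%
    ungroup()
  missing_prec <- out %>%
    filter(.data$loss_label == "precursor", .data$intensity == 0)
  if (nrow(missing_prec) > 0) {
    warn(sprintf(
      "dropping %d (sample, precursor) pairs whose precursor peak is absent",
      nrow(missing_prec)
    ))
    out <- anti_join(out, missing_prec,
                     by = c("sample_id", "precursor_formula"))
  }
  if (nrow(out) == 0) abort("no precursor peak present; cannot normalize")
  out$rel_intensity <- out$intensity / out$i_tot
  out$loss_label <- factor(out$loss_label, levels = major)
  out <- arrange(out, .data$sample_id, .data$precursor_formula,
                 .data$loss_label)
  out$loss_label <- as.character(out$loss_label)
  if (!has_sample) out$sample_id <- NULL
  select(out, -"i_tot")
}

#' Common detection limit across samples
#'
#' The cross-sample comparison of fragment intensities is only meaningful
#' above a detection limit shared by all samples. For each precursor the
#' common limit is the *minimum* of its signal-to-noise ratios across the
#' samples compared; a relative fragment intensity below
#' `noise_snr / limit` (the analytical noise expressed on the relative scale
#' of the weakest sample) in *any* sample is censored to zero in *all*
#' samples, so that presence/absence differences caused purely by dynamic
#' range do not masquerade as structural differences.
#'
#' @param precursor_snr Tibble with `sample_id`, `precursor_formula`, `snr`
#'   of the precursor peak in each sample's fragmentation spectrum.
#' @return Tibble `precursor_formula`, `common_limit` (min S/N),
#'   `n_samples`.
#' @export
common_detection_limit <- function(precursor_snr) {
  stopifnot(all(c("sample_id", "precursor_formula", "snr") %in%
                  names(precursor_snr)))
  precursor_snr %>%
    group_by(.data$precursor_formula) %>%
    summarise(common_limit = min(.data$snr),
              n_samples = dplyr::n_distinct(.data$sample_id),
              .groups = "drop")
}

#' @rdname common_detection_limit
#' @param rel Relative-intensity table from [relative_intensities()] with a
#'   `sample_id` column.
#' @param noise_snr Analytical noise level in S/N units (default 1).
#' @return `censor_below_common_limit()`: `rel` with sub-threshold fragment
#'   signals set to 0 symmetrically across samples (precursor rows are never
#'   censored).
#' @export
censor_below_common_limit <- function(rel, precursor_snr, noise_snr = 1) {
  lim <- common_detection_limit(precursor_snr)
  df <- left_join(rel, lim, by = "precursor_formula")
  df$threshold_rel <- noise_snr / df$common_limit
  below <- df %>%
    filter(.data$loss_label != "precursor",
           .data$rel_intensity < .data$threshold_rel) %>%
    distinct(.data$precursor_formula, .data$loss_label)
  if (nrow(below) > 0) {
    key <- paste(df$precursor_formula, df$loss_label)
    censored <- key %in% paste(below$precursor_formula, below$loss_label) &
      df$loss_label != "precursor"
    df$rel_intensity[censored] <- 0
    df$intensity[censored] <- 0
  }
  select(df, -"common_limit", -"n_samples", -"threshold_rel")
}
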