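#' Paired regression of relative fragment intensities
#'
#' Fits relative fragment intensities of one sample against another over the
#' shared fragment keys (precursor formula x neutral loss, fragments of
#' common formulas only). If the two samples contain structurally identical
#' compounds the points fall on the identity line, so the deviation of the
#' fitted slope from 1, `delta_sl = |1 - slope|`, measures structural
#' difference; the Pearson correlation and its two-sided p-value quantify
#' scatter.
#'
#' The sample given first is the abscissa (for systematic pair tables, order
#' pairs lexicographically by label — see [all_pairs_regression()]). One
#' outlier at most is removed, and only when its externally studentized
#' residual exceeds `outlier_sigma`; both the raw and the screened fit are
#' reported.
#'
#' @param rel Relative-intensity table ([relative_intensities()]) holding
#'   both samples.
#' @param sample_a,sample_b Sample labels; `sample_a` is the abscissa.
#' @param include_precursor Include the precursor-share rows as points
#'   (default FALSE: fragments only, as in the intensity statistics the
#'   index was designed for).
#' @param outlier_sigma Externally studentized residual threshold (default
#'   4).
#' @return A `dom_pair_regression` object; [tidy()] gives the point table
#'   (key, x, y, excluded flag), [glance()] the one-row fit summary
#'   (`slope`, `intercept`, `r`, `p_value`, `n`, `delta_sl`, plus the
#'   unscreened `slope_raw`, `delta_sl_raw`, `n_excluded`).
#' @export
paired_regression <- function(rel, sample_a, sample_b,
                              include_precursor = FALSE, outlier_sigma = 4) {
  stopifnot(all(c("sample_id", "precursor_formula", "loss_label",
                  "rel_intensity") %in% names(rel)))
  df <- rel
  if (!include_precursor) df <- df[df$loss_label != "precursor", ]
  a <- df[df$sample_id == sample_a, ]
  b <- df[df$sample_id == sample_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("one of the requested samples has no relative intensities")
  }
  pts <- inner_join(
    select(a, "precursor_formula", "loss_label", x = "rel_intensity"),
    select(b, "precursor_formula", "loss_label", y = "rel_intensity"),
    by = c("precursor_formula", "loss_label")
  )
  if (nrow(pts) < 3) abort("need at least 3 shared fragment keys")
  if (sd(pts$x) == 0) abort("degenerate abscissa: all x values identical")
  pts$key <- paste(pts$precursor_formula, pts$loss_label, sep = ":")

  fit_once <- function(d) {
    fit <- lm(y ~ x, data = d)
    ct <- suppressWarnings(cor.test(d$x, d$y))
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d), fit = fit
    )
  }
  raw <- fit_once(pts)
  excluded <- character()
  screened <- raw
  rs <- suppressWarnings(stats::rstudent(raw$fit))
  # an (almost) exact fit has no outliers: studentized residuals on a
  # zero-scale residual vector are numerical noise
  resid_scale <- suppressWarnings(summary(raw$fit)$sigma)
  if (resid_scale > 1e-10 * max(abs(pts$y), 1) &&
      any(is.finite(rs) & abs(rs) > outlier_sigma)) {
    worst <- which.max(abs(ifelse(is.finite(rs), rs, 0)))
    excluded <- pts$key[worst]
    screened <- fit_once(pts[-worst, , drop = FALSE])
  }
  pts$excluded <- pts$key %in% excluded
  structure(
    list(
      sample_a = sample_a, sample_b = sample_b,
      points = as_tibble(pts[c("key", "precursor_formula", "loss_label",
                               "x", "y", "excluded")]),
      slope = screened$slope, intercept = screened$intercept,
      r = screened$r, p_value = screened$p_value, n = screened$n,
      delta_sl = abs(1 - screened$slope),
      slope_raw = raw$slope, delta_sl_raw = abs(1 - raw$slope),
      n_excluded = length(excluded), excluded_keys = excluded,
      outlier_sigma = outlier_sigma
    ),
    class = "dom_pair_regression"
  )
}

#' @export
print.dom_pair_regression <- function(x, ...) {
  cat(sprintf(
    "<dom_pair_regression> %s (x) vs %s (y): slope %.4f (delta_sl %.4f), r %.4f, p %.3g, n %d%s\n",
    x$sample_a, x$sample_b, x$slope, x$delta_sl, x$r, x$p_value, x$n,
    if (x$n_excluded > 0) sprintf(" (%d outlier excluded)", x$n_excluded) else ""
  ))
  invisible(x)
}

#' @export
tidy.dom_pair_regression <- function(x, ...) x$points

#' @export
glance.dom_pair_regression <- function(x, ...) {
  tibble(
    sample_a = x$sample_a, sample_b = x$sample_b,
    slope = x$slope, intercept = x$intercept, r = x$r,
    p_value = x$p_value, n = x$n, delta_sl = x$delta_sl,
    slope_raw = x$slope_raw, delta_sl_raw = x$delta_sl_raw,
    n_excluded = x$n_excluded
  )
}

#' @rdname paired_regression
#' @return `all_pairs_regression()`: a tibble with one [glance()] row per
#'   unordered sample pair, pairs ordered lexicographically (first label is
#'   the abscissa).
#' @export
all_pairs_regression <- function(rel, include_precursor = FALSE,
                                 outlier_sigma = 4) {
  ids <- sort(unique(rel$sample_id))
  if (length(ids) < 2) abort("need at least two samples")
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    glance(paired_regression(rel, p[1], p[2],
                             include_precursor = include_precursor,
                             outlier_sigma = outlier_sigma))
  })
}

#' Bray-Curtis compositional dissimilarity of two vectors
#'
#' `BC = sum(|x - y|) / sum(x + y)` on non-negative, aligned composition
#' vectors: 0 for identical compositions, 1 for disjoint supports. Keys
#' present in only one sample must enter the other as zeros before the call
#' (matrix-level helpers do this alignment automatically).
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return A scalar in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 0), c(1, 1))  # 0.5
#' @export
bray_curtis <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(x < 0) || any(y < 0)) abort("Bray-Curtis needs non-negative inputs")
  tot <- sum(x + y)
  if (tot == 0) abort("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

# sample-by-feature matrix from a long table; absent keys enter as 0
.wide_matrix <- function(df, key_cols, value_col) {
  df$.key <- do.call(paste, c(df[key_cols], sep = ":"))
  wide <- tidyr::pivot_wider(
    df[c("sample_id", ".key", value_col)],
    names_from = ".key", values_from = all_of(value_col), values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

.bc_matrix <- function(m, renormalize = FALSE) {
  if (renormalize) {
    rs <- rowSums(m)
    if (any(rs == 0)) abort("a sample has zero total intensity at this level")
    m <- m / rs
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Bray-Curtis dissimilarity at three compositional levels
#'
#' Computes sample-by-sample Bray-Curtis matrices on
#' \enumerate{
#'   \item the normalized intensities of *all* assigned molecular formulas
#'     in the full-range spectra,
#'   \item the subset of formulas *common* to every sample (renormalized
#'     over that subset by default, so the two levels stay on comparable
#'     compositional scales), and
#'   \item the relative intensities of major-loss *fragments* of the
#'     fragmented common formulas (each sample's fragment vector normalized
#'     to sum 1).
#' }
#' A universal structural background shows up as level-3 values near the
#' replicate noise floor even when levels 1–2 are large.
#'
#' @param assigned Multi-sample assignment table.
#' @param rel Optional relative-intensity table for level 3 (omit with a
#'   warning when unavailable).
#' @param common Optional character vector of common formulas (computed via
#'   [common_formulae()] when NULL).
#' @param renormalize_common Renormalize level 2 over the common subset
#'   (default TRUE; FALSE keeps the level-1 scale).
#' @return A `dom_dissimilarity` object holding the matrices; [tidy()] gives
#'   the long form (`sample_a`, `sample_b`, `level`, `dissimilarity`).
#' @export
dissimilarity_levels <- function(assigned, rel = NULL, common = NULL,
                                 renormalize_common = TRUE) {
  df <- assigned[!is.na(assigned$formula) & !assigned$is_isotopologue, ]
  if (length(unique(df$sample_id)) < 2) abort("need at least two samples")
  df <- normalize_intensities(df)
  m1 <- .wide_matrix(df, "formula", "rel_intensity")
  levels <- list(all_formulae = .bc_matrix(m1))
  if (is.null(common)) common <- common_formulae(assigned)$formulas
  if (length(common) == 0) {
    abort("no formulas common to all samples; level 2 is undefined")
  }
  m2 <- m1[, colnames(m1) %in% common, drop = FALSE]
  levels$common_formulae <- .bc_matrix(m2, renormalize = renormalize_common)
  n_feat <- c(all_formulae = ncol(m1), common_formulae = ncol(m2),
              fragments = NA_integer_)
  if (is.null(rel)) {
    warn("no fragmentation data supplied; fragment-level dissimilarity omitted")
  } else {
    fr <- rel[rel$loss_label != "precursor" &
                rel$precursor_formula %in% common, , drop = FALSE]
    if (nrow(fr) == 0) abort("no fragments of common formulas in 'rel'")
    m3 <- .wide_matrix(fr, c("precursor_formula", "loss_label"),
                       "rel_intensity")
    levels$fragments <- .bc_matrix(m3, renormalize = TRUE)
    n_feat["fragments"] <- ncol(m3)
  }
  structure(list(levels = levels, n_features = n_feat,
                 renormalize_common = renormalize_common),
            class = "dom_dissimilarity")
}

#' @export
print.dom_dissimilarity <- function(x, ...) {
  cat("<dom_dissimilarity>\n")
  for (lv in names(x$levels)) {
    m <- x$levels[[lv]]
    up <- m[upper.tri(m)]
    cat(sprintf("  %-16s n_features %5s, max %.3f, mean %.3f\n",
                lv, x$n_features[[lv]], max(up), mean(up)))
  }
  invisible(x)
}

#' @export
tidy.dom_dissimilarity <- function(x, ...) {
  purrr::map_dfr(names(x$levels), function(lv) {
    m <- x$levels[[lv]]
    idx <- which(upper.tri(m), arr.ind = TRUE)
    tibble(
      sample_a = rownames(m)[idx[, 1]], sample_b = colnames(m)[idx[, 2]],
      level = lv, dissimilarity = m[idx]
    )
  })
}

#' Replicate analytical variability
#'
#' Fragment-level Bray-Curtis dissimilarity between two analytical runs of
#' the same sample — the noise floor against which between-sample
#' fragment-level dissimilarities are interpreted.
#'
#' @param rel Relative-intensity table holding both replicate runs.
#' @param rep_a,rep_b The two replicate labels.
#' @return Scalar Bray-Curtis dissimilarity.
#' @export
replicate_variability <- function(rel, rep_a, rep_b) {
  fr <- rel[rel$loss_label != "precursor" &
              rel$sample_id %in% c(rep_a, rep_b), , drop = FALSE]
  if (length(unique(fr$sample_id)) != 2) {
    abort("both replicate labels must be present in 'rel'")
  }
  m <- .wide_matrix(fr, c("precursor_formula", "loss_label"), "rel_intensity")
  rs <- rowSums(m)
  if (any(rs == 0)) abort("a replicate has zero total fragment intensity")
  m <- m / rs
  bray_curtis(m[rep_a, ], m[rep_b, ])
}
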