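#' Plot a mass spectrum
#'
#' Centroid stick plot of a peak list, faceted by sample when several are
#' present.
#'
#' @param pl A peak list.
#' @param mz_range Optional length-2 zoom range.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(pl, mz_range = NULL) {
  pl <- peaklist(pl)
  if (!is.null(mz_range)) {
    pl <- pl[pl$mz >= mz_range[1] & pl$mz <= mz_range[2], ]
  }
  p <- ggplot2::ggplot(pl, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                        y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment(linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
  if ("sample_id" %in% names(pl)) {
    p <- p + ggplot2::facet_wrap(~sample_id, ncol = 1)
  }
  p
}

#' Van Krevelen diagram of assigned formulas
#'
#' H/C against O/C for every assigned monoisotopic formula, coloured by
#' compound class — the standard at-a-glance map of DOM composition.
#'
#' @param assigned Assignment table from [assign_formulas()].
#' @return A ggplot object.
#' @export
plot_van_krevelen <- function(assigned) {
  df <- assigned[!is.na(assigned$formula) & !assigned$is_isotopologue, ]
  f <- as_formula(df$formula)
  df$hc <- f$h / f$c
  df$oc <- f$o / f$c
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$oc, y = .data$hc,
                                        colour = .data$compound_class,
                                        size = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "O/C", y = "H/C", colour = "class") +
    ggplot2::theme_minimal()
  if ("sample_id" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~sample_id)
  }
  p
}

#' @export
autoplot.dom_pair_regression <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "steelblue") +
    ggplot2::geom_smooth(data = pts[!pts$excluded, ], method = "lm",
                         formula = y ~ x, se = FALSE, colour = "black",
                         linewidth = 0.5) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = sprintf("rel. fragment intensity, %s", object$sample_a),
      y = sprintf("rel. fragment intensity, %s", object$sample_b),
      title = sprintf("slope %.3f (delta_sl %.3f), r %.3f, n %d",
                      object$slope, object$delta_sl, object$r, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dom_dissimilarity <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  names(df2)[1:2] <- c("sample_b", "sample_a")
  long <- bind_rows(df, df2)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                     fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", 100 * .data$dissimilarity)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Bray-Curtis") +
    ggplot2::theme_minimal()
}
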