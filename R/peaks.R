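#' Construct and validate a peak list
#'
#' A peak list is a plain tibble with one detected ion per row and numeric
#' columns `mz` (measured mass-to-charge, Da), `intensity` (arbitrary detector
#' units) and `snr` (signal-to-noise ratio). Multi-sample tables carry an
#' additional `sample_id` column and are validated per sample. `peaklist()`
#' checks the invariants every downstream function relies on: positive m/z,
#' non-negative intensity and S/N, strictly ascending m/z within a sample, and
#' no duplicate m/z within 1e-6 Da.
#'
#' @param x A data frame with columns `mz`, `intensity`, `snr` (and optionally
#'   `sample_id`).
#' @param sample_id Optional label attached as a `sample_id` column when `x`
#'   has none.
#' @return A validated tibble sorted by (`sample_id`,) `mz`.
#' @examples
#' peaklist(tibble::tibble(mz = c(200.1, 300.2), intensity = c(5, 7), snr = c(10, 14)))
#' @export
peaklist <- function(x, sample_id = NULL) {
  x <- as_tibble(x)
  need <- c("mz", "intensity", "snr")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("peak list is missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (col in need) {
    if (!is.numeric(x[[col]])) abort(sprintf("column '%s' must be numeric", col))
    if (any(!is.finite(x[[col]]))) abort(sprintf("column '%s' has non-finite values", col))
  }
  if (!is.null(sample_id) && !"sample_id" %in% names(x)) {
    x$sample_id <- sample_id
  }
  if (any(x$mz <= 0)) abort("all m/z values must be > 0")
  if (any(x$intensity < 0)) abort("intensities must be >= 0")
  if (any(x$snr < 0)) abort("signal-to-noise ratios must be >= 0")
  grp <- if ("sample_id" %in% names(x)) x$sample_id else rep("", nrow(x))
  x <- x[order(grp, x$mz), , drop = FALSE]
  grp <- if ("sample_id" %in% names(x)) x$sample_id else rep("", nrow(x))
  same <- grp[-1] == grp[-length(grp)]
  if (nrow(x) > 1 && any(same & diff(x$mz) < 1e-6)) {
    abort("duplicate m/z values within 1e-6 Da in one sample")
  }
  x
}

#' Read and write peak-list tables
#'
#' Peak lists travel as tab-separated text with a header line naming at least
#' the lowercase columns `mz`, `intensity` and `snr`; lines starting with `#`
#' are comment/header metadata and are skipped. `write_peaklist()` emits the
#' same dialect, prefixed with comment lines recording the ion-mass convention
#' and an optional calibration summary, and prints numbers at 7 significant
#' digits (read–write round-trips to that precision).
#'
#' @param path File path.
#' @param pl A peak list (see [peaklist()]).
#' @param comment Extra comment lines (without the leading `#`).
#' @return `read_peaklist()`: a validated peak-list tibble.
#' @export
read_peaklist <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("mz", "intensity", "snr")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("'", path, "' is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    df[need] <- lapply(df[need], as.numeric)
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      abort(sprintf("'%s': non-numeric value in column '%s' (data row %d)",
                    path, col, if (is.na(bad)) NA_integer_ else bad))
    }
  }
  bad <- which(df$intensity < 0)
  if (length(bad) > 0) {
    abort(sprintf("'%s': negative intensity in data row %d", path, bad[1]))
  }
  peaklist(df)
}

#' @rdname read_peaklist
#' @export
write_peaklist <- function(pl, path, comment = character()) {
  pl <- peaklist(pl)
  hdr <- c(
    "# fticrdom peak list (tab-separated)",
    "# ion convention: [M-H]-, m/z = neutral mass - 1.00727646 Da",
    if (length(comment) > 0) paste0("# ", comment)
  )
  num <- vapply(pl, is.numeric, logical(1))
  out <- pl
  out[num] <- lapply(pl[num], function(v) formatC(v, digits = 7, format = "g"))
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(out, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Signal-to-noise filtering
#'
#' Retains peaks with `snr >= min_snr` (boundary inclusive; the conventional
#' detection cut for DOM FT-ICR-MS work is S/N >= 5). Idempotent and
#' order-preserving.
#'
#' @param pl A peak list.
#' @param min_snr Minimum signal-to-noise ratio (default 5).
#' @return The filtered peak list.
#' @export
snr_filter <- function(pl, min_snr = 5) {
  pl <- peaklist(pl)
  pl[pl$snr >= min_snr, , drop = FALSE]
}

#' Normalize intensities to their sum
#'
#' Adds a `rel_intensity` column, `intensity / sum(intensity)`, computed per
#' sample when a `sample_id` column is present. Used to put assigned-peak
#' intensities of different samples on a common compositional scale before
#' dissimilarity analysis.
#'
#' @param pl A peak list (typically already restricted to assigned peaks).
#' @return The input with a `rel_intensity` column; each sample's values sum
#'   to 1.
#' @export
normalize_intensities <- function(pl) {
  pl <- as_tibble(pl)
  if (nrow(pl) == 0) abort("cannot normalize an empty peak set")
  grp <- if ("sample_id" %in% names(pl)) pl$sample_id else rep("all", nrow(pl))
  tot <- tapply(pl$intensity, grp, sum)
  if (any(tot <= 0)) abort("total intensity is zero; cannot normalize")
  pl$rel_intensity <- pl$intensity / as.numeric(tot[match(grp, names(tot))])
  pl
}
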