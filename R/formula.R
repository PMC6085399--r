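#' Elemental formula tables
#'
#' Formulas are carried through the package in two interchangeable shapes: a
#' Hill-order text form (`"C18H22O8"`, isotope substitutions as prefix tokens,
#' e.g. `"[13C]1C17H22O8"` for a molecule with 18 carbons of which one is
#' thirteen-C) and a counts tibble with one row per formula and integer columns
#' `c, h, n, o, s, p, c13, n15`. `parse_formula()` and `format_formula()`
#' convert between the two bit-exactly; `as_formula()` accepts either and
#' returns a validated counts tibble.
#'
#' In the counts form, `c` and `n` are the *total* carbon and nitrogen counts
#' (including substituted atoms); `c13 <= c` and `n15 <= n` give the number of
#' heavy substitutions. In the text form the plain `C`/`N` tokens carry only
#' the light-isotope count, so the two representations round-trip.
#'
#' @param x For `parse_formula()`, a character vector of formula strings. For
#'   `as_formula()`, a character vector or a data frame with (a subset of) the
#'   count columns. For `format_formula()`, a counts data frame.
#' @return `parse_formula()` and `as_formula()`: a tibble of element counts.
#'   `format_formula()`: a character vector.
#' @examples
#' parse_formula("C18H22O8")
#' format_formula(tibble::tibble(c = 9, h = 6, o = 6))
#' @name formula-representation
NULL

.empty_counts <- function(size) {
  cols <- rep(list(integer(size)), length(.dom_elements))
  as_tibble(setNames(cols, .dom_elements))
}

#' @rdname formula-representation
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x))
  out <- .empty_counts(length(x))
  token_re <- "\\[13C\\][0-9]+|\\[15N\\][0-9]+|[CHNOPS][0-9]*"
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s)) {
      out[i, ] <- NA_integer_
      next
    }
    toks <- regmatches(s, gregexpr(token_re, s))[[1]]
    if (paste(toks, collapse = "") != s) {
      abort(sprintf("cannot parse formula string '%s'", s))
    }
    for (tk in toks) {
      if (startsWith(tk, "[13C]")) {
        k <- as.integer(substring(tk, 6))
        out$c13[i] <- out$c13[i] + k
        out$c[i] <- out$c[i] + k
      } else if (startsWith(tk, "[15N]")) {
        k <- as.integer(substring(tk, 6))
        out$n15[i] <- out$n15[i] + k
        out$n[i] <- out$n[i] + k
      } else {
        el <- tolower(substring(tk, 1, 1))
        k <- if (nchar(tk) > 1) as.integer(substring(tk, 2)) else 1L
        out[[el]][i] <- out[[el]][i] + k
      }
    }
  }
  validate_formula(out)
}

#' @rdname formula-representation
#' @export
format_formula <- function(x) {
  f <- as_formula(x)
  piece <- function(sym, k, always_count = FALSE) {
    ifelse(k == 0L, "",
      paste0(sym, ifelse(k == 1L & !always_count, "", as.character(k)))
    )
  }
  # Hill order: C, H, then remaining elements alphabetically (N, O, P, S);
  # isotope tokens lead and always print their multiplicity.
  paste0(
    piece("[13C]", f$c13, always_count = TRUE),
    piece("[15N]", f$n15, always_count = TRUE),
    piece("C", f$c - f$c13),
    piece("H", f$h),
    piece("N", f$n - f$n15),
    piece("O", f$o),
    piece("P", f$p),
    piece("S", f$s)
  )
}

#' @rdname formula-representation
#' @export
as_formula <- function(x) {
  if (is.character(x)) {
    return(parse_formula(x))
  }
  if (!is.data.frame(x)) {
    abort("formulas must be given as strings or as a counts data frame")
  }
  out <- .empty_counts(nrow(x))
  for (el in .dom_elements) {
    if (el %in% names(x)) {
      v <- x[[el]]
      if (!is.numeric(v) || any(!is.na(v) & v != floor(v))) {
        abort(sprintf("column '%s' must hold integer counts", el))
      }
      out[[el]] <- as.integer(v)
    }
  }
  validate_formula(out)
}

validate_formula <- function(f) {
  bad <- rowSums(as.matrix(f) < 0L, na.rm = TRUE) > 0
  if (any(bad)) abort("element counts must be >= 0")
  if (any(f$c13 > f$c, na.rm = TRUE)) abort("c13 substitutions exceed carbon count")
  if (any(f$n15 > f$n, na.rm = TRUE)) abort("n15 substitutions exceed nitrogen count")
  f
}

.recycle2 <- function(a, b) {
  if (nrow(a) == nrow(b)) return(list(a = a, b = b))
  if (nrow(a) == 1L) return(list(a = a[rep(1L, nrow(b)), ], b = b))
  if (nrow(b) == 1L) return(list(a = a, b = b[rep(1L, nrow(a)), ]))
  abort("formula tables must have matching length (or length 1)")
}

#' Formula arithmetic
#'
#' Element-wise addition and subtraction of formulas, e.g. to remove a neutral
#' loss from a precursor composition. Subtraction is only defined when every
#' resulting count stays non-negative; `formula_subtract()` errors otherwise
#' (use [formula_contains()] to test availability first).
#'
#' @param a,b Formulas (strings or counts tables); one of the two may have a
#'   single row, which is recycled.
#' @return A counts tibble (`formula_add`, `formula_subtract`) or a logical
#'   vector (`formula_contains`: does `a` contain all atoms of `b`?).
#' @examples
#' format_formula(formula_subtract("C9H6O6", "CO2"))
#' formula_contains("CH4", "CO2")
#' @export
formula_add <- function(a, b) {
  xs <- .recycle2(as_formula(a), as_formula(b))
  validate_formula(as_tibble(as.data.frame(
    as.matrix(xs$a) + as.matrix(xs$b)
  )))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  xs <- .recycle2(as_formula(a), as_formula(b))
  m <- as.matrix(xs$a) - as.matrix(xs$b)
  if (any(m < 0L)) abort("formula subtraction would give negative counts")
  validate_formula(as_tibble(as.data.frame(m)))
}

#' @rdname formula_add
#' @export
formula_contains <- function(a, b) {
  xs <- .recycle2(as_formula(a), as_formula(b))
  rowSums(as.matrix(xs$a) - as.matrix(xs$b) < 0L) == 0L
}
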