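#' Monoisotopic mass constants
#'
#' CODATA/IUPAC monoisotopic atomic masses for the elements considered in DOM
#' formula assignment (C, H, N, O, S, P), together with the proton and electron
#' masses and the isotope mass differences used for isotopologue detection.
#' All values in Dalton. The list is fixed; it is the single source of every
#' mass computed by the package.
#'
#' @return Named list of masses (Da): `C`, `H`, `N`, `O`, `S`, `P`, `electron`,
#'   `proton`, `d13C` (mass difference between one thirteen-C and one
#'   twelve-C), `d15N` (fifteen-N minus fourteen-N), and `abundance_13C`
#'   (natural fractional abundance of thirteen-C, used for isotopologue
#'   intensity checks).
#' @examples
#' dom_masses()$proton
#' @export
dom_masses <- function() {
  list(
    C = 12.0,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    S = 31.97207100,
    P = 30.97376163,
    electron = 0.000548579909,
    proton = 1.007276466621,
    d13C = 1.0033548378,
    d15N = 0.9970348934,
    abundance_13C = 0.0107
  )
}

# element order used everywhere a formula is stored as counts
.dom_elements <- c("c", "h", "n", "o", "s", "p", "c13", "n15")
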