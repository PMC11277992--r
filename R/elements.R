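#' Atomic constants used throughout the package
#'
#' Monoisotopic masses are CODATA/IUPAC values for the most abundant isotope
#' of each element; isotope lists carry (mass, natural abundance fraction)
#' pairs and the integer nominal-mass offset of each isotope relative to the
#' monoisotopic one.  Valences are the standard bonding valences used in the
#' degrees-of-unsaturation (ring plus double-bond equivalent) formula.
#'
#' @format A named list, one entry per element symbol, each a list with
#'   fields `monoisotopic` (Da), `isotopes` (data.frame with columns
#'   `mass`, `abundance`, `offset`) and `valence` (integer).
#' @keywords internal
.element_table <- local({
  el <- function(mono, valence, masses, abundances) {
    stopifnot(length(masses) == length(abundances))
    offset <- as.integer(round(masses - masses[1L]))
    list(
      monoisotopic = mono,
      isotopes = data.frame(mass = masses, abundance = abundances,
                            offset = offset),
      valence = valence
    )
  }
  list(
    C  = el(12.0,          4L, c(12.0, 13.00335484), c(0.9893, 0.0107)),
    H  = el(1.00782503207, 1L, c(1.00782503207, 2.01410177785),
            c(0.999885, 0.000115)),
    O  = el(15.99491461956, 2L, c(15.99491461956, 16.99913170, 17.9991610),
            c(0.99757, 0.00038, 0.00205)),
    N  = el(14.0030740048, 3L, c(14.0030740048, 15.0001088982),
            c(0.99636, 0.00364)),
    S  = el(31.97207100,   2L,
            c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            c(0.9499, 0.0075, 0.0425, 0.0001)),
    Cl = el(34.96885268,   1L, c(34.96885268, 36.96590259),
            c(0.7576, 0.2424)),
    Br = el(78.9183371,    1L, c(78.9183371, 80.9162906),
            c(0.5069, 0.4931)),
    F  = el(18.99840322,   1L, c(18.99840322), c(1.0)),
    I  = el(126.904473,    1L, c(126.904473), c(1.0)),
    P  = el(30.97376163,   3L, c(30.97376163), c(1.0)),
    Na = el(22.98976928,   1L, c(22.98976928), c(1.0)),
    K  = el(38.96370668,   1L, c(38.96370668, 39.96399848, 40.96182576),
            c(0.932581, 0.000117, 0.067302))
  )
})

#' Electron rest mass in daltons
#' @keywords internal
.electron_mass <- 0.00054857990907

#' List supported element symbols
#'
#' @return Character vector of element symbols the mass table knows about.
#' @export
#' @examples
#' supported_elements()
supported_elements <- function() names(.element_table)

#' Look up the monoisotopic mass of an element
#'
#' @param symbol Element symbol, e.g. `"Na"`.
#' @return Monoisotopic mass in Da.
#' @export
element_mass <- function(symbol) {
  entry <- .element_table[[symbol]]
  if (is.null(entry)) {
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  }
  entry$monoisotopic
}
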