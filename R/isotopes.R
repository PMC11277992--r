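#' Simulate the nominal-mass isotope pattern of a molecular formula
#'
#' Convolves the per-element isotopologue distributions, aggregated by
#' integer nominal-mass offset from the monoisotopic peak (M+0, M+1, M+2,
#' ...), and normalizes so the tallest peak is 1.  Heavy two-neutron
#' isotopes (37Cl, 81Br, 34S, 18O) land in the M+2 slot, the usual
#' mass-spectrometric convention.  Fine structure within a nominal slot is
#' summed, not resolved.
#'
#' @param formula A `molecular_formula` or formula string.
#' @param max_offset Largest offset retained (>= 2).
#' @return An `isotope_pattern`: data.frame with columns `offset`
#'   (0, 1, ..., `max_offset`) and `intensity` (max 1).
#' @export
#' @examples
#' isotope_pattern("C15H25ClO4")   # strong M+2 from the single chlorine
isotope_pattern <- function(formula, max_offset = 4L) {
  formula <- as_formula(formula)
  if (max_offset < 2L) stop("max_offset must be >= 2", call. = FALSE)
  n_slots <- max_offset + 1L
  # distribution over offsets as a probability vector, built by repeated
  # convolution; element counts here are small so the direct loop is cheap
  dist <- c(1, rep(0, max_offset))
  for (sym in names(formula)) {
    iso <- .element_table[[sym]]$isotopes
    atom <- rep(0, n_slots)
    for (k in seq_len(nrow(iso))) {
      off <- iso$offset[k]
      if (off <= max_offset) {
        atom[off + 1L] <- atom[off + 1L] + iso$abundance[k]
      }
    }
    for (i in seq_len(formula[[sym]])) {
      full <- convolve(dist, rev(atom), type = "open")
      dist <- full[seq_len(n_slots)]
    }
  }
  dist[dist < 0] <- 0  # guard against FFT round-off
  structure(
    data.frame(offset = 0:max_offset, intensity = dist / max(dist)),
    class = c("isotope_pattern", "data.frame")
  )
}

#' Test an isotope pattern for a one-chlorine M+2 signature
#'
#' A single chlorine atom gives an M+2/M intensity ratio near the 37Cl/35Cl
#' abundance ratio (about 0.32, the classic "3:1" appearance).  Returns
#' `TRUE` when M+2/M falls in a window centered on that value.
#'
#' @param pattern An `isotope_pattern` (from [isotope_pattern()]).
#' @param window Acceptance interval for M+2/M; default `c(0.24, 0.42)`.
#' @return Logical.
#' @export
#' @examples
#' chlorine_signature(isotope_pattern("C15H25ClO4"))  # TRUE
#' chlorine_signature(isotope_pattern("C15H24O3"))    # FALSE
chlorine_signature <- function(pattern, window = c(0.24, 0.42)) {
  if (!inherits(pattern, "isotope_pattern") &&
      !(is.data.frame(pattern) && all(c("offset", "intensity") %in%
                                        names(pattern)))) {
    stop("pattern must be an isotope_pattern", call. = FALSE)
  }
  if (!all(c(0L, 2L) %in% pattern$offset)) {
    stop("pattern must contain the M and M+2 offsets", call. = FALSE)
  }
  m0 <- pattern$intensity[pattern$offset == 0L][1L]
  m2 <- pattern$intensity[pattern$offset == 2L][1L]
  if (m0 <= 0) stop("monoisotopic peak has zero intensity", call. = FALSE)
  ratio <- m2 / m0
  ratio >= window[1L] && ratio <= window[2L]
}
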