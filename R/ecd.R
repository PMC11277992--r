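#' Construct a spectrum grid
#'
#' A spectrum grid pairs a strictly increasing wavelength axis (nm) with
#' circular-dichroism intensities Delta-epsilon (M-1 cm-1, signed), plus a
#' provenance tag.
#'
#' @param lambda_nm Strictly increasing wavelengths (nm, > 0).
#' @param delta_epsilon Delta-epsilon values, same length, no missing.
#' @param provenance One of "theoretical", "experimental", "scaled".
#' @param lambda_peak Wavelength used for peak scaling, if any.
#' @return A `spectrum_grid` data.frame.
#' @export
spectrum_grid <- function(lambda_nm, delta_epsilon,
                          provenance = c("theoretical", "experimental",
                                         "scaled"),
                          lambda_peak = NULL) {
  provenance <- match.arg(provenance)
  lambda_nm <- as.numeric(lambda_nm)
  delta_epsilon <- as.numeric(delta_epsilon)
  if (length(lambda_nm) != length(delta_epsilon)) {
    stop("wavelength and intensity vectors must have equal length",
         call. = FALSE)
  }
  if (length(lambda_nm) < 2L) stop("grid needs at least 2 points",
                                   call. = FALSE)
  if (anyNA(lambda_nm) || anyNA(delta_epsilon)) {
    stop("spectrum contains missing values", call. = FALSE)
  }
  if (any(lambda_nm <= 0) || any(diff(lambda_nm) <= 0)) {
    stop("wavelengths must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(
    data.frame(lambda_nm = lambda_nm, delta_epsilon = delta_epsilon),
    provenance = provenance,
    lambda_peak = lambda_peak,
    class = c("spectrum_grid", "data.frame")
  )
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat("<spectrum_grid> [", attr(x, "provenance"), "] ",
      nrow(x), " points, ", min(x$lambda_nm), "-", max(x$lambda_nm), " nm",
      sep = "")
  lp <- attr(x, "lambda_peak")
  if (!is.null(lp)) cat(", scaled at ", round(lp, 1), " nm", sep = "")
  cat("\n  delta_epsilon range: [",
      format(min(x$delta_epsilon), digits = 4), ", ",
      format(max(x$delta_epsilon), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Default wavelength grid for ECD work
#'
#' @param from,to,by Grid limits and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(from = 190, to = 400, by = 1) seq(from, to, by = by)

# Gaussian band-shape sum on the energy axis.  Delta-epsilon at photon
# energy E (eV) from transitions (E_i in eV, R_i in 1e-40 cgs):
#   de(E) = sum_i E_i * R_i / (22.97 * sqrt(pi) * zeta) *
#           exp(-((E - E_i) / zeta)^2)
# The dimensionless 1/22.97 comes from the cgs dipole-strength prefactor
# 2.297e-39 with R supplied in units of 1e-40; zeta is the 1/e half-width.
.band_shape <- function(E, E_i, R_i, zeta) {
  pref <- E_i * R_i / (22.97 * sqrt(pi) * zeta)
  out <- numeric(length(E))
  for (k in seq_along(E_i)) {
    out <- out + pref[k] * exp(-((E - E_i[k]) / zeta)^2)
  }
  out
}

#' Broaden stick transitions into a continuous ECD spectrum
#'
#' Each electronic transition (excitation energy `E_i` in eV, rotatory
#' strength `R_i` in 1e-40 cgs) contributes a Gaussian band centred at
#' `E_i` on the energy axis with 1/e half-width `zeta`; the sign of the
#' band is the sign of `R_i`.  The band-shape sum is evaluated at
#' `E = 1239.84193 / lambda` on the requested wavelength grid, then the UV
#' shift `delta_lambda` (nm) is applied on the wavelength axis by
#' re-evaluating the sum at the shifted wavelengths, so no interpolation
#' error is incurred.
#'
#' @param transitions data.frame with columns `E_eV` and `R_cgs40`.
#' @param zeta Gaussian bandwidth in eV (> 0); typical values 0.2-0.4.
#' @param grid Wavelength grid in nm (default [default_grid()]).
#' @param delta_lambda UV shift in nm applied to the computed spectrum
#'   (default 0).
#' @return A theoretical `spectrum_grid`.
#' @export
#' @examples
#' tr <- data.frame(E_eV = 4.275, R_cgs40 = 10)
#' sp <- stick_to_spectrum(tr, zeta = 0.36)
#' sp$lambda_nm[which.max(sp$delta_epsilon)]  # about 290 nm
stick_to_spectrum <- function(transitions, zeta, grid = default_grid(),
                              delta_lambda = 0) {
  stopifnot(is.data.frame(transitions),
            all(c("E_eV", "R_cgs40") %in% names(transitions)))
  if (nrow(transitions) == 0L) {
    stop("at least one transition is required", call. = FALSE)
  }
  if (!is.finite(zeta) || zeta <= 0) {
    stop("bandwidth zeta must be positive", call. = FALSE)
  }
  # shift on the wavelength axis: the value reported at lambda is the
  # unshifted spectrum at lambda - delta_lambda
  lam_eval <- grid - delta_lambda
  if (any(lam_eval <= 0)) {
    stop("UV shift pushes grid wavelengths to non-positive values",
         call. = FALSE)
  }
  E <- ev_from_nm(lam_eval)
  de <- .band_shape(E, transitions$E_eV, transitions$R_cgs40, zeta)
  spectrum_grid(grid, de, provenance = "theoretical")
}

#' Boltzmann-averaged ECD spectrum of a conformer ensemble
#'
#' Computes each conformer's broadened spectrum and averages them with the
#' supplied statistical weights (pointwise linear combination).
#'
#' @param ensemble A `conformer_ensemble` whose conformers have transitions.
#' @param weights Named weight vector covering exactly the ensemble's
#'   conformers (e.g. from [boltzmann_weights()] or
#'   [class_mixture_weights()]).  Default: Boltzmann weights.
#' @param zeta Gaussian bandwidth in eV.
#' @param grid Wavelength grid in nm.
#' @param delta_lambda UV shift in nm (default 0).
#' @return A theoretical `spectrum_grid`.
#' @export
ensemble_spectrum <- function(ensemble, weights = NULL, zeta,
                              grid = default_grid(), delta_lambda = 0) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  ids <- ensemble$conformers$id
  if (is.null(weights)) weights <- boltzmann_weights(ensemble)
  if (is.null(names(weights)) || !setequal(names(weights), ids) ||
      length(weights) != length(ids)) {
    stop("weights must cover exactly the ensemble's conformers",
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weights must sum to 1", call. = FALSE)
  }
  total <- numeric(length(grid))
  for (id in ids) {
    tr <- ensemble$transitions[ensemble$transitions$id == id, ,
                               drop = FALSE]
    if (nrow(tr) == 0L) {
      stop("conformer '", id, "' has no transitions", call. = FALSE)
    }
    sp <- stick_to_spectrum(tr, zeta, grid, delta_lambda)
    total <- total + weights[[id]] * sp$delta_epsilon
  }
  spectrum_grid(grid, total, provenance = "theoretical")
}

#' Shift a spectrum along the wavelength axis
#'
#' Returns the spectrum translated by `delta_lambda` nm:
#' `de_shifted(lambda) = de(lambda - delta_lambda)`, evaluated on the
#' original grid by linear interpolation and edge-held beyond the original
#' coverage.  For theoretical spectra prefer the `delta_lambda` argument of
#' [stick_to_spectrum()] / [ensemble_spectrum()], which re-evaluates the
#' band-shape sum exactly.
#'
#' @param spectrum A `spectrum_grid`.
#' @param delta_lambda Shift in nm (positive moves bands to the red).
#' @return A `spectrum_grid` on the same wavelength axis.
#' @export
apply_uv_shift <- function(spectrum, delta_lambda) {
  stopifnot(inherits(spectrum, "spectrum_grid"))
  if (delta_lambda == 0) return(spectrum)
  shifted <- stats::approx(x = spectrum$lambda_nm, y = spectrum$delta_epsilon,
                           xout = spectrum$lambda_nm - delta_lambda,
                           method = "linear", rule = 2)$y
  spectrum_grid(spectrum$lambda_nm, shifted,
                provenance = attr(spectrum, "provenance"))
}

#' Scale a spectrum by its positive characteristic band
#'
#' Divides the whole spectrum by the absolute intensity of the positive
#' local maximum nearest the requested reference wavelength, so the scaled
#' curve has value +1 there.  This removes unknown amplitude calibration
#' (concentration, path length) before comparing experimental and
#' theoretical curves; scaling is idempotent and invariant under
#' multiplication of the input by any positive constant.
#'
#' @param spectrum A `spectrum_grid`.
#' @param reference_band Approximate wavelength of the positive
#'   characteristic band in nm (default 290).
#' @param search_halfwidth Half-width of the peak search window in nm
#'   (default 25).
#' @return A `spectrum_grid` with provenance "scaled" and attribute
#'   `lambda_peak` recording the peak used.
#' @export
#' @examples
#' sp <- stick_to_spectrum(data.frame(E_eV = 4.275, R_cgs40 = 10),
#'                         zeta = 0.36)
#' sc <- scale_spectrum(sp)
#' max(sc$delta_epsilon)  # 1
scale_spectrum <- function(spectrum, reference_band = 290,
                           search_halfwidth = 25) {
  stopifnot(inherits(spectrum, "spectrum_grid"))
  lam <- spectrum$lambda_nm
  de <- spectrum$delta_epsilon
  lo <- reference_band - search_halfwidth
  hi <- reference_band + search_halfwidth
  in_window <- which(lam >= lo & lam <= hi)
  if (length(in_window) == 0L) {
    stop("no grid points in the peak search window [", lo, ", ", hi, "] nm",
         call. = FALSE)
  }
  # local maxima: interior points not lower than both neighbours; window
  # edges count only against their inside neighbour
  n <- length(lam)
  is_locmax <- function(i) {
    left_ok <- i == 1L || de[i] >= de[i - 1L]
    right_ok <- i == n || de[i] >= de[i + 1L]
    left_ok && right_ok
  }
  cand <- in_window[vapply(in_window, is_locmax, logical(1))]
  cand <- cand[de[cand] > 0]
  if (length(cand) == 0L) {
    stop("no positive local maximum in the search window [", lo, ", ", hi,
         "] nm; cannot anchor the scaling", call. = FALSE)
  }
  peak <- cand[which.max(de[cand])]
  spectrum_grid(lam, de / abs(de[peak]), provenance = "scaled",
                lambda_peak = lam[peak])
}

#' Cosine similarity of two spectra on a common window
#'
#' Resamples both spectra onto the intersection of their wavelength
#' coverage restricted to `window` and returns the cosine of the angle
#' between the two intensity vectors: +1 for proportional curves of the
#' same sign, -1 for mirror-image (enantiomeric) curves, 0 for orthogonal
#' ones.  The metric is invariant to positive rescaling of either input.
#'
#' @param a,b `spectrum_grid` objects with overlapping coverage.
#' @param window Wavelength window `c(lo, hi)` in nm; default
#'   `c(200, Inf)`, i.e. everything red of 200 nm.
#' @param n_points Number of resampling points (default 256).
#' @return Similarity in [-1, 1].
#' @export
compare_spectra <- function(a, b, window = c(200, Inf), n_points = 256L) {
  stopifnot(inherits(a, "spectrum_grid"), inherits(b, "spectrum_grid"))
  lo <- max(min(a$lambda_nm), min(b$lambda_nm), window[1L])
  hi <- min(max(a$lambda_nm), max(b$lambda_nm), window[2L])
  if (!(hi > lo)) {
    stop("spectra have no overlapping wavelength coverage in the window",
         call. = FALSE)
  }
  common <- seq(lo, hi, length.out = n_points)
  va <- stats::approx(a$lambda_nm, a$delta_epsilon, xout = common,
                      method = "linear")$y
  vb <- stats::approx(b$lambda_nm, b$delta_epsilon, xout = common,
                      method = "linear")$y
  na_ <- sqrt(sum(va^2))
  nb_ <- sqrt(sum(vb^2))
  if (na_ == 0 || nb_ == 0) {
    stop("a spectrum is identically zero on the comparison window",
         call. = FALSE)
  }
  sum(va * vb) / (na_ * nb_)
}

#' Decide between a modeled structure and its enantiomer
#'
#' Compares an experimental ECD spectrum against the theoretical spectrum
#' of the modeled configuration and against its mirror image (every
#' intensity negated, as an enantiomer gives).  Returns `"as-modeled"` when
#' the modeled spectrum matches at least as well, `"mirror"` otherwise;
#' ties within 1e-12 are reported as undecidable.
#'
#' @param theoretical Theoretical `spectrum_grid` (scaled or not; the
#'   similarity metric is amplitude-invariant).
#' @param experimental Experimental `spectrum_grid`.
#' @param window Comparison window in nm (default `c(200, Inf)`).
#' @return List with elements `label` ("as-modeled", "mirror" or
#'   "undecidable"), `score` (the winning similarity) and `similarity`
#'   (named vector with both similarities).
#' @export
assign_enantiomer <- function(theoretical, experimental,
                              window = c(200, Inf)) {
  s_direct <- compare_spectra(theoretical, experimental, window)
  mirror <- spectrum_grid(theoretical$lambda_nm,
                          -theoretical$delta_epsilon,
                          provenance = attr(theoretical, "provenance"))
  s_mirror <- compare_spectra(mirror, experimental, window)
  sims <- c("as-modeled" = s_direct, "mirror" = s_mirror)
  if (abs(s_direct - s_mirror) < 1e-12) {
    return(list(label = "undecidable", score = max(sims),
                similarity = sims))
  }
  winner <- names(sims)[which.max(sims)]
  list(label = winner, score = max(sims), similarity = sims)
}
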