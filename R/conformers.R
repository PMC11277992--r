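#' Gas constant in kcal mol-1 K-1
#' @keywords internal
.R_kcal <- 1.98720425e-3

#' Construct a conformer ensemble
#'
#' An ensemble holds the conformers of one compound: identifiers, relative
#' Gibbs free energies (kcal/mol, 0 for the most stable), an optional
#' dihedral-class label per conformer (e.g. "0" vs "180" for the two rotamer
#' families of a ring substituent), and the electronic transitions of each
#' conformer (excitation energy in eV, rotatory strength in 1e-40 cgs).
#'
#' @param conformers data.frame with columns `id`, `dG_kcal_mol` and
#'   optionally `theta1_class` (character or NA).
#' @param transitions data.frame with columns `id` (matching a conformer),
#'   `E_eV` (> 0) and `R_cgs40`.  Transitions supplied as wavelengths can be
#'   converted with [ev_from_nm()].
#' @param temperature Temperature in K for Boltzmann weighting
#'   (default 298.15).
#' @return A `conformer_ensemble` object.
#' @export
conformer_ensemble <- function(conformers, transitions = NULL,
                               temperature = 298.15) {
  stopifnot(is.data.frame(conformers),
            all(c("id", "dG_kcal_mol") %in% names(conformers)))
  conformers$id <- as.character(conformers$id)
  if (anyDuplicated(conformers$id)) {
    stop("conformer identifiers must be unique", call. = FALSE)
  }
  if (nrow(conformers) == 0L) stop("ensemble is empty", call. = FALSE)
  if (any(!is.finite(conformers$dG_kcal_mol)) ||
      any(conformers$dG_kcal_mol < 0)) {
    stop("relative Gibbs free energies must be finite and >= 0",
         call. = FALSE)
  }
  if (min(conformers$dG_kcal_mol) != 0) {
    stop("the most stable conformer must have dG = 0 (relative energies)",
         call. = FALSE)
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive", call. = FALSE)
  }
  if (!"theta1_class" %in% names(conformers)) {
    conformers$theta1_class <- NA_character_
  }
  conformers$theta1_class <- as.character(conformers$theta1_class)
  if (is.null(transitions)) {
    transitions <- data.frame(id = character(0), E_eV = numeric(0),
                              R_cgs40 = numeric(0))
  }
  stopifnot(is.data.frame(transitions),
            all(c("id", "E_eV", "R_cgs40") %in% names(transitions)))
  transitions$id <- as.character(transitions$id)
  if (nrow(transitions) > 0L) {
    orphan <- setdiff(transitions$id, conformers$id)
    if (length(orphan) > 0L) {
      stop("transitions reference unknown conformer(s): ",
           paste(unique(orphan), collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(transitions$E_eV)) || any(transitions$E_eV <= 0)) {
      stop("excitation energies must be positive", call. = FALSE)
    }
    if (any(!is.finite(transitions$R_cgs40))) {
      stop("rotatory strengths must be finite", call. = FALSE)
    }
  }
  structure(
    list(conformers = conformers[, c("id", "dG_kcal_mol", "theta1_class")],
         transitions = transitions[, c("id", "E_eV", "R_cgs40")],
         temperature = temperature),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", nrow(x$conformers), " conformer(s), ",
      nrow(x$transitions), " transition(s), T = ", x$temperature, " K\n",
      sep = "")
  cat("  dG range: [", min(x$conformers$dG_kcal_mol), ", ",
      max(x$conformers$dG_kcal_mol), "] kcal/mol\n", sep = "")
  cls <- unique(stats::na.omit(x$conformers$theta1_class))
  if (length(cls) > 0L) {
    cat("  dihedral classes:", paste(cls, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Boltzmann statistical weights of an ensemble
#'
#' Population fraction of each conformer from its relative Gibbs free
#' energy: `g_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)` with RT in
#' kcal/mol (R = 1.98720425e-3 kcal mol-1 K-1).
#'
#' @param ensemble A `conformer_ensemble`.
#' @param temperature Optional override of the ensemble temperature (K).
#' @return Named numeric vector of weights summing to 1, in conformer order.
#' @export
#' @examples
#' ens <- conformer_ensemble(data.frame(id = c("a", "b"),
#'                                      dG_kcal_mol = c(0, 1)))
#' boltzmann_weights(ens)  # 0.8439, 0.1561 at 298.15 K
boltzmann_weights <- function(ensemble, temperature = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  temp <- if (is.null(temperature)) ensemble$temperature else temperature
  if (!is.finite(temp) || temp <= 0) {
    stop("temperature must be positive", call. = FALSE)
  }
  dG <- ensemble$conformers$dG_kcal_mol
  w <- exp(-dG / (.R_kcal * temp))
  stats::setNames(w / sum(w), ensemble$conformers$id)
}

#' Filter an ensemble by relative Gibbs free energy
#'
#' Keeps the conformers with `dG <= cutoff` (boundary inclusive) together
#' with their transitions.  The most stable conformer (dG = 0) always
#' survives, so the result is never empty; weights recomputed on the
#' survivors renormalize to 1.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param cutoff Energy cutoff in kcal/mol (default 4).
#' @return A `conformer_ensemble` containing the retained conformers.
#' @export
select_conformers <- function(ensemble, cutoff = 4.0) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0) {
    stop("cutoff must be positive", call. = FALSE)
  }
  keep <- ensemble$conformers$dG_kcal_mol <= cutoff
  conf <- ensemble$conformers[keep, , drop = FALSE]
  trans <- ensemble$transitions[ensemble$transitions$id %in% conf$id, ,
                                drop = FALSE]
  rownames(conf) <- NULL
  rownames(trans) <- NULL
  conformer_ensemble(conf, trans, ensemble$temperature)
}

#' Reweight an ensemble to imposed dihedral-class totals
#'
#' Conformational modeling sometimes fixes the total population of each
#' rotamer family (e.g. the two dihedral classes "0" and "180" mixed as
#' 40:60) instead of trusting computed energies across families.  Within
#' each class the conformers keep their Boltzmann proportions; the class
#' totals are then imposed, so the overall weights sum to 1.
#'
#' @param ensemble A `conformer_ensemble` whose conformers all carry a
#'   `theta1_class` label present in `class_totals`.
#' @param class_totals Named numeric vector, class label -> total fraction;
#'   must sum to 1.  A class with a nonzero total must have members.
#' @param temperature Optional temperature override (K).
#' @return Named numeric vector of weights summing to 1.
#' @export
#' @examples
#' ens <- conformer_ensemble(data.frame(
#'   id = c("a", "b", "c"), dG_kcal_mol = c(0, 1, 0),
#'   theta1_class = c("0", "0", "180")))
#' class_mixture_weights(ens, c("0" = 0.4, "180" = 0.6))
class_mixture_weights <- function(ensemble, class_totals,
                                  temperature = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (is.null(names(class_totals)) || any(!nzchar(names(class_totals)))) {
    stop("class_totals must be named by dihedral class", call. = FALSE)
  }
  if (abs(sum(class_totals) - 1) > 1e-9) {
    stop("class totals must sum to 1", call. = FALSE)
  }
  labels <- ensemble$conformers$theta1_class
  if (anyNA(labels)) {
    bad <- ensemble$conformers$id[is.na(labels)]
    stop("conformer(s) without a dihedral-class label: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(labels, names(class_totals))
  if (length(unknown) > 0L) {
    stop("dihedral class(es) not in class_totals: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(names(class_totals)[class_totals > 0], labels)
  if (length(empty) > 0L) {
    stop("class(es) with nonzero total but no members: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  g <- boltzmann_weights(ensemble, temperature)
  out <- numeric(length(g))
  names(out) <- names(g)
  for (cls in names(class_totals)) {
    members <- labels == cls
    if (!any(members)) next
    out[members] <- g[members] / sum(g[members]) * class_totals[[cls]]
  }
  out
}

#' Convert between excitation energy (eV) and wavelength (nm)
#'
#' Uses the conversion constant hc = 1239.84193 eV nm.
#'
#' @param nm Wavelength(s) in nm.
#' @return Energy in eV.
#' @export
ev_from_nm <- function(nm) 1239.84193 / nm

#' @rdname ev_from_nm
#' @param eV Energy(ies) in eV.
#' @export
nm_from_ev <- function(eV) 1239.84193 / eV
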