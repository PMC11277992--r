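#' Parse a flat molecular-formula string
#'
#' Accepts formulas of the form repeated `ElementSymbol` + optional count
#' (e.g. `"C15H24O3"`).  Charges, parentheses, hydrates and isotope labels
#' are not part of the grammar.  Repeated element symbols are summed.
#'
#' @param text Formula string.
#' @return A `molecular_formula`: a named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C15H24O3")
#' parse_formula("H2O")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  text <- trimws(text)
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  if (length(matched) == 0L || paste(matched, collapse = "") != text) {
    stop("cannot parse formula '", text,
         "': expected element symbols with optional counts", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in matched) {
    sym <- sub("[0-9]*$", "", tok)
    n_str <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n_str)) as.integer(n_str) else 1L
    if (is.null(.element_table[[sym]])) {
      stop("unknown element symbol '", sym, "' in formula '", text, "'",
           call. = FALSE)
    }
    counts[sym] <- if (is.na(counts[sym][1L])) n else counts[[sym]] + n
  }
  molecular_formula(counts)
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector or list, element symbol -> count.
#'   Zero counts are dropped.
#' @return A `molecular_formula` object.
#' @export
molecular_formula <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by element symbol", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.element_table))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  keep <- counts > 0L
  out <- counts[keep]
  if (length(out) == 0L) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  structure(out, class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format_formula(x), "  (",
      format(round(monoisotopic_mass(x), 4), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

#' Render a molecular formula in Hill order
#'
#' Hill convention: carbon first, then hydrogen, then remaining elements
#' alphabetically (all alphabetical when no carbon is present).
#'
#' @param formula A `molecular_formula`.
#' @return Formula string, e.g. `"C15H24O3"`.
#' @export
format_formula <- function(formula) {
  stopifnot(inherits(formula, "molecular_formula"))
  syms <- names(formula)
  ord <- if ("C" %in% syms) {
    c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    sort(syms)
  }
  paste0(vapply(ord, function(s) {
    n <- formula[[s]]
    if (n == 1L) s else paste0(s, n)
  }, character(1)), collapse = "")
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the monoisotopic atomic mass; no charge
#' or electron handling (see [adduct_mz()] for ions).
#'
#' @param formula A `molecular_formula` or a formula string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C14H22O3")
monoisotopic_mass <- function(formula) {
  formula <- as_formula(formula)
  sum(vapply(names(formula),
             function(s) .element_table[[s]]$monoisotopic, numeric(1)) *
        as.numeric(formula))
}

as_formula <- function(formula) {
  if (is.character(formula)) parse_formula(formula)
  else if (inherits(formula, "molecular_formula")) formula
  else stop("expected a molecular_formula or formula string", call. = FALSE)
}

# Registry of ESI adduct species.  delta: atoms gained (negative = lost)
# relative to the neutral molecule M; charge: +1 or -1.  The electron-mass
# correction is always applied: a cation is missing one electron, an anion
# carries one extra.
.default_adducts <- list(
  "[M+H]+"  = list(delta = c(H = 1L),  charge = +1L),
  "[M+Na]+" = list(delta = c(Na = 1L), charge = +1L),
  "[M+K]+"  = list(delta = c(K = 1L),  charge = +1L),
  "[M-H]-"  = list(delta = c(H = -1L), charge = -1L),
  "[M+Cl]-" = list(delta = c(Cl = 1L), charge = -1L)
)

# Typographic minus/dash variants appear in the literature; normalize so
# "[M−H]−" and "[M-H]-" name the same adduct.
.normalize_adduct_name <- function(name) {
  gsub("[−‐–—]", "-", name)
}

#' List the registered ESI adducts
#'
#' @return Character vector of adduct names, e.g. `"[M+Na]+"`.
#' @export
adduct_names <- function() names(.default_adducts)

#' m/z of an ESI adduct ion
#'
#' Computes `(mass(M) + mass(delta) - charge * m_e) / |charge|`, i.e. the
#' electron-mass correction is always applied: cations ([M+H]+, [M+Na]+)
#' are lighter by one electron, anions ([M-H]-, [M+Cl]-) heavier by one.
#' Unicode minus signs in the adduct name are accepted.
#'
#' @param formula A `molecular_formula` or formula string for the neutral
#'   molecule M.
#' @param adduct Adduct name; one of [adduct_names()].
#' @return m/z in Da per unit charge, full precision (round to 4 decimals
#'   for presentation, as mass-spectrometry reports do).
#' @export
#' @examples
#' round(adduct_mz("C14H22O3", "[M+Na]+"), 4)  # 261.1461
#' round(adduct_mz("C14H22O3", "[M-H]-"), 4)   # 237.1496
adduct_mz <- function(formula, adduct) {
  formula <- as_formula(formula)
  spec <- .default_adducts[[.normalize_adduct_name(adduct)]]
  if (is.null(spec)) {
    stop("unknown adduct '", adduct, "'; registered adducts: ",
         paste(adduct_names(), collapse = ", "), call. = FALSE)
  }
  delta_mass <- sum(vapply(names(spec$delta),
                           function(s) .element_table[[s]]$monoisotopic,
                           numeric(1)) * as.numeric(spec$delta))
  (monoisotopic_mass(formula) + delta_mass -
      spec$charge * .electron_mass) / abs(spec$charge)
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (> 0).
#' @param calculated Calculated m/z (> 0).
#' @return `1e6 * (observed - calculated) / calculated`.
#' @export
#' @examples
#' ppm_error(261.1469, adduct_mz("C14H22O3", "[M+Na]+"))
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(observed)) || any(!is.finite(calculated)) ||
      any(observed <= 0) || any(calculated <= 0)) {
    stop("observed and calculated m/z must be positive finite numbers",
         call. = FALSE)
  }
  1e6 * (observed - calculated) / calculated
}

#' Degrees of unsaturation (ring plus double-bond equivalents)
#'
#' `DBE = 1 + sum(n_i * (v_i - 2) / 2)` with standard valences (C 4, N/P 3,
#' O/S 2, H/halogen 1).  Integer-valued for even-electron neutral formulas.
#'
#' @param formula A `molecular_formula` or formula string.
#' @return DBE (numeric; an integer for ordinary neutral molecules).
#' @export
#' @examples
#' degrees_of_unsaturation("C15H24O3")  # 4
degrees_of_unsaturation <- function(formula) {
  formula <- as_formula(formula)
  v <- vapply(names(formula),
              function(s) as.numeric(.element_table[[s]]$valence), numeric(1))
  1 + sum(as.numeric(formula) * (v - 2) / 2)
}
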