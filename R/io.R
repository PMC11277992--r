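#' Read and write conformer ensembles as TSV
#'
#' The ensemble file is a single TSV with a `record` column distinguishing
#' conformer rows from transition rows.  Conformer rows fill
#' `conformer_id`, `dG_kcal_mol` and optionally `theta1_class`; transition
#' rows fill `conformer_id`, `E_eV` and `R_cgs40`.  Numeric values are
#' written with enough digits to round-trip to better than 1e-9.  A header
#' comment line records the temperature.
#'
#' @param path File path.
#' @return `read_ensemble()` returns a `conformer_ensemble`.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  header_comments <- grep("^#", lines, value = TRUE)
  temperature <- 298.15
  temp_line <- grep("^#\\s*temperature_K\\s*=", header_comments,
                    value = TRUE)
  if (length(temp_line) > 0L) {
    temperature <- as.numeric(sub("^#\\s*temperature_K\\s*=\\s*", "",
                                  temp_line[1L]))
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("record", "conformer_id", "dG_kcal_mol", "theta1_class",
                "E_eV", "R_cgs40")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("ensemble file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(x, col, rows) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & nzchar(x))
    if (length(bad) > 0L) {
      stop("non-numeric value in column '", col, "' at data row ",
           rows[bad[1L]], " of ", path, call. = FALSE)
    }
    out
  }
  rows <- seq_len(nrow(tab))
  is_conf <- tab$record == "conformer"
  is_tran <- tab$record == "transition"
  if (any(!is_conf & !is_tran)) {
    bad <- which(!is_conf & !is_tran)[1L]
    stop("unknown record type '", tab$record[bad], "' at data row ", bad,
         " of ", path, call. = FALSE)
  }
  conf <- data.frame(
    id = tab$conformer_id[is_conf],
    dG_kcal_mol = num(tab$dG_kcal_mol[is_conf], "dG_kcal_mol",
                      rows[is_conf]),
    theta1_class = ifelse(nzchar(tab$theta1_class[is_conf]),
                          tab$theta1_class[is_conf], NA_character_)
  )
  trans <- data.frame(
    id = tab$conformer_id[is_tran],
    E_eV = num(tab$E_eV[is_tran], "E_eV", rows[is_tran]),
    R_cgs40 = num(tab$R_cgs40[is_tran], "R_cgs40", rows[is_tran])
  )
  conformer_ensemble(conf, trans, temperature)
}

#' @rdname read_ensemble
#' @param ensemble A `conformer_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  conf <- ensemble$conformers
  trans <- ensemble$transitions
  lines <- c(
    sprintf("# temperature_K=%s", fmt(ensemble$temperature)),
    paste("record", "conformer_id", "dG_kcal_mol", "theta1_class",
          "E_eV", "R_cgs40", sep = "\t"),
    sprintf("conformer\t%s\t%s\t%s\t\t", conf$id, fmt(conf$dG_kcal_mol),
            ifelse(is.na(conf$theta1_class), "", conf$theta1_class)),
    if (nrow(trans) > 0L) {
      sprintf("transition\t%s\t\t\t%s\t%s", trans$id, fmt(trans$E_eV),
              fmt(trans$R_cgs40))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write ECD spectra as CSV
#'
#' Two-column CSV (`lambda_nm, delta_epsilon`) with `#` header comments
#' recording provenance and, for scaled spectra, the anchoring peak
#' wavelength.  Comments are preserved on a write/read round-trip.
#'
#' @param path File path.
#' @return `read_spectrum()` returns a `spectrum_grid`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  provenance <- "experimental"
  prov_line <- grep("^#\\s*provenance\\s*=", comments, value = TRUE)
  if (length(prov_line) > 0L) {
    provenance <- trimws(sub("^#\\s*provenance\\s*=", "", prov_line[1L]))
  } else if (any(grepl("^#\\s*scaled\\s*=\\s*true", comments))) {
    provenance <- "scaled"
  }
  lambda_peak <- NULL
  peak_line <- grep("^#\\s*lambda_peak_nm\\s*=", comments, value = TRUE)
  if (length(peak_line) > 0L) {
    lambda_peak <- as.numeric(sub("^#\\s*lambda_peak_nm\\s*=", "",
                                  peak_line[1L]))
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  if (!all(c("lambda_nm", "delta_epsilon") %in% names(tab))) {
    stop("spectrum file ", path,
         " must have columns lambda_nm, delta_epsilon", call. = FALSE)
  }
  tab$lambda_nm <- suppressWarnings(as.numeric(tab$lambda_nm))
  tab$delta_epsilon <- suppressWarnings(as.numeric(tab$delta_epsilon))
  bad <- which(!is.finite(tab$lambda_nm) | !is.finite(tab$delta_epsilon))
  if (length(bad) > 0L) {
    stop("non-numeric or missing value at data row ", bad[1L], " of ",
         path, call. = FALSE)
  }
  spectrum_grid(tab$lambda_nm, tab$delta_epsilon,
                provenance = provenance, lambda_peak = lambda_peak)
}

#' @rdname read_spectrum
#' @param spectrum A `spectrum_grid`.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum_grid"))
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  provenance <- attr(spectrum, "provenance")
  comments <- sprintf("# provenance=%s", provenance)
  if (identical(provenance, "scaled")) {
    comments <- c(comments, "# scaled=true")
    lp <- attr(spectrum, "lambda_peak")
    if (!is.null(lp)) {
      comments <- c(comments, sprintf("# lambda_peak_nm=%s", fmt(lp)))
    }
  }
  lines <- c(comments, "lambda_nm,delta_epsilon",
             sprintf("%s,%s", fmt(spectrum$lambda_nm),
                     fmt(spectrum$delta_epsilon)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write Mosher shift tables as CSV
#'
#' Columns `proton, side, delta_S_ppm, delta_R_ppm`; an optional `#`
#' comment records the stereocenter label.
#'
#' @param path File path.
#' @return `read_mosher()` returns a `mosher_table`.
#' @export
read_mosher <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  stereocenter <- NA_character_
  sc_line <- grep("^#\\s*stereocenter\\s*=", comments, value = TRUE)
  if (length(sc_line) > 0L) {
    stereocenter <- trimws(sub("^#\\s*stereocenter\\s*=", "", sc_line[1L]))
  }
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  required <- c("proton", "side", "delta_S_ppm", "delta_R_ppm")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("Mosher file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$delta_S_ppm))) |
                 !is.finite(suppressWarnings(as.numeric(tab$delta_R_ppm))))
  if (length(bad) > 0L) {
    stop("non-numeric shift at data row ", bad[1L], " of ", path,
         call. = FALSE)
  }
  mosher_table(tab, stereocenter = stereocenter)
}

#' @rdname read_mosher
#' @param table A `mosher_table`.
#' @export
write_mosher <- function(table, path) {
  stopifnot(inherits(table, "mosher_table"))
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  comments <- character(0)
  sc <- attr(table, "stereocenter")
  if (!is.na(sc)) comments <- sprintf("# stereocenter=%s", sc)
  lines <- c(comments, "proton,side,delta_S_ppm,delta_R_ppm",
             sprintf("%s,%s,%s,%s", table$proton, table$side,
                     fmt(table$delta_S_ppm), fmt(table$delta_R_ppm)))
  writeLines(lines, path)
  invisible(path)
}

#' Summarise HRESIMS support for a molecular formula
#'
#' Convenience wrapper used in reports: for a formula and a set of
#' observed adduct peaks, tabulates calculated m/z (4 decimals), signed
#' ppm error (1 decimal), the degrees of unsaturation and the simulated
#' M+2/M ratio with the one-chlorine verdict.
#'
#' @param formula Formula string or `molecular_formula`.
#' @param observed Named numeric vector of observed m/z keyed by adduct
#'   name, e.g. `c("[M+Na]+" = 261.1469)`.
#' @return List with `formula`, `dbe`, `m2_ratio`, `chlorine`, and a
#'   data.frame `peaks` (adduct, mz_calcd, mz_obs, ppm).
#' @export
#' @examples
#' hresims_report("C14H22O3", c("[M+Na]+" = 261.1469, "[M-H]-" = 237.1495))
hresims_report <- function(formula, observed = numeric(0)) {
  formula <- as_formula(formula)
  pat <- isotope_pattern(formula)
  m2 <- pat$intensity[pat$offset == 2L] / pat$intensity[pat$offset == 0L]
  peaks <- data.frame(adduct = character(0), mz_calcd = numeric(0),
                      mz_obs = numeric(0), ppm = numeric(0))
  if (length(observed) > 0L) {
    adds <- names(observed)
    calcd <- vapply(adds, function(a) adduct_mz(formula, a), numeric(1))
    peaks <- data.frame(
      adduct = adds,
      mz_calcd = round(calcd, 4),
      mz_obs = as.numeric(observed),
      ppm = round(ppm_error(as.numeric(observed), calcd), 1),
      row.names = NULL
    )
  }
  list(formula = format_formula(formula),
       dbe = degrees_of_unsaturation(formula),
       m2_ratio = m2,
       chlorine = chlorine_signature(pat),
       peaks = peaks)
}
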