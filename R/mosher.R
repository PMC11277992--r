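#' Construct a Mosher ester shift table
#'
#' Holds the proton chemical shifts of the (S)- and (R)-MTPA esters of a
#' secondary alcohol, with each proton assigned to one of the two
#' substituent branches flanking the carbinol center.  Convention for the
#' side labels: side "A" is the branch that carries negative
#' delta-delta = delta_S - delta_R when the center is R under the MTPA
#' plane model (Ohtani convention); side "B" is the other branch.  The
#' geometric step of placing protons on sides is the user's, from the
#' drawn structure.
#'
#' @param protons data.frame with columns `proton` (unique labels, e.g.
#'   "H-10"), `side` ("A" or "B"), `delta_S_ppm`, `delta_R_ppm` (shifts in
#'   ppm, each in (-1, 16)).
#' @param stereocenter Optional label of the carbinol center, e.g. "C-9".
#' @return A `mosher_table` data.frame.
#' @export
mosher_table <- function(protons, stereocenter = NA_character_) {
  stopifnot(is.data.frame(protons),
            all(c("proton", "side", "delta_S_ppm", "delta_R_ppm") %in%
                  names(protons)))
  protons$proton <- as.character(protons$proton)
  protons$side <- as.character(protons$side)
  if (anyDuplicated(protons$proton)) {
    stop("proton labels must be unique", call. = FALSE)
  }
  if (!all(protons$side %in% c("A", "B"))) {
    stop("side labels must be 'A' or 'B'", call. = FALSE)
  }
  if (!all(c("A", "B") %in% protons$side)) {
    stop("both sides of the stereocenter must carry at least one proton",
         call. = FALSE)
  }
  shifts <- c(protons$delta_S_ppm, protons$delta_R_ppm)
  if (anyNA(shifts) || any(shifts <= -1) || any(shifts >= 16)) {
    stop("chemical shifts must lie in (-1, 16) ppm", call. = FALSE)
  }
  structure(
    protons[, c("proton", "side", "delta_S_ppm", "delta_R_ppm")],
    stereocenter = stereocenter,
    class = c("mosher_table", "data.frame")
  )
}

#' Per-proton chemical-shift differences of a Mosher table
#'
#' @param table A `mosher_table`.
#' @return Named numeric vector: proton label -> delta-delta
#'   (delta_S - delta_R, ppm).
#' @export
#' @examples
#' tb <- mosher_table(data.frame(
#'   proton = c("H-8", "H-10"), side = c("A", "B"),
#'   delta_S_ppm = c(1.70, 2.90), delta_R_ppm = c(1.76, 2.83)))
#' delta_delta(tb)
delta_delta <- function(table) {
  stopifnot(inherits(table, "mosher_table"))
  stats::setNames(table$delta_S_ppm - table$delta_R_ppm, table$proton)
}

#' Call the carbinol configuration from a Mosher table
#'
#' Under the MTPA plane model with the side convention of
#' [mosher_table()], an R center places negative delta-delta on side A and
#' positive on side B; an S center gives the reverse pattern.  The call is
#' the hypothesis matching the larger fraction of sign-informative protons.
#' Protons with |delta-delta| below `zero_tol` are uninformative and
#' excluded from the count; the call is withheld (`configuration = NA`)
#' when the best fraction is below `min_consistency`, and a tie between the
#' two hypotheses is reported as undecidable.
#'
#' @param table A `mosher_table`.
#' @param min_consistency Minimum fraction of sign-matching protons for a
#'   call (default 0.8).
#' @param zero_tol Protons with |delta-delta| < `zero_tol` ppm are treated
#'   as zero and excluded (default 0.005, below 2-decimal shift
#'   resolution).
#' @return A `configuration_call` list: `configuration` ("R", "S" or NA),
#'   `decided` (logical), `consistency` (winning fraction), `fractions`
#'   (named vector for both hypotheses), `delta_delta` (per-proton vector),
#'   `n_informative`, and `reason` when no call is made.
#' @export
#' @examples
#' tb <- mosher_table(data.frame(
#'   proton = c("H-8", "H-15", "H-10", "H-11"),
#'   side = c("A", "A", "B", "B"),
#'   delta_S_ppm = c(1.70, 0.88, 2.90, 5.60),
#'   delta_R_ppm = c(1.76, 0.93, 2.83, 5.52)))
#' assign_configuration(tb)  # R, consistency 1
assign_configuration <- function(table, min_consistency = 0.8,
                                 zero_tol = 0.005) {
  stopifnot(inherits(table, "mosher_table"))
  dd <- delta_delta(table)
  side <- table$side
  informative <- abs(dd) >= zero_tol
  call_obj <- function(configuration, decided, consistency, fractions,
                       reason = NA_character_) {
    structure(list(configuration = configuration, decided = decided,
                   consistency = consistency, fractions = fractions,
                   delta_delta = dd,
                   n_informative = sum(informative),
                   stereocenter = attr(table, "stereocenter"),
                   reason = reason),
              class = "configuration_call")
  }
  if (!any(informative)) {
    return(call_obj(NA_character_, FALSE, NA_real_,
                    c(R = NA_real_, S = NA_real_),
                    "no proton has a resolvable delta-delta"))
  }
  s <- sign(dd[informative])
  sd <- side[informative]
  # hypothesis R: negative on side A, positive on side B
  match_R <- sum((sd == "A" & s < 0) | (sd == "B" & s > 0))
  match_S <- sum((sd == "A" & s > 0) | (sd == "B" & s < 0))
  n <- sum(informative)
  fractions <- c(R = match_R / n, S = match_S / n)
  if (match_R == match_S) {
    return(call_obj(NA_character_, FALSE, max(fractions), fractions,
                    "tie between the R and S hypotheses"))
  }
  winner <- names(fractions)[which.max(fractions)]
  best <- max(fractions)
  if (best < min_consistency) {
    return(call_obj(NA_character_, FALSE, best, fractions,
                    sprintf("consistency %.2f below threshold %.2f",
                            best, min_consistency)))
  }
  call_obj(winner, TRUE, best, fractions)
}

#' @export
print.configuration_call <- function(x, ...) {
  sc <- x$stereocenter
  label <- if (is.na(sc)) "stereocenter" else sc
  if (x$decided) {
    cat("<configuration_call> ", label, ": ", x$configuration,
        " (consistency ", format(x$consistency, digits = 3), ", ",
        x$n_informative, " informative protons)\n", sep = "")
  } else {
    cat("<configuration_call> ", label, ": no call (", x$reason, ")\n",
        sep = "")
  }
  invisible(x)
}
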