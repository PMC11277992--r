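#' Generate a synthetic conformer ensemble with ECD transitions
#'
#' Emulates the conformer ensembles that quantum-chemistry conformational
#' searches of flexible decalin polyketides produce: one dominant
#' hydrogen-bond-stabilized conformer at dG = 0, the rest spread over an
#' exponential-like energy ladder truncated at twice the usual 4 kcal/mol
#' selection cutoff (so the cutoff is actually exercised), and per-conformer
#' electronic transitions with energies uniform in a deep-UV window and
#' rotatory strengths from a centred normal distribution.  Every conformer
#' additionally carries one positive-rotatory-strength transition at
#' 4.275 eV (about 290 nm), spectrally isolated from the random deep-UV
#' bands the way the carbonyl n-pi* band of a decalin ketone sits clear of
#' its pi-pi* bands; peak-anchored scaling therefore always has a positive
#' characteristic band to lock onto.
#'
#' @param n_conformers Number of conformers (>= 1).
#' @param n_transitions Transitions per conformer (>= 1).
#' @param energy_spread Mean of the exponential energy ladder (kcal/mol,
#'   default 2); energies are truncated at 8 kcal/mol.
#' @param r_scale Standard deviation of rotatory strengths (1e-40 cgs,
#'   default 15).
#' @param energy_window Excitation-energy window of the random deep-UV
#'   transitions in eV (default `c(5.2, 6.5)`, about 190-238 nm, keeping
#'   the ~290 nm anchor band isolated).
#' @param frac_180 Fraction of conformers labelled with dihedral class
#'   "180" (the rest get "0"); default 0.6.
#' @param temperature Ensemble temperature in K.
#' @param seed Integer random seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return A `conformer_ensemble`.
#' @export
generate_ensemble <- function(n_conformers = 8L, n_transitions = 6L,
                              energy_spread = 2, r_scale = 15,
                              energy_window = c(5.2, 6.5), frac_180 = 0.6,
                              temperature = 298.15, seed = 1L) {
  stopifnot(n_conformers >= 1L, n_transitions >= 1L, energy_spread > 0,
            r_scale > 0, frac_180 >= 0, frac_180 <= 1)
  if (energy_window[1L] <= 3.0 || energy_window[2L] >= 6.6 ||
      energy_window[1L] >= energy_window[2L]) {
    stop("energy_window must lie within (3.0, 6.6) eV", call. = FALSE)
  }
  rng <- .local_rng(seed)
  dG <- c(0, pmin(rng$rexp(n_conformers - 1L, rate = 1 / energy_spread), 8))
  n180 <- round(frac_180 * n_conformers)
  theta1 <- rep("0", n_conformers)
  if (n180 > 0L) theta1[seq_len(n180)] <- "180"
  ids <- sprintf("conf%02d", seq_len(n_conformers))
  conf <- data.frame(id = ids, dG_kcal_mol = dG, theta1_class = theta1)
  trans <- do.call(rbind, lapply(seq_len(n_conformers), function(i) {
    # one guaranteed positive band at ~290 nm, the rest random
    e_anchor <- 4.275
    r_anchor <- abs(rng$rnorm(1L, mean = r_scale, sd = r_scale / 4))
    n_rest <- n_transitions - 1L
    e_rest <- if (n_rest > 0L) {
      rng$runif(n_rest, energy_window[1L], energy_window[2L])
    } else numeric(0)
    r_rest <- if (n_rest > 0L) rng$rnorm(n_rest, 0, r_scale) else numeric(0)
    data.frame(id = ids[i], E_eV = c(e_anchor, e_rest),
               R_cgs40 = c(r_anchor, r_rest))
  }))
  conformer_ensemble(conf, trans, temperature)
}

#' Simulate a measured ECD spectrum from a known enantiomer
#'
#' Forward model of an ECD measurement: the Boltzmann-averaged theoretical
#' spectrum of the ensemble, shifted by `delta_lambda`, multiplied by the
#' enantiomer sign and an unknown positive amplitude calibration, plus
#' additive Gaussian noise (scaled to the peak absolute intensity of the
#' clean signal) and a slow quadratic baseline drift.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param sign True enantiomer: `+1` for the modeled configuration, `-1`
#'   for its mirror image.
#' @param zeta Gaussian bandwidth in eV.
#' @param delta_lambda UV shift in nm applied in the forward model.
#' @param amplitude Positive multiplicative calibration factor.
#' @param noise_sd Additive noise standard deviation as a fraction of the
#'   peak absolute intensity (in [0, 0.5]).
#' @param baseline_amp Amplitude of the quadratic baseline drift, same
#'   fractional units as `noise_sd`.
#' @param grid Wavelength grid in nm.
#' @param cutoff Energy cutoff applied before averaging (kcal/mol).
#' @param seed Integer random seed.
#' @return An experimental-tagged `spectrum_grid`.
#' @export
forward_experiment <- function(ensemble, sign = +1, zeta = 0.36,
                               delta_lambda = 4, amplitude = 1,
                               noise_sd = 0, baseline_amp = 0,
                               grid = default_grid(), cutoff = 4,
                               seed = 1L) {
  stopifnot(sign %in% c(-1, 1), amplitude > 0,
            noise_sd >= 0, noise_sd <= 0.5, baseline_amp >= 0)
  kept <- select_conformers(ensemble, cutoff)
  clean <- ensemble_spectrum(kept, boltzmann_weights(kept), zeta, grid,
                             delta_lambda)
  signal <- sign * amplitude * clean$delta_epsilon
  peak <- max(abs(signal))
  rng <- .local_rng(seed)
  noise <- rng$rnorm(length(grid), 0, noise_sd * peak)
  x <- (grid - mean(grid)) / (max(grid) - min(grid))
  drift_coef <- rng$rnorm(3L, 0, 1)
  baseline <- baseline_amp * peak *
    (drift_coef[1L] * x^2 + drift_coef[2L] * x + drift_coef[3L]) / 2
  spectrum_grid(grid, signal + noise + baseline,
                provenance = "experimental")
}

#' Monte-Carlo recovery rate of the enantiomer decision
#'
#' Runs `n_trials` independent simulated studies: generate an ensemble,
#' pick a true enantiomer sign at random, simulate a noisy measured
#' spectrum, run the theoretical pipeline (cutoff, Boltzmann averaging,
#' band broadening, UV shift, peak scaling) and let [assign_enantiomer()]
#' decide.  Returns the fraction of trials in which the decision matches
#' the true sign; per-trial seeds are derived deterministically from
#' `master_seed`.
#'
#' @param n_trials Number of trials (>= 20).
#' @param noise_sd Peak-relative noise level passed to
#'   [forward_experiment()].
#' @param baseline_amp Baseline drift amplitude.
#' @param amplitude Amplitude calibration of the simulated measurement.
#' @param n_conformers,n_transitions Ensemble size per trial.
#' @param zeta Bandwidth in eV.
#' @param delta_lambda UV shift in nm.
#' @param master_seed Master seed controlling the whole experiment.
#' @return List: `rate` (fraction correct), `n_trials`, `n_undecided`.
#' @export
recovery_rate <- function(n_trials = 100L, noise_sd = 0.10,
                          baseline_amp = 0.05, amplitude = 1,
                          n_conformers = 8L, n_transitions = 6L,
                          zeta = 0.36, delta_lambda = 4,
                          master_seed = 1L) {
  stopifnot(n_trials >= 20L)
  rng <- .local_rng(master_seed)
  trial_seeds <- rng$sample_int(.Machine$integer.max - 1L, 2L * n_trials)
  correct <- 0L
  undecided <- 0L
  for (i in seq_len(n_trials)) {
    ens <- generate_ensemble(n_conformers, n_transitions,
                             seed = trial_seeds[2L * i - 1L])
    true_sign <- if (rng$runif(1L) < 0.5) -1 else +1
    expm <- forward_experiment(ens, sign = true_sign, zeta = zeta,
                               delta_lambda = delta_lambda,
                               amplitude = amplitude, noise_sd = noise_sd,
                               baseline_amp = baseline_amp,
                               seed = trial_seeds[2L * i])
    kept <- select_conformers(ens, 4)
    theo <- ensemble_spectrum(kept, boltzmann_weights(kept), zeta,
                              default_grid(), delta_lambda)
    theo <- scale_spectrum(theo)
    decision <- assign_enantiomer(theo, expm)
    if (decision$label == "undecidable") {
      undecided <- undecided + 1L
    } else {
      called_sign <- if (decision$label == "as-modeled") +1 else -1
      if (called_sign == true_sign) correct <- correct + 1L
    }
  }
  list(rate = correct / n_trials, n_trials = n_trials,
       n_undecided = undecided)
}

#' Generate a Mosher shift table with known configuration
#'
#' Builds a synthetic MTPA ester shift table whose delta-delta sign
#' pattern follows the stated true configuration (R: negative on side A,
#' positive on side B; S reversed), with independent sign flips at the
#' given error probability emulating assignment/overlap errors.
#' Magnitudes are exponential around `magnitude`; delta_R values are drawn
#' in a plausible 0.8-5.5 ppm aliphatic/carbinol range and
#' delta_S = delta_R + delta-delta.
#'
#' @param true_config "R" or "S".
#' @param protons_per_side Protons on each side (>= 1).
#' @param magnitude Typical |delta-delta| in ppm (default 0.06).
#' @param sign_error_prob Probability of flipping each proton's sign
#'   (in [0, 0.5)).
#' @param seed Integer random seed.
#' @return A `mosher_table`.
#' @export
generate_mosher_table <- function(true_config = c("R", "S"),
                                  protons_per_side = 4L,
                                  magnitude = 0.06,
                                  sign_error_prob = 0, seed = 1L) {
  true_config <- match.arg(true_config)
  stopifnot(protons_per_side >= 1L, magnitude > 0,
            sign_error_prob >= 0, sign_error_prob < 0.5)
  rng <- .local_rng(seed)
  n <- 2L * protons_per_side
  side <- rep(c("A", "B"), each = protons_per_side)
  # expected sign under the true configuration
  expected <- ifelse(side == "A", -1, +1)
  if (true_config == "S") expected <- -expected
  flips <- ifelse(rng$runif(n) < sign_error_prob, -1, 1)
  mag <- magnitude / 2 + rng$rexp(n, rate = 2 / magnitude)
  dd <- expected * flips * mag
  delta_R <- rng$runif(n, 0.8, 5.5)
  mosher_table(data.frame(
    proton = sprintf("H-%d", seq_len(n)),
    side = side,
    delta_S_ppm = delta_R + dd,
    delta_R_ppm = delta_R
  ))
}

#' Monte-Carlo recovery rate of the Mosher configuration call
#'
#' Generates `n_tables` synthetic Mosher tables with a known configuration
#' and sign noise, and reports the fraction of decided tables whose call
#' matches the truth.
#'
#' @param n_tables Number of tables.
#' @param protons_per_side Protons per side in each table.
#' @param sign_error_prob Per-proton sign-flip probability.
#' @param min_consistency Threshold passed to [assign_configuration()].
#' @param master_seed Master seed.
#' @return List: `rate` (correct / decided), `n_decided`, `n_tables`.
#' @export
mosher_recovery_rate <- function(n_tables = 200L, protons_per_side = 5L,
                                 sign_error_prob = 0.10,
                                 min_consistency = 0.8,
                                 master_seed = 1L) {
  rng <- .local_rng(master_seed)
  seeds <- rng$sample_int(.Machine$integer.max - 1L, n_tables)
  configs <- ifelse(rng$runif(n_tables) < 0.5, "R", "S")
  decided <- 0L
  correct <- 0L
  for (i in seq_len(n_tables)) {
    tb <- generate_mosher_table(configs[i], protons_per_side,
                                sign_error_prob = sign_error_prob,
                                seed = seeds[i])
    call <- assign_configuration(tb, min_consistency)
    if (call$decided) {
      decided <- decided + 1L
      if (call$configuration == configs[i]) correct <- correct + 1L
    }
  }
  list(rate = if (decided > 0L) correct / decided else NA_real_,
       n_decided = decided, n_tables = n_tables)
}

# Self-contained RNG: draws come from a private stream seeded with `seed`,
# without touching the caller's .Random.seed, so generators are pure
# functions of their arguments.
.local_rng <- function(seed) {
  if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer",
                                              call. = FALSE)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(fn) {
    function(...) {
      outer <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(outer)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", outer, globalenv())
        }
      })
      fn(...)
    }
  }
  list(
    rnorm = with_state(stats::rnorm),
    runif = with_state(stats::runif),
    rexp = with_state(stats::rexp),
    sample_int = with_state(function(n, size) sample.int(n, size))
  )
}
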