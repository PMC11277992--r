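# Band broadening, ensemble averaging, UV shift, peak scaling and the
# enantiomer decision.

one_band <- function(E = 4.275, R = 10, zeta = 0.36,
                     grid = default_grid()) {
  stick_to_spectrum(data.frame(E_eV = E, R_cgs40 = R), zeta, grid)
}

test_that("an isolated band peaks at its transition wavelength with the sign of R", {
  sp <- one_band()
  peak_lambda <- sp$lambda_nm[which.max(sp$delta_epsilon)]
  expect_equal(peak_lambda, round(1239.84193 / 4.275), tolerance = 1)
  expect_true(all(sp$delta_epsilon >= 0))
  neg <- one_band(R = -10)
  expect_equal(neg$delta_epsilon, -sp$delta_epsilon)
})

test_that("band broadening is linear in the rotatory strengths", {
  tr <- data.frame(E_eV = c(4.2, 5.5, 6.0), R_cgs40 = c(8, -20, 5))
  sp1 <- stick_to_spectrum(tr, 0.3)
  tr_scaled <- transform(tr, R_cgs40 = 3.7 * R_cgs40)
  sp2 <- stick_to_spectrum(tr_scaled, 0.3)
  expect_equal(sp2$delta_epsilon, 3.7 * sp1$delta_epsilon, tolerance = 1e-12)
  # sum of per-transition spectra equals the joint spectrum
  parts <- lapply(seq_len(nrow(tr)), function(i)
    stick_to_spectrum(tr[i, ], 0.3)$delta_epsilon)
  expect_equal(Reduce(`+`, parts), sp1$delta_epsilon, tolerance = 1e-12)
})

test_that("the band integral matches the closed form R/22.97 by quadrature", {
  # integral of (delta_epsilon / E) dE over a wide window -> R/22.97
  for (zeta in c(0.36, 0.24, 0.05)) {
    grid <- seq(120, 1000, by = 0.05)
    sp <- one_band(E = 4.275, R = 10, zeta = zeta, grid = grid)
    E <- ev_from_nm(sp$lambda_nm)
    y <- sp$delta_epsilon / E
    o <- order(E)
    I <- sum(diff(E[o]) * (y[o][-1] + y[o][-length(y)]) / 2)
    expect_equal(I, 10 / 22.97, tolerance = 5e-3, label = paste("zeta", zeta))
  }
})

test_that("ensemble averaging is the weighted pointwise combination", {
  conf <- data.frame(id = c("a", "b"), dG_kcal_mol = c(0, 1))
  tra <- data.frame(id = c("a", "a", "b"),
                    E_eV = c(4.275, 5.6, 4.5), R_cgs40 = c(10, -15, 6))
  ens <- conformer_ensemble(conf, tra)
  w <- boltzmann_weights(ens)
  sp <- ensemble_spectrum(ens, w, zeta = 0.36)
  sp_a <- stick_to_spectrum(tra[tra$id == "a", ], 0.36)
  sp_b <- stick_to_spectrum(tra[tra$id == "b", ], 0.36)
  expect_equal(sp$delta_epsilon,
               w[["a"]] * sp_a$delta_epsilon + w[["b"]] * sp_b$delta_epsilon,
               tolerance = 1e-12)
  # single conformer with weight 1 is the plain broadened spectrum
  ens1 <- conformer_ensemble(conf[1, ], tra[tra$id == "a", ])
  expect_equal(ensemble_spectrum(ens1, c(a = 1), 0.36)$delta_epsilon,
               sp_a$delta_epsilon)
  # enantiomeric pair at equal weight cancels exactly
  tra_mirror <- data.frame(id = c("a", "a", "b", "b"),
                           E_eV = c(4.275, 5.6, 4.275, 5.6),
                           R_cgs40 = c(10, -15, -10, 15))
  ens_m <- conformer_ensemble(data.frame(id = c("a", "b"),
                                         dG_kcal_mol = c(0, 0)), tra_mirror)
  sp0 <- ensemble_spectrum(ens_m, c(a = 0.5, b = 0.5), 0.36)
  expect_equal(sp0$delta_epsilon, rep(0, nrow(sp0)), tolerance = 1e-12)
  expect_error(ensemble_spectrum(ens, c(a = 1), 0.36), "cover exactly")
})

test_that("the UV shift translates bands and inverts cleanly", {
  sp <- one_band(E = ev_from_nm(286), R = 10)
  shifted <- apply_uv_shift(sp, 4)
  expect_equal(shifted$lambda_nm[which.max(shifted$delta_epsilon)],
               290, tolerance = 1)
  expect_equal(apply_uv_shift(sp, 0)$delta_epsilon, sp$delta_epsilon)
  back <- apply_uv_shift(shifted, -4)
  interior <- sp$lambda_nm > 200 & sp$lambda_nm < 390
  expect_equal(back$delta_epsilon[interior], sp$delta_epsilon[interior],
               tolerance = 1e-3)
  # exact re-evaluation path agrees with interpolation away from edges
  exact <- stick_to_spectrum(data.frame(E_eV = ev_from_nm(286),
                                        R_cgs40 = 10), 0.36,
                             delta_lambda = 4)
  expect_equal(exact$delta_epsilon[interior], shifted$delta_epsilon[interior],
               tolerance = 1e-4)
})

test_that("peak scaling anchors the positive ~290 nm band at +1 and is idempotent", {
  # two positive bands near 208 and 295 nm, as in a measured curve with
  # maxima at 208 (+3.84) and 295 (+2.25)
  tr <- data.frame(E_eV = ev_from_nm(c(208, 295)), R_cgs40 = c(22, 16))
  sp <- stick_to_spectrum(tr, 0.30)
  sc <- scale_spectrum(sp, reference_band = 290)
  expect_equal(attr(sc, "lambda_peak"), 295, tolerance = 1)
  expect_equal(sc$delta_epsilon[sc$lambda_nm == attr(sc, "lambda_peak")], 1,
               tolerance = 1e-9)
  # idempotence
  sc2 <- scale_spectrum(sc, reference_band = 290)
  expect_equal(sc2$delta_epsilon, sc$delta_epsilon, tolerance = 1e-12)
  # invariance under positive amplitude calibration
  sp_amp <- spectrum_grid(sp$lambda_nm, 7.3 * sp$delta_epsilon)
  expect_equal(scale_spectrum(sp_amp, 290)$delta_epsilon, sc$delta_epsilon,
               tolerance = 1e-12)
  # a negative band in the window is not a valid anchor
  neg <- stick_to_spectrum(data.frame(E_eV = ev_from_nm(290),
                                      R_cgs40 = -10), 0.3)
  expect_error(scale_spectrum(neg, 290), "no positive local maximum")
})

test_that("negating all rotatory strengths negates the spectrum pointwise", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- data.frame(E_eV = stats::runif(6, 3.5, 6.4),
                     R_cgs40 = stats::rnorm(6, 0, 15))
    sp <- stick_to_spectrum(tr, 0.3)
    sp_m <- stick_to_spectrum(transform(tr, R_cgs40 = -R_cgs40), 0.3)
    expect_equal(sp_m$delta_epsilon, -sp$delta_epsilon, tolerance = 1e-12)
  }
})

test_that("cosine similarity behaves as a sign-sensitive overlap score", {
  s <- one_band(E = 4.4, R = 12)
  expect_equal(compare_spectra(s, s), 1, tolerance = 1e-12)
  s_neg <- spectrum_grid(s$lambda_nm, -s$delta_epsilon)
  expect_equal(compare_spectra(s, s_neg), -1, tolerance = 1e-12)
  # orthogonal pair constructed by Gram-Schmidt on the common grid
  t0 <- one_band(E = 5.8, R = 12)
  va <- s$delta_epsilon
  vt <- t0$delta_epsilon - sum(t0$delta_epsilon * va) / sum(va * va) * va
  orth <- spectrum_grid(s$lambda_nm, vt)
  expect_equal(compare_spectra(s, orth, window = c(min(s$lambda_nm), Inf)),
               0, tolerance = 1e-3)
  # resampling stability: doubling the grid density barely moves the score
  dense <- seq(190, 400, by = 0.5)
  s_d <- one_band(E = 4.4, R = 12, grid = dense)
  t_d <- one_band(E = 5.8, R = 12, grid = dense)
  expect_equal(compare_spectra(s, t0), compare_spectra(s_d, t_d),
               tolerance = 1e-3)
  expect_error(compare_spectra(s, t0, window = c(500, 600)), "overlap")
})

test_that("assign_enantiomer picks the better-matching mirror image", {
  set.seed(12)
  tr <- data.frame(E_eV = c(4.275, 5.4, 6.0), R_cgs40 = c(14, -20, 9))
  theo <- scale_spectrum(stick_to_spectrum(tr, 0.36))
  noisy <- spectrum_grid(theo$lambda_nm,
                         theo$delta_epsilon +
                           stats::rnorm(nrow(theo), 0, 0.02))
  res <- assign_enantiomer(theo, noisy)
  expect_equal(res$label, "as-modeled")
  expect_gt(res$score, 0.99)
  mirror_exp <- spectrum_grid(theo$lambda_nm, -theo$delta_epsilon)
  res_m <- assign_enantiomer(theo, mirror_exp)
  expect_equal(res_m$label, "mirror")
  expect_equal(res_m$score, 1, tolerance = 1e-12)
})
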