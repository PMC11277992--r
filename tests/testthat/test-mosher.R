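# Modified Mosher delta-delta analysis and the configuration call.

consistent_table <- function(config = "R", nA = 3L, nB = 3L, mag = 0.06) {
  sgnA <- if (config == "R") -1 else +1
  dd <- c(rep(sgnA * mag, nA), rep(-sgnA * mag, nB))
  dR <- seq(1, 5, length.out = nA + nB)
  mosher_table(data.frame(
    proton = sprintf("H-%d", seq_len(nA + nB)),
    side = rep(c("A", "B"), c(nA, nB)),
    delta_S_ppm = dR + dd,
    delta_R_ppm = dR
  ))
}

swap_columns <- function(tb) {
  mosher_table(data.frame(proton = tb$proton, side = tb$side,
                          delta_S_ppm = tb$delta_R_ppm,
                          delta_R_ppm = tb$delta_S_ppm),
               stereocenter = attr(tb, "stereocenter"))
}

test_that("delta_delta is the exact per-proton difference", {
  tb <- mosher_table(data.frame(
    proton = c("H-8", "H-10"), side = c("A", "B"),
    delta_S_ppm = c(2.83, 2.90), delta_R_ppm = c(2.83, 2.83)))
  dd <- delta_delta(tb)
  expect_equal(unname(dd), c(0, 0.07), tolerance = 1e-12)
  expect_equal(names(dd), c("H-8", "H-10"))
  expect_equal(unname(delta_delta(swap_columns(tb))), -unname(dd))
})

test_that("fully consistent sign patterns give the declared configuration at consistency 1", {
  for (config in c("R", "S")) {
    call <- assign_configuration(consistent_table(config))
    expect_true(call$decided)
    expect_equal(call$configuration, config)
    expect_equal(call$consistency, 1)
  }
})

test_that("column swap mirrors the configuration at identical consistency", {
  set.seed(99)
  for (rep in 1:25) {
    tb <- generate_mosher_table(sample(c("R", "S"), 1),
                                protons_per_side = sample(2:6, 1),
                                sign_error_prob = stats::runif(1, 0, 0.3),
                                seed = sample.int(1e6, 1))
    a <- assign_configuration(tb, min_consistency = 0)
    b <- assign_configuration(swap_columns(tb), min_consistency = 0)
    expect_equal(unname(b$fractions[c("R", "S")]),
                 unname(a$fractions[c("S", "R")]))
    if (a$decided) {
      expect_true(b$decided)
      expect_equal(b$configuration, setdiff(c("R", "S"), a$configuration))
      expect_equal(b$consistency, a$consistency)
    }
  }
})

test_that("the call is invariant under proton reordering", {
  tb <- generate_mosher_table("R", 4L, sign_error_prob = 0.15, seed = 5L)
  set.seed(1)
  perm <- sample(nrow(tb))
  tb_perm <- mosher_table(as.data.frame(tb)[perm, ])
  a <- assign_configuration(tb, min_consistency = 0)
  b <- assign_configuration(tb_perm, min_consistency = 0)
  expect_equal(a$configuration, b$configuration)
  expect_equal(a$consistency, b$consistency)
  expect_equal(sort(names(a$delta_delta)), sort(names(b$delta_delta)))
})

test_that("consistency counts match exhaustive sign-pattern enumeration", {
  # brute-force oracle over every sign pattern of 3 + 2 protons
  nA <- 3L; nB <- 2L
  side <- rep(c("A", "B"), c(nA, nB))
  signs_grid <- expand.grid(rep(list(c(-1, 1)), nA + nB))
  for (row in seq_len(nrow(signs_grid))) {
    s <- as.numeric(signs_grid[row, ])
    dR <- seq(1.5, 4.5, length.out = nA + nB)
    tb <- mosher_table(data.frame(
      proton = sprintf("H-%d", seq_len(nA + nB)), side = side,
      delta_S_ppm = dR + s * 0.05, delta_R_ppm = dR))
    match_R <- sum((side == "A" & s < 0) | (side == "B" & s > 0))
    match_S <- (nA + nB) - match_R
    call <- assign_configuration(tb, min_consistency = 0)
    expect_equal(unname(call$fractions["R"]), match_R / (nA + nB))
    if (match_R > match_S) {
      expect_equal(call$configuration, "R")
    } else if (match_S > match_R) {
      expect_equal(call$configuration, "S")
    } else {
      expect_false(call$decided)
      expect_match(call$reason, "tie")
    }
  }
})

test_that("near-zero shift differences are excluded as uninformative", {
  tb <- mosher_table(data.frame(
    proton = c("H-1", "H-2", "H-3"), side = c("A", "A", "B"),
    delta_S_ppm = c(1.000, 2.002, 3.06),   # H-2: |dd| = 0.002 < 0.005
    delta_R_ppm = c(1.05, 2.000, 3.00)))
  call <- assign_configuration(tb)
  expect_equal(call$n_informative, 2L)
  expect_equal(call$configuration, "R")
  expect_equal(call$consistency, 1)
})

test_that("low-consistency patterns are withheld below the threshold", {
  # 3 of 5 informative protons agree with R: consistency 0.6 < 0.8
  tb <- mosher_table(data.frame(
    proton = sprintf("H-%d", 1:5),
    side = c("A", "A", "A", "B", "B"),
    delta_S_ppm = c(0.95, 0.95, 1.05, 3.05, 2.95),
    delta_R_ppm = c(1, 1, 1, 3, 3)))
  call <- assign_configuration(tb, min_consistency = 0.8)
  expect_false(call$decided)
  expect_match(call$reason, "below threshold")
  expect_equal(call$consistency, 0.6)
  # the same table is called at a laxer threshold
  expect_equal(assign_configuration(tb, min_consistency = 0.5)$configuration,
               "R")
})

test_that("adding an agreeing proton never lowers consistency", {
  set.seed(17)
  for (rep in 1:10) {
    tb <- generate_mosher_table("R", 3L, sign_error_prob = 0.2,
                                seed = sample.int(1e6, 1))
    call <- assign_configuration(tb, min_consistency = 0)
    if (!call$decided) next
    extra_sign <- if (call$configuration == "R") -0.08 else 0.08
    tb2 <- mosher_table(rbind(as.data.frame(tb),
                              data.frame(proton = "H-extra", side = "A",
                                         delta_S_ppm = 2 + extra_sign,
                                         delta_R_ppm = 2)))
    call2 <- assign_configuration(tb2, min_consistency = 0)
    expect_gte(call2$consistency, call$consistency)
  }
})
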