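make_exact_series <- function(proton = "HN2", dU = 8.00, dF = 8.50,
                              Tm = 274.0, dHm = 23900,
                              T_K = seq(218, 348, by = 10), noise = 0) {
  mu <- dU + (dF - dU) / (1 + exp(-dHm / 8.314 * (1 / T_K - 1 / Tm)))
  shift_melt_series(proton, T_K, mu + if (noise > 0) rnorm(length(mu), 0, noise) else 0)
}

test_that("two-state fit recovers exact parameters and the sigmoid midpoint", {
  s <- make_exact_series()
  fit <- fit_two_state(s)
  expect_equal(fit$dU, 8.00, tolerance = 1e-6)
  expect_equal(fit$dF, 8.50, tolerance = 1e-6)
  expect_equal(fit$Tm, 274.0, tolerance = 1e-6)
  expect_equal(fit$dHm, 23900, tolerance = 1e-6)
  # fitted curve at T = Tm is the terminal midpoint
  expect_equal(predict_shift(fit, fit$Tm), (fit$dU + fit$dF) / 2,
               tolerance = 1e-9)
  # flat series is rejected as "no transition"
  flat <- shift_melt_series("x", seq(218, 348, 10), rep(8, 14))
  expect_error(fit_two_state(flat), "no transition")
  expect_error(fit_two_state(shift_melt_series("x", c(270, 280, 290),
                                               c(8, 8.2, 8.4))),
               "at least 5")
})

test_that("folded fraction follows the closed form and its limits", {
  fit <- list(Tm = 274.0, dHm = 23900)
  expect_equal(folded_fraction(fit, 274.0), 0.5, tolerance = 1e-12)
  expect_equal(folded_fraction(fit, 284), 0.409, tolerance = 1e-3)
  expect_equal(folded_fraction(fit, 1e-3), 1.0, tolerance = 1e-12)
  expect_error(folded_fraction(fit, -5), "positive")
  # kF = f/(1-f) identically (route-a consistency)
  for (T_K in c(230, 260, 274, 300, 340)) {
    f <- folded_fraction(fit, T_K)
    expect_equal(delta_g(fit, T_K)$kF, f / (1 - f), tolerance = 1e-9)
  }
  # dG(Tm) = 0 via route (a)
  expect_equal(delta_g(fit, 274.0)$dG, 0, tolerance = 1e-9)
})

test_that("free-energy routes reproduce tabulated and closed-form values", {
  # enthalpy/entropy route: dG = dHm - T dSm at 298 K
  expect_equal(delta_g(list(dHm = 23900, dSm = 73.1), 298, route = "hs")$dG / 1000,
               2.1, tolerance = 0.05)
  expect_equal(delta_g(list(dHm = 26400, dSm = 78.4), 298, route = "hs")$dG / 1000,
               3.0, tolerance = 0.05)
  # shift route closed form
  r <- delta_g(list(Tm = 274.0, dHm = 23900), 284)
  expect_equal(r$kF, 0.692, tolerance = 1e-2)
  expect_equal(r$dG, 870, tolerance = 10)
  # kF = 1 -> dG = 0
  expect_equal(-8.314 * 298 * log(1), 0)
  # observed-shift kF errors outside the terminals
  expect_equal(kf_from_shift(8.25, 8.0, 8.5), 1, tolerance = 1e-12)
  expect_error(kf_from_shift(8.6, 8.0, 8.5), "outside")
})

test_that("global fit matches the generator truth and excludes degenerate protons", {
  cfg <- noise_free_config(seed = 21)
  m <- simulate_melt(cfg)
  gf <- global_melt_fit(m$series)
  expect_equal(gf$Tm, 274.0, tolerance = 274 * 1e-4)
  expect_equal(gf$dHm, 23900, tolerance = 23900 * 1e-4)
  # single series: global fit equals the per-proton fit
  g1 <- suppressWarnings(global_melt_fit(m$series[1L]))
  f1 <- fit_two_state(m$series[[1L]])
  expect_equal(g1$Tm, f1$Tm, tolerance = 1e-6)
  expect_equal(g1$dHm, f1$dHm, tolerance = 1e-4 * f1$dHm)
  # a zero-change proton is excluded with a warning, result unchanged
  flat <- shift_melt_series("flat", m$series[[1L]]$T_K,
                            rep(7.5, length(m$series[[1L]]$T_K)))
  expect_warning(gf2 <- global_melt_fit(c(m$series, list(flat = flat))),
                 "excluded")
  expect_identical(gf2$excluded, "flat")
  expect_equal(gf2$Tm, gf$Tm, tolerance = 1e-9)
})

test_that("van 't Hoff line reproduces the fitted enthalpy on exact data", {
  fit <- fit_two_state(make_exact_series())
  vh <- van_t_hoff_entropy(fit)
  expect_equal(vh$dH, fit$dHm, tolerance = 1e-6 * fit$dHm)
  expect_equal(vh$dS, fit$dHm / fit$Tm, tolerance = 1e-6 * fit$dHm / fit$Tm)
  # too few points inside the transition: all folded fractions < 0.02
  T_hot <- c(450, 460, 470, 480, 490)
  hot_fit <- structure(list(dU = 8.0, dF = 8.5, Tm = 274.0, dHm = 23900,
                            series = make_exact_series(T_K = T_hot)),
                       class = "two_state_fit")
  expect_error(van_t_hoff_entropy(hot_fit), "usable temperatures")
})

test_that("relative folding: identity, closed form, antisymmetry, worked example", {
  T_K <- seq(218, 348, by = 10)
  s1 <- make_exact_series(Tm = 274, dHm = 25000, T_K = T_K)
  s2 <- make_exact_series(Tm = 268, dHm = 25000, dU = 7.6, dF = 7.3, T_K = T_K)

  # identical compounds -> K = 1, ddG = 0
  self <- relative_folding(s1, s1, c(8.00, 8.50), c(8.00, 8.50), 274)
  expect_equal(self$K_ratio, 1.0, tolerance = 1e-9)
  expect_equal(self$ddG, 0, tolerance = 1e-6)

  # equal enthalpies: K = exp(dH/R (1/Tm2 - 1/Tm1)), points collinear
  rf <- relative_folding(s1, s2, c(8.00, 8.50), c(7.6, 7.3), 268)
  K_true <- exp(25000 / 8.314 * (1 / 268 - 1 / 274))
  expect_equal(rf$K_ratio, K_true, tolerance = 1e-3)
  expect_equal(rf$K_ratio, 1.278, tolerance = 1e-3)
  fit_y <- rf$K_ratio * rf$points$x
  expect_lt(max(abs(fit_y - rf$points$y)), 1e-10 * max(abs(rf$points$y)))

  # antisymmetry on noise-free collinear data
  rf_swap <- relative_folding(s2, s1, c(7.6, 7.3), c(8.00, 8.50), 274)
  expect_equal(rf_swap$K_ratio, 1 / rf$K_ratio, tolerance = 1e-6)

  # worked example: K = 1.3 at Tm2 = 267.6 K -> -0.6 kJ/mol at 1 d.p.
  expect_equal(round(-8.314 * 267.6 * log(1.3) / 1000, 1), -0.6)

  # out-of-terminal shifts are dropped with a warning
  s3 <- s1
  s3$shift_ppm[1L] <- 9.0
  expect_warning(relative_folding(s3, s2, c(8.00, 8.50), c(7.6, 7.3), 268),
                 "dropped")
})

test_that("temperature coefficients and hydrogen-bond classes follow the band rule", {
  T_K <- seq(218, 348, by = 10)
  mk <- function(name, slope_ppb) {
    shift_melt_series(name, T_K, 8.0 - slope_ppb / 1000 * (T_K - 218))
  }
  tc <- temperature_coefficients(list(mk("Lys7", 2.45), mk("flat", 0),
                                      mk("edge3", 3.0), mk("edge5", 5.0),
                                      mk("exposed", 5.65)))
  expect_equal(tc$coef_ppb_per_K,
               c(2.45, 0, 3.0, 5.0, 5.65), tolerance = 1e-9)
  expect_identical(tc$class,
                   c("intramolecular H-bond", "intramolecular H-bond",
                     "dynamic equilibrium", "dynamic equilibrium",
                     "solvent exposed"))
  expect_error(temperature_coefficients(list(
    shift_melt_series("x", c(270, 280), c(8, 8.1)))), "3 temperatures")
})

test_that("VT tables round-trip through the delimited format", {
  cfg <- noise_free_config(seed = 31)
  m <- simulate_melt(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vt_table(m$series, path)
  back <- read_vt_table(path)
  expect_identical(names(back), names(m$series))
  expect_equal(back[["HA3"]]$shift_ppm, m$series[["HA3"]]$shift_ppm,
               tolerance = 1e-8)
})
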