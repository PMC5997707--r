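test_that("noiseless round-trips recover E_CY and E_RY to 1e-5", {
  b <- test_basis
  for (e_cy in seq(0.1, 0.9, 0.2)) {
    sim <- gen_biosensor_spectrum(b, transfer_params(E_CY = e_cy),
                                  "fluorescence", noise = "none")
    fit <- fit_E_CY(sim$spectrum, b)
    expect_lt(abs(fit$estimate[["E_CY"]] - e_cy), 1e-5)
    expect_true(fit$converged)
  }
  for (e_ry in c(0, 0.02, 0.05)) {
    sim <- gen_biosensor_spectrum(
      b, transfer_params(E_CY = 0.29, E_RC = 0.13, E_RY = e_ry),
      "bioluminescence", noise = "none")
    fit <- fit_E_RY(sim$spectrum, b, E_RC = 0.13, E_CY = 0.29)
    expect_lt(abs(fit$estimate[["E_RY"]] - e_ry), 1e-5)
  }
})

test_that("a pure donor spectrum fits to E_CY = 0", {
  b <- test_basis
  b$cross_excitation_fraction <- 0
  pure <- spectrum(b$grid, b$phi$C * b$f_C$intensity)
  fit <- fit_E_CY(pure, b)
  expect_lt(fit$estimate[["E_CY"]], 1e-6)
  expect_true(fit$at_bound[["E_CY"]])
})

test_that("Poisson noise at peak 1e4 counts biases E_CY by less than 0.02", {
  b <- test_basis
  errs <- vapply(1:20, function(s) {
    sim <- gen_biosensor_spectrum(b, transfer_params(E_CY = 0.29),
                                  "fluorescence", noise = "poisson",
                                  peak_counts = 1e4, seed = s)
    fit_E_CY(sim$spectrum, b)$estimate[["E_CY"]] - 0.29
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.02)
})

test_that("increasing true E_CY increases the fitted yellow/cyan area ratio", {
  b <- test_basis
  yc_ratio <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(e) {
    sim <- gen_biosensor_spectrum(b, transfer_params(E_CY = e),
                                  "fluorescence", noise = "none")
    fit <- fit_E_CY(sim$spectrum, b)
    crv <- fit$fitted_curve
    yellow <- crv$wavelength_nm >= 515
    pracma::trapz(crv$wavelength_nm[yellow], crv$intensity[yellow]) /
      pracma::trapz(crv$wavelength_nm[!yellow], crv$intensity[!yellow])
  }, numeric(1))
  expect_true(all(diff(yc_ratio) > 0))
})

test_that("the optimum is robust to the choice of starting grid", {
  b <- test_basis
  sim <- gen_biosensor_spectrum(b, transfer_params(E_CY = 0.37),
                                "fluorescence", noise = "none")
  y <- sim$spectrum$intensity
  mfun1 <- function(e)
    fluorescence_model(b, transfer_params(E_CY = e, amplitude = 1),
                       grid = sim$spectrum$wavelength_nm)$intensity
  f1 <- hybret:::.ls_engine(y, mfun1, 0, 1, starts_e = c(0.05, 0.95))
  f2 <- hybret:::.ls_engine(y, mfun1, 0, 1, starts_e = c(0.2, 0.5, 0.8))
  expect_lt(abs(sqrt(f1$ss / length(y)) - sqrt(f2$ss / length(y))), 1e-8)
  expect_lt(abs(f1$fit$par[["E"]] - f2$fit$par[["E"]]), 1e-7)
})

test_that("E_RY bound respects the luciferase branch budget", {
  b <- test_basis
  sim <- gen_biosensor_spectrum(
    b, transfer_params(E_CY = 0.29, E_RC = 0.13, E_RY = 0.05),
    "bioluminescence", noise = "none")
  fit <- fit_E_RY(sim$spectrum, b, E_RC = 0.13, E_CY = 0.29)
  expect_lte(fit$estimate[["E_RY"]], 1 - 0.13)
  expect_error(fit_E_RY(sim$spectrum, b, E_RC = 1, E_CY = 0.29),
               "no admissible range")
  expect_error(fit_E_RY(sim$spectrum, b, E_RC = 1.3, E_CY = 0.29),
               "\\[0, 1\\]")
})

test_that("E_NC-only mode fits the NanoLuc-CFP fusion with E_NY = E_CY = 0", {
  b <- test_basis
  truth <- transfer_params(E_NC = 0.4)
  sim <- gen_biosensor_spectrum(b, truth, "bioluminescence",
                                donor = "nanoluc", noise = "none")
  fit <- fit_E_RY(sim$spectrum, b, E_RC = NA, E_CY = NA,
                  donor = "nanoluc", fit_param = "E_NC")
  expect_lt(abs(fit$estimate[["E_NC"]] - 0.4), 1e-5)
  expect_equal(fit$fixed, list(E_NY = 0, E_CY = 0))
})

test_that("bootstrap envelopes are deterministic under seed and collapse at zero residual", {
  b <- test_basis
  clean <- gen_biosensor_spectrum(b, transfer_params(E_CY = 0.3),
                                  "fluorescence", noise = "none")
  fit0 <- fit_E_CY(clean$spectrum, b)
  env0 <- suppressWarnings(confidence_envelope(fit0, n_boot = 30, seed = 1))
  expect_lt(max(env0$envelope_hi - env0$envelope_lo), 1e-6)
  expect_warning(confidence_envelope(fit0, n_boot = 30, seed = 1),
                 "n_boot")
  noisy <- gen_biosensor_spectrum(b, transfer_params(E_CY = 0.3),
                                  "fluorescence", noise = "poisson",
                                  seed = 11)
  fit <- fit_E_CY(noisy$spectrum, b)
  e1 <- confidence_envelope(fit, n_boot = 60, seed = 5)
  e2 <- confidence_envelope(fit, n_boot = 60, seed = 5)
  expect_identical(e1$envelope_lo, e2$envelope_lo)
  expect_identical(e1$ci95, e2$ci95)
  expect_true(all(e1$envelope_lo <= fit$fitted_curve$intensity + 1e-12))
  expect_true(all(e1$envelope_hi >= fit$fitted_curve$intensity - 1e-12))
})

test_that("bootstrap envelope agrees with the delta-method band under homoscedastic noise", {
  b <- test_basis
  sim <- gen_biosensor_spectrum(b, transfer_params(E_CY = 0.4),
                                "fluorescence", noise = "gaussian",
                                peak_counts = 1e4, sigma = 100, seed = 3)
  fit <- fit_E_CY(sim$spectrum, b)
  env <- confidence_envelope(fit, n_boot = 500, seed = 9)
  dm <- delta_method_band(fit)
  w_boot <- env$envelope_hi - env$envelope_lo
  w_delta <- dm$band_hi - dm$band_lo
  sel <- w_delta > 0.2 * max(w_delta)
  expect_lt(median(abs(w_boot[sel] / w_delta[sel] - 1)), 0.10)
})

test_that("non-finite spectra are rejected before fitting", {
  expect_error(spectrum(c(480, 482), c(Inf, 1)), "finite")
})
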