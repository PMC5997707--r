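test_that("Z' matches hand arithmetic and its degenerate limits", {
  # zero spread in both groups: a perfect assay
  expect_equal(zprime(c(1, 1, 1), c(0.5, 0.5, 0.5)), 1)
  # sample SD 0.02 in each group, means 1.0 and 0.5 -> 1 - 3*0.04/0.5
  neg <- c(0.98, 1.00, 1.02)
  pos <- c(0.48, 0.50, 0.52)
  expect_equal(zprime(neg, pos), 0.76)
  expect_error(zprime(c(1, 1), c(1, 1)), "equal")
  expect_error(zprime(1, c(0.5, 0.5)), "2 wells")
})

test_that("Z' is bounded by 1 and decreases as either SD grows", {
  set.seed(31)
  for (i in 1:20) {
    neg <- rnorm(8, 1, runif(1, 0.001, 0.1))
    pos <- rnorm(8, 0.6, runif(1, 0.001, 0.1))
    if (mean(neg) == mean(pos)) next
    expect_lte(zprime(neg, pos), 1)
  }
  neg <- c(0.99, 1.00, 1.01); pos <- c(0.59, 0.60, 0.61)
  wider <- c(0.95, 1.00, 1.05)
  expect_lt(zprime(wider, pos), zprime(neg, pos))
  expect_lt(zprime(neg, (pos - 0.6) * 5 + 0.6), zprime(neg, pos))
})

test_that("Hill fit recovers noiseless parameters and the half-maximal identity", {
  true <- list(min = 0.2, amp = 0.8, IC50 = 0.015, nH = 1.2)
  doses <- c(0, 10^seq(-4, 1, length.out = 11))
  resp <- hill_model(doses, true$min, true$amp, true$IC50, true$nH)
  fit <- hill_fit(doses, resp)
  expect_equal(fit$params$min, true$min, tolerance = 1e-6)
  expect_equal(fit$params$amp, true$amp, tolerance = 1e-6)
  expect_equal(fit$params$IC50, true$IC50, tolerance = 1e-5)
  expect_equal(fit$params$nH, true$nH, tolerance = 1e-5)
  expect_true(fit$converged)
  # response at X = IC50 is exactly min + amp/2
  expect_equal(hill_model(true$IC50, true$min, true$amp, true$IC50,
                          true$nH), true$min + true$amp / 2)
})

test_that("Hill fit is scale-equivariant in the dose axis", {
  doses <- c(0, 10^seq(-3, 1, length.out = 9))
  resp <- hill_model(doses, 0.3, 0.5, 0.05, 1.7)
  f1 <- hill_fit(doses, resp)
  f2 <- hill_fit(doses * 40, resp)
  expect_equal(f2$params$IC50 / f1$params$IC50, 40, tolerance = 1e-4)
  expect_equal(f2$params$nH, f1$params$nH, tolerance = 1e-5)
})

test_that("zero-amplitude data flags an unidentifiable IC50", {
  doses <- c(0, 10^seq(-3, 1, length.out = 9))
  fit <- hill_fit(doses, rep(0.4, length(doses)))
  expect_false(fit$converged)
})

test_that("the inverse ERK-Hill composed with the forward curve is the identity", {
  p <- list(min = 0.30, amp = 0.30, IC50 = 0.015, nH = 1.3)
  doses <- 10^seq(-4, 1, length.out = 25)
  erk <- hill_model(doses, p$min, p$amp, p$IC50, p$nH)
  back <- dose_from_erk(erk, p$min, p$amp, p$IC50, p$nH)
  expect_lt(max(abs(back / doses - 1)), 1e-10)
  # the admissibility guard: boundary values are NA, not garbage
  expect_true(is.na(dose_from_erk(p$min, p$min, p$amp, p$IC50, p$nH)))
  expect_true(is.na(dose_from_erk(p$min + p$amp, p$min, p$amp, p$IC50,
                                  p$nH)))
})

test_that("coupled fit recovers all four free parameters from noiseless plates", {
  g <- gen_plate(cv = 0, replicates = 2, seed = 1)
  cf <- suppressMessages(
    coupled_fit(g$plate$bret_ratio, g$plate$total, g$plate$dose,
                fixed = list(min_ERK = 0.30, amp_ERK = 0.30,
                             min_L = 1000, amp_L = 9000)))
  expect_equal(cf$IC50_ERK, 0.015, tolerance = 1e-4)
  expect_equal(cf$nH_ERK, 1, tolerance = 1e-4)
  expect_equal(cf$IC50_L, 0.028, tolerance = 1e-4)
  expect_equal(cf$nH_L, 1.5, tolerance = 1e-4)
  # the two zero-dose wells sit exactly at ERK = min + amp, the upper
  # admissibility bound of the inverse ERK-Hill, and are excluded
  expect_equal(cf$n_excluded, 2)
})

test_that("matched ERK and live-cell Hill curves give a linear live-vs-ERK relation", {
  fixed <- list(min_ERK = 0.3, amp_ERK = 0.3, min_L = 1000, amp_L = 9000)
  p <- list(IC50 = 0.02, nH = 1.4)
  doses <- c(0, 10^seq(-4, 1, length.out = 15))
  erk <- hill_model(doses, fixed$min_ERK, fixed$amp_ERK, p$IC50, p$nH)
  live <- hill_model(doses, fixed$min_L, fixed$amp_L, p$IC50, p$nH)
  cf <- coupled_fit(erk, live, doses, fixed)
  # dense evaluation of the predicted correlation curve: linear when the
  # two dose-response curves share IC50 and nH
  e_grid <- seq(fixed$min_ERK + 0.01, fixed$min_ERK + fixed$amp_ERK - 0.01,
                length.out = 80)
  pred <- cf$live_vs_erk(e_grid)
  lin <- lm(pred ~ e_grid)
  expect_lt(max(abs(residuals(lin))) / diff(range(pred)), 1e-4)
})

test_that("coupled fit excludes wells with inadmissible ERK values and reports the count", {
  g <- gen_plate(cv = 0, seed = 2)
  erk <- g$plate$bret_ratio
  erk[1] <- 0.30 - 0.05   # below min_ERK: Eq-inverse undefined
  erk[2] <- 0.30 + 0.31   # above min_ERK + amp_ERK
  expect_message(
    cf <- coupled_fit(erk, g$plate$total, g$plate$dose,
                      fixed = list(min_ERK = 0.30, amp_ERK = 0.30,
                                   min_L = 1000, amp_L = 9000)),
    "2 well")
  expect_equal(cf$n_excluded, 2)
})

test_that("coupled fit tolerates 2% multiplicative well noise", {
  errs <- vapply(1:10, function(s) {
    g <- gen_plate(cv = 0.02, replicates = 4, seed = s)
    cf <- suppressMessages(coupled_fit(
      g$plate$bret_ratio, g$plate$total, g$plate$dose,
      fixed = list(min_ERK = 0.30, amp_ERK = 0.30,
                   min_L = 1000, amp_L = 9000)))
    max(abs(log2(cf$IC50_ERK / 0.015)), abs(log2(cf$IC50_L / 0.028)))
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("halving both channels preserves the ratio and halves the total", {
  g <- gen_plate(cv = 0.02, seed = 3)
  p <- g$plate
  tmp <- tempfile(fileext = ".csv")
  half <- p
  half$cyan <- half$cyan / 2
  half$yellow <- half$yellow / 2
  write_plate(half, tmp)
  back <- read_plate(tmp)
  expect_equal(back$bret_ratio, p$bret_ratio, tolerance = 1e-6)
  expect_equal(back$total, p$total / 2, tolerance = 1e-6)
})
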