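test_that("an injected cosmic-ray spike is replaced and nothing else moves", {
  set.seed(1)
  base <- matrix(rpois(40 * 40, 100), 40, 40)
  spiked <- base
  spiked[17, 23] <- 1e5
  st <- ratio_stack(spiked, base)
  out <- preprocess_stack(st, spike_z = 8, filter_radius = 0,
                          background = list(cyan = 0, yellow = 0))
  expect_lt(out$cyan[17, 23, 1], 200)  # back near the local median
  untouched <- out$cyan[, , 1]
  untouched[17, 23] <- base[17, 23]
  expect_equal(untouched, base)
})

test_that("preprocessing with no spikes, radius 0 and zero background is the identity", {
  set.seed(2)
  a <- matrix(rpois(25 * 25, 500), 25, 25)
  b <- matrix(rpois(25 * 25, 300), 25, 25)
  st <- ratio_stack(a, b)
  out <- preprocess_stack(st, spike_z = Inf, filter_radius = 0,
                          background = list(cyan = 0, yellow = 0))
  expect_equal(out$cyan[, , 1], a)
  expect_equal(out$yellow[, , 1], b)
})

test_that("supplied scalar background is subtracted and clipped at zero", {
  st <- flat_stack(200, 50)
  out <- preprocess_stack(st, spike_z = Inf,
                          background = list(cyan = 100, yellow = 100))
  expect_true(all(out$cyan == 100))
  expect_true(all(out$yellow == 0))  # clipped, not negative
  expect_error(preprocess_stack(flat_stack(0, 10)), "all zero")
})

test_that("ratio is yellow/cyan on the mask and respects min_denominator", {
  st <- flat_stack(100, 200)
  st <- compute_ratio(st)
  expect_true(all(st$ratio == 2.0))
  # pixels under the denominator threshold leave the mask
  a <- matrix(100, 10, 10); a[1, 1] <- 3
  st2 <- compute_ratio(ratio_stack(a, a * 1.5), min_denominator = 10)
  expect_false(st2$mask[1, 1, 1])
  expect_true(is.na(st2$ratio[1, 1, 1]))
  expect_equal(sum(st2$mask), 99)
  expect_warning(compute_ratio(ratio_stack(a * 0 + 1, a), min_denominator = 10),
                 "empty")
})

test_that("per-cell median ratios recover the generator truth within 2%", {
  g <- gen_ratio_stack(n_cells = 2, ratio_range = c(0.35, 0.65),
                       T = 3, seed = 4, spike_rate = 0)
  st <- preprocess_stack(g$stack, spike_z = Inf,
                         background = list(cyan = g$truth$background,
                                           yellow = g$truth$background))
  st <- compute_ratio(st, min_denominator = 50)
  tr <- cell_traces(st)
  est <- tapply(tr$ratio, tr$cell_id, mean)
  expect_lt(max(abs(est - g$truth$ratio) / g$truth$ratio), 0.02)
})

test_that("a common per-frame decay leaves every per-cell ratio trace unchanged", {
  g <- gen_ratio_stack(n_cells = 4, T = 8, seed = 7, noise = "none",
                       spike_rate = 0, background = 0,
                       half_life_min = Inf)
  base <- compute_ratio(g$stack, min_denominator = 1)
  tr0 <- cell_traces(base)
  # exponential decay with 9-min half-life applied identically to both
  decay <- 0.5^((seq_len(8) - 1) / 9)
  dec <- g$stack
  for (t in 1:8) {
    dec$cyan[, , t] <- dec$cyan[, , t] * decay[t]
    dec$yellow[, , t] <- dec$yellow[, , t] * decay[t]
  }
  dec <- compute_ratio(ratio_stack(dec$cyan, dec$yellow,
                                   labels = g$stack$labels),
                       min_denominator = 0)
  tr1 <- cell_traces(dec)
  expect_lt(max(abs(tr1$ratio - tr0$ratio)), 1e-12)
})

test_that("ratio is invariant under common gain, equivariant under yellow-only gain", {
  g <- gen_ratio_stack(n_cells = 3, T = 2, seed = 9, noise = "none",
                       spike_rate = 0, background = 0)
  r0 <- compute_ratio(g$stack, 1)
  rc <- compute_ratio(ratio_stack(g$stack$cyan * 3.7,
                                  g$stack$yellow * 3.7,
                                  labels = g$stack$labels), 1)
  ry <- compute_ratio(ratio_stack(g$stack$cyan, g$stack$yellow * 3.7,
                                  labels = g$stack$labels), 1)
  m <- r0$mask
  expect_equal(rc$ratio[m], r0$ratio[m], tolerance = 1e-12)
  expect_equal(ry$ratio[m], r0$ratio[m] * 3.7, tolerance = 1e-12)
})

test_that("IMD rendering bins the ratio into exactly eight ordered hues", {
  # a ramp spanning the display range occupies all bins in order
  H <- 8; W <- 100
  ramp <- matrix(rep(seq(0.2, 0.8, length.out = W), each = H), H, W)
  st <- compute_ratio(ratio_stack(matrix(1000, H, W), ramp * 1000))
  imd <- render_imd(st, r_min = 0.2, r_max = 0.8)
  idx <- imd$color_index[1, , 1]
  expect_setequal(unique(idx), 0:7)
  expect_true(all(diff(idx) >= 0))  # monotone in ratio
  # uniform ratio at r_min -> everything in bin 0
  st0 <- compute_ratio(flat_stack(1000, 200))
  imd0 <- render_imd(st0, r_min = 0.2, r_max = 0.8)
  expect_true(all(imd0$color_index == 0))
  # values beyond the range clip to the end bins
  sthi <- compute_ratio(flat_stack(1000, 5000))
  expect_true(all(render_imd(sthi, 0.2, 0.8)$color_index == 7))
  expect_error(render_imd(st0, 0.8, 0.2), "r_min")
})

test_that("masked-out pixels render black", {
  a <- matrix(1000, 10, 10); a[3, ] <- 0
  st <- compute_ratio(ratio_stack(a, a * 0.5), min_denominator = 10)
  imd <- render_imd(st, 0.2, 0.8)
  expect_true(all(imd$rgb[3, , , 1] == 0))
  expect_true(all(imd$brightness[3, , 1] == 0))
})

test_that("linear unmixing inverts a known forward mixture", {
  # luminophore signatures (cyan, yellow fractions per unit abundance)
  A <- cbind(c(0.7, 0.3), c(0.2, 0.8))
  set.seed(5)
  ab1 <- matrix(runif(16 * 16, 0, 1000), 16, 16)
  ab2 <- matrix(runif(16 * 16, 0, 1000), 16, 16)
  ab2[1, 1] <- 0  # a pure luminophore-1 pixel
  cy <- A[1, 1] * ab1 + A[1, 2] * ab2
  ye <- A[2, 1] * ab1 + A[2, 2] * ab2
  um <- unmix_two_luminophores(ratio_stack(cy, ye), A)
  expect_equal(um$abundance1[, , 1], ab1, tolerance = 1e-9)
  expect_equal(um$abundance2[, , 1], ab2, tolerance = 1e-9)
  expect_equal(um$abundance2[1, 1, 1], 0)
  expect_lt(max(um$residual), 1e-9)
  # identity mixing returns the channels unchanged
  st <- flat_stack(123, 456)
  id <- unmix_two_luminophores(st, diag(2))
  expect_true(all(id$abundance1 == 123) && all(id$abundance2 == 456))
  expect_error(unmix_two_luminophores(st, matrix(1, 2, 2)), "singular")
})

test_that("baseline normalization fixes the pre-stimulus mean at 1", {
  expect_equal(normalize_timecourse(rep(0.4, 10), 1:3), rep(1, 10))
  tr <- c(rep(1, 4), rep(2, 4))
  expect_equal(normalize_timecourse(tr, 1:4), c(rep(1, 4), rep(2, 4)))
  expect_error(normalize_timecourse(c(0, 0, 1), 1:2), "zero")
  expect_error(normalize_timecourse(1:5, integer(0)), "nonempty")
  expect_error(normalize_timecourse(1:5, 9), "outside")
})

test_that("a 30% ERK pulse survives the full imaging pipeline", {
  # two-phase stack: baseline frames then a 30% ratio rise in every cell
  g <- gen_ratio_stack(n_cells = 3, T = 4, seed = 12, noise = "poisson",
                       spike_rate = 0, background = 50,
                       half_life_min = Inf, cell_intensity = 5000)
  post <- g$stack
  for (t in 3:4) post$yellow[, , t] <- post$yellow[, , t] * 1.3
  st <- preprocess_stack(ratio_stack(post$cyan, post$yellow,
                                     labels = g$stack$labels),
                         spike_z = Inf,
                         background = list(cyan = 50, yellow = 50))
  st <- compute_ratio(st, min_denominator = 100)
  tr <- cell_traces(st)
  for (id in unique(tr$cell_id)) {
    nt <- normalize_timecourse(tr$ratio[tr$cell_id == id], 1:2)
    expect_equal(mean(nt[3:4]), 1.30, tolerance = 0.03)
  }
})
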