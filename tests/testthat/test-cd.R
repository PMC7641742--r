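test_that("two-state decomposition is exact on noise-free mixtures", {
  c1 <- cd_component_spectrum("hybrid")
  c2 <- cd_component_spectrum("antiparallel")
  # mixture equal to a pure component
  f <- decompose_two_state(c1, c1, c2)
  expect_equal(f$w1, 1)
  expect_equal(f$w2, 0)
  # 50/50 mixture to machine precision
  mix <- simulate_cd_mixture(0.5, c1, c2, noise_sd = 0)
  f <- decompose_two_state(mix, c1, c2)
  expect_equal(f$w1, 0.5, tolerance = 1e-10)
  expect_lt(f$residual, 1e-10)
  # arbitrary weights invert exactly at zero noise
  for (w in c(0.81, 0.19, 0.05)) {
    mix <- simulate_cd_mixture(w, c1, c2, noise_sd = 0)
    expect_equal(decompose_two_state(mix, c1, c2)$w1, w,
                 tolerance = 1e-10)
  }
})

test_that("identical component spectra are rejected as degenerate", {
  c1 <- cd_component_spectrum("hybrid")
  expect_error(decompose_two_state(c1, c1, c1), "degenerate")
})

test_that("weight recovery error shrinks with noise amplitude", {
  c1 <- cd_component_spectrum("hybrid")
  c2 <- cd_component_spectrum("antiparallel")
  err <- sapply(c(0.05, 0.005), function(sd) {
    ws <- sapply(1:20, function(s)
      decompose_two_state(simulate_cd_mixture(0.7, c1, c2, sd, seed = s),
                          c1, c2)$w1)
    mean(abs(ws - 0.7))
  })
  expect_lt(err[2], err[1])
})

test_that("spectra are resampled onto common support before fitting", {
  c1 <- cd_component_spectrum("hybrid", grid = seq(220, 320, 1))
  c2 <- cd_component_spectrum("antiparallel", grid = seq(230, 310, 0.5))
  mixg <- seq(235, 305, 2)
  mix <- cd_spectrum(mixg, 0.6 * approx(c1$wavelength, c1$ellipticity,
                                        mixg)$y +
                       0.4 * approx(c2$wavelength, c2$ellipticity, mixg)$y)
  f <- decompose_two_state(mix, c1, c2)
  expect_equal(f$w1, 0.6, tolerance = 1e-3)
})

test_that("baseline fitting recovers generating lines and checks windows", {
  grid <- seq(15, 95, 1)
  lin <- melt_curve(grid, 2 - 0.01 * grid)
  bl <- fit_baselines(lin, c(15, 25), c(85, 95))
  expect_equal(bl$folded, c(2, -0.01), tolerance = 1e-10)
  expect_equal(bl$unfolded, c(2, -0.01), tolerance = 1e-10)
  # sigmoid with flat baselines 1 and 0
  curve <- simulate_melting_curve(55, grid = grid)
  bl2 <- fit_baselines(curve, c(15, 25), c(85, 95))
  expect_equal(bl2$folded[2], 0, tolerance = 1e-3)
  expect_equal(bl2$unfolded[1], 0, tolerance = 1e-2)
  expect_equal(bl2$folded[1], 1, tolerance = 1e-2)
  expect_error(fit_baselines(lin, c(15, 60), c(55, 95)), "overlap")
  expect_error(fit_baselines(lin, c(15, 16.5), c(85, 95)),
               "fewer than 3")
})

test_that("Tm extraction: symmetric sigmoid, affine invariance, errors", {
  grid <- seq(15, 95, 1)
  curve <- simulate_melting_curve(50, dH = 50, grid = grid)
  bl <- fit_baselines(curve, c(15, 25), c(85, 95))
  fit <- melt_tm(curve, bl)
  expect_equal(fit$tm, 50, tolerance = 0.05)
  expect_true(all(fit$theta >= 0 & fit$theta <= 1))
  # invariance under affine rescaling of the ellipticity axis
  scaled <- melt_curve(grid, 7.3 * curve$ellipticity - 2.1)
  bls <- fit_baselines(scaled, c(15, 25), c(85, 95))
  expect_equal(melt_tm(scaled, bls)$tm, fit$tm, tolerance = 1e-6)
  # incomplete transition
  flat <- melt_curve(grid, rep(1, length(grid)))
  blf <- list(folded = c(1, 0), unfolded = c(0, 0))
  expect_error(melt_tm(flat, blf), "never crosses")
})

test_that("Tm recovery bias on a 1-degree grid is below 0.2 degrees", {
  grid <- seq(15, 95, 1)
  for (tm in c(65, 67, 52.3)) {
    curve <- simulate_melting_curve(tm, grid = grid)
    bl <- fit_baselines(curve, c(15, 25), c(85, 95))
    expect_lt(abs(melt_tm(curve, bl)$tm - tm), 0.2)
  }
})

test_that("spectrum and curve containers validate their grids", {
  expect_error(cd_spectrum(c(2, 1), c(0, 0)))
  expect_error(melt_curve(c(1, 1), c(0, 0)))
  p <- withr::local_tempfile(fileext = ".tsv")
  s <- cd_component_spectrum("hybrid")
  write_cd_spectrum(s, p)
  s2 <- read_cd_spectrum(p)
  expect_equal(s2$ellipticity, s$ellipticity, tolerance = 1e-9)
  pm <- withr::local_tempfile(fileext = ".tsv")
  m <- simulate_melting_curve(60)
  write_melt_curve(m, pm)
  expect_equal(read_melt_curve(pm)$ellipticity, m$ellipticity,
               tolerance = 1e-9)
})
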