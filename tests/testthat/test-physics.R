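test_that("Mayneord Zeff matches the direct-summation oracle and its bounds", {
  # single element degenerates to Z
  expect_equal(mayneord_zeff(composition("C", 1)), 6.0)
  # water, frozen from the term-by-term oracle
  zw <- mayneord_zeff(make_composition(water_weights))
  expect_equal(zw, 7.4635331462, tolerance = 1e-9)
  expect_equal(zw, oracle_zeff(water_weights), tolerance = 1e-12)
  # within 1% of the tabulated water reference 7.42
  expect_lt(abs(zw - 7.42) / 7.42, 0.01)
  # bounds: between min and max Z of the mixture
  set.seed(11)
  for (i in 1:20) {
    w <- random_composition_weights()
    z <- mayneord_zeff(make_composition(w))
    Zs <- vapply(oracle_element_table()[names(w)], `[`, numeric(1), 1)
    expect_gte(z, min(Zs)); expect_lte(z, max(Zs))
  }
})

test_that("relative electron density is water-normalized and linear in density", {
  wat <- make_composition(water_weights)
  expect_equal(relative_electron_density(wat, 1.000), 1.000, tolerance = 1e-12)
  set.seed(12)
  w <- random_composition_weights()
  cmp <- make_composition(w)
  r1 <- relative_electron_density(cmp, 0.77)
  expect_equal(relative_electron_density(cmp, 2 * 0.77), 2 * r1,
               tolerance = 1e-12)
  expect_error(relative_electron_density(cmp, -1), "positive")
})

test_that("bundled surrogate REDs agree with manufacturer values within 0.02", {
  mats <- read_material_table()
  for (m in mats) {
    if (is.na(m$red_ref)) next
    red <- relative_electron_density(m$composition, m$mass_density)
    expect_lt(abs(red - m$red_ref), 0.02, label = m$name)
  }
})

test_that("Bragg additivity lnI: degenerate case, water oracle, monotonicity", {
  expect_equal(bragg_additivity_lnI(composition("O", 1)), log(106))
  lw <- bragg_additivity_lnI(make_composition(water_weights))
  expect_equal(lw, 4.3217518823, tolerance = 1e-9)
  expect_equal(exp(lw), 75.3, tolerance = 1e-3)
  # raising any component's I strictly increases the weighted mean
  cmp <- make_composition(water_weights)
  bumped <- composition(cmp$symbol, cmp$w, Z = cmp$Z, A = cmp$A,
                        I_eV = cmp$I_eV * c(2, 1))
  expect_gt(bragg_additivity_lnI(bumped), lw)
  # missing elemental I is an error
  noI <- composition("H", 1)
  noI$I_eV <- NA_real_
  expect_error(bragg_additivity_lnI(noI), "excitation")
})

test_that("all physics operations match independent oracles on random compositions", {
  set.seed(42)
  for (i in 1:20) {
    w <- random_composition_weights()
    cmp <- make_composition(w)
    rho <- stats::runif(1, 0.2, 2.0)
    expect_equal(mayneord_zeff(cmp), oracle_zeff(w), tolerance = 1e-10)
    expect_equal(bragg_additivity_lnI(cmp), oracle_lnI(w), tolerance = 1e-10)
    expect_equal(relative_electron_density(cmp, rho), oracle_red(w, rho),
                 tolerance = 1e-10)
    red <- stats::runif(1, 0.2, 1.9); I <- stats::runif(1, 60, 150)
    Tk <- stats::runif(1, 70, 230)
    expect_equal(bethe_bloch_rsp(red, I, Tk), oracle_rsp(red, I, Tk),
                 tolerance = 1e-10)
  }
})

test_that("Bethe-Bloch RSP identity, monotonicity and energy insensitivity", {
  # I_m = I_w makes the bracket ratio cancel: RSP == RED to machine precision
  for (Tk in c(10, 50, 100, 175, 250))
    for (red in c(0.05, 0.3, 1.0, 1.7, 2.0))
      expect_equal(bethe_bloch_rsp(red, 75.3, Tk), red, tolerance = 1e-14)
  # strictly decreasing in I_m
  Is <- seq(55, 150, by = 5)
  rsps <- bethe_bloch_rsp(rep(1.2, length(Is)), Is, 100)
  expect_true(all(diff(rsps) < 0))
  # < 1% relative change between 80 and 200 MeV
  for (I in c(60, 75.3, 90, 120)) for (red in c(0.2, 1.0, 1.9)) {
    d <- abs(bethe_bloch_rsp(red, I, 80) - bethe_bloch_rsp(red, I, 200)) /
      bethe_bloch_rsp(red, I, 100)
    expect_lt(d, 0.01)
  }
  # unphysically large I at low energy breaks the bracket
  expect_error(bethe_bloch_rsp(1.0, 5e5, 1), "bracket")
})

test_that("RSP from WET is the plain thickness ratio", {
  expect_equal(rsp_from_wet(30, 20), 1.5)
  expect_equal(rsp_from_wet(17.3, 17.3), 1.0)
  expect_equal(rsp_from_wet(0, 20), 0.0)
  expect_error(rsp_from_wet(10, 0), "thickness")
})

test_that("composition validation and renormalization behave as specified", {
  expect_error(composition(character(0), numeric(0)), "at least one")
  expect_error(composition(c("H", "O"), c(0, 0)), "all zero")
  expect_warning(cmp <- composition(c("H", "O"), c(0.12, 0.90)), "renormaliz")
  expect_equal(sum(cmp$w), 1, tolerance = 1e-12)
  expect_error(composition("Xx", 1), "unknown element")
})
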