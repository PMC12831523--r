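flat_volume <- function(value = 1, nx = 40, ny = 40, nz = 8, q = "red") {
  property_volume(array(value, c(nx, ny, nz)), spacing = c(1, 1, 2.5),
                  quantity = q)
}

test_that("Gaussian noise operator: identity, determinism, sigma recovery", {
  v <- flat_volume(1.2)
  expect_identical(add_noise(v, 0, seed = 5)$values, v$values)
  a <- add_noise(v, 0.02, seed = 99)
  b <- add_noise(v, 0.02, seed = 99)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, add_noise(v, 0.02, seed = 100)$values))
  # sample SD over >= 1e4 voxels within 5% of the injected 0.018
  big <- flat_volume(0.5, 50, 50, 5)
  n <- add_noise(big, 0.018, seed = 3)
  expect_lt(abs(stats::sd(n$values) - 0.018) / 0.018, 0.05)
  expect_lt(abs(mean(n$values) - 0.5), 3 * 0.018 / sqrt(12500))
  expect_error(add_noise(v, -0.1), ">= 0")
})

test_that("noise table presets resolve to the tabulated sigmas", {
  nm <- noise_preset("george_head_82.77")
  expect_equal(c(nm$sigma_zeff, nm$sigma_red, nm$sigma_rsp),
               c(0.028, 0.003, 0.003))
  expect_equal(noise_preset("model467_14.55")$sigma_rsp, 0.018)
  expect_error(noise_preset("atlantis_1.00"), "unknown noise preset")
  tab <- load_noise_table()
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$sigma_zeff > 0 & tab$sigma_red > 0 & tab$sigma_rsp > 0))
})

test_that("high-density proximity bias decays with distance and defaults off", {
  v <- flat_volume(1, 81, 81, 2)
  expect_identical(add_highz_bias(v, NULL)$values, v$values)
  src <- data.frame(x = 0, y = 0, amplitude = 0.05, decay_cm = 1.0)
  b <- add_highz_bias(v, src)
  ctr <- c(41, 41)
  expect_equal(b$values[ctr[1], ctr[2], 1] - 1, 0.05, tolerance = 1e-9)
  # closer voxels are biased more (1.4 cm vs 3 cm from the source)
  at <- function(dx_mm) b$values[ctr[1] + dx_mm, ctr[2], 1] - 1
  expect_gt(at(14), at(30))
  expect_equal(at(14), 0.05 * exp(-1.4), tolerance = 1e-9)
  # zero amplitude is the identity
  src0 <- data.frame(x = 0, y = 0, amplitude = 0, decay_cm = 1.0)
  expect_equal(add_highz_bias(v, src0)$values, v$values, tolerance = 0)
})

test_that("noise and bias operators conserve grid shape, spacing and labels", {
  spec <- preset_phantom("george_head")
  lab <- build_label_volume(spec, 2, 2.5, 2)
  maps <- render_property_maps(lab, spec)
  n <- add_noise(maps$red, 0.01, seed = 1)
  b <- add_highz_bias(n, data.frame(x = 1, y = 2, amplitude = 0.02,
                                    decay_cm = 2))
  for (v in list(n, b)) {
    expect_identical(dim(v$values), dim(maps$red$values))
    expect_identical(v$spacing, maps$red$spacing)
    expect_identical(v$origin, maps$red$origin)
    expect_identical(v$quantity, "red")
  }
  # the label volume itself is untouched by construction (operators copy)
  expect_identical(sort(unique(as.integer(lab$values))),
                   0:(length(spec$inserts) + 1L))
})

test_that("noise does not disturb the caller's RNG stream", {
  set.seed(123); x1 <- stats::rnorm(1)
  set.seed(123); invisible(add_noise(flat_volume(), 0.01, seed = 9))
  x2 <- stats::rnorm(1)
  expect_identical(x1, x2)
})
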