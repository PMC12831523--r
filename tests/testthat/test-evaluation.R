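test_that("tissue classification is nearest-interval and total", {
  expect_identical(classify_tissue(0.93), "fat")
  expect_identical(classify_tissue(0.200), "air_lung")
  expect_identical(classify_tissue(1.875), "bone")
  expect_identical(classify_tissue(c(0.35, 0.99, 1.05, 1.30)),
                   c("air_lung", "water", "muscle", "bone"))
  # total and deterministic over (0, 2.5]
  grid <- seq(0.01, 2.5, by = 0.01)
  c1 <- classify_tissue(grid); c2 <- classify_tissue(grid)
  expect_identical(c1, c2)
  expect_true(all(c1 %in% names(tissue_bins())))
  # every benchmark insert maps to exactly one category
  ref <- load_insert_reference()
  expect_true(all(nchar(classify_tissue(ref$red_ref)) > 0))
})

test_that("percent error and MAPE match their definitions", {
  expect_equal(percent_error(1.004, 1.000), 0.4, tolerance = 1e-9)
  expect_equal(percent_error(0.95, 1.00), -5.0)
  expect_equal(percent_error(1.23, 1.23), 0)
  expect_error(percent_error(1, 0), "non-zero")
  expect_equal(mape(c(4.90, 2.86, 1.11, 2.14, 6.30)), 3.462)
  expect_equal(mape(c(0, 0, 0)), 0)
  expect_equal(mape(-2), 2)
  expect_error(mape(numeric(0)), "empty")
  # mape(S) >= |mean(S)| on random sets
  set.seed(31)
  for (i in 1:50) {
    s <- stats::rnorm(sample(1:12, 1), sd = 3)
    expect_gte(mape(s) + 1e-12, abs(mean(s)))
  }
})

test_that("ROI means: geometry, exact noiseless recovery, noisy standard error", {
  spec <- preset_phantom("model467")
  lab <- build_label_volume(spec, 1, 2.5, 10)
  maps <- render_property_maps(lab, spec)
  ins <- spec$inserts[[1]]
  # 60% area fraction on a 28 mm insert uses a ~21.7 mm ROI circle
  expect_equal(sqrt(0.6) * ins$diameter * 10, 21.7, tolerance = 0.05)
  # noiseless constant insert returns the assigned value exactly
  expect_equal(extract_roi_mean(maps$red, ins), ins$assigned_red)
  expect_equal(extract_roi_mean(maps$zeff, ins), ins$assigned_zeff)
  # with sigma = 0.018 noise, the mean stays within 3 sigma / sqrt(N)
  noisy <- add_noise(maps$red, 0.018, seed = 8)
  v <- dectrsp:::roi_values(noisy, ins)
  expect_gt(length(v), 3000)
  expect_lt(abs(mean(v) - ins$assigned_red), 3 * 0.018 / sqrt(length(v)))
  # an insert outside the grid has no voxels
  far <- insert_spec("far", c(60, 0), 2.8, 8, 1)
  expect_error(extract_roi_mean(maps$red, far), "no voxels")
})

test_that("central-circle noise measurement recovers injected sigma", {
  spec <- preset_phantom("george_head")
  maps <- render_property_maps(build_label_volume(spec, 1, 2.5, 10), spec)
  expect_equal(noise_sigma(maps$red), 0)  # constant background
  noisy <- add_noise(maps$red, 0.003, seed = 4)
  expect_lt(abs(noise_sigma(noisy, diameter = 2.8) - 0.003) / 0.003, 0.10)
  # the nested-insert protocol (1 cm circle) also recovers sigma
  expect_lt(abs(noise_sigma(noisy, diameter = 1.0) - 0.003) / 0.003, 0.10)
  tiny <- property_volume(array(1, c(3, 3, 1)), c(10, 10, 10), quantity = "red")
  expect_error(noise_sigma(tiny, diameter = 0.1), "fewer than 2")
})

test_that("paired t-test conventions and sensitivity", {
  x <- c(1, 2, 3, 4)
  expect_equal(paired_t_test(x, x), 1)
  expect_error(paired_t_test(x, x + 1), "zero-variance")
  set.seed(9)
  a <- stats::rnorm(20, 1, 0.01)
  expect_lt(paired_t_test(a, a + 0.1 + stats::rnorm(20, 0, 0.01)), 0.01)
  b <- a + stats::rnorm(20, 0, 0.01)
  expect_equal(paired_t_test(a, b),
               stats::t.test(a - b, mu = 0)$p.value, tolerance = 1e-12)
})

test_that("summaries aggregate unrounded values with n-1 SDs", {
  rows <- benchmark_roi_results("body")
  expect_equal(nrow(rows), 56)
  rep <- summarize_evaluation(rows)
  # category counts over the Body-SFOV benchmark
  counts <- stats::setNames(rep$by_category$n, rep$by_category$category)
  expect_equal(counts[c("air_lung", "fat", "water", "muscle", "bone")],
               c(air_lung = 5, fat = 6, water = 15, muscle = 11, bone = 19))
  expect_equal(rep$overall$n, sum(rep$by_category$n))
  expect_equal(rep$overall$sd_pe, stats::sd(rows$percent_error))
  # single row: MAPE equals |PE|
  one <- summarize_evaluation(rows[7, ])
  expect_equal(one$overall$mape, abs(rows$percent_error[7]))
  # mixing quantities is refused
  mixed <- rows; mixed$quantity[1] <- "red"
  expect_error(summarize_evaluation(mixed), "mixed quantities")
})

test_that("report files carry the rounding conventions", {
  rows <- benchmark_roi_results("body")
  rep <- summarize_evaluation(rows)
  dir <- withr::local_tempdir()
  write_evaluation_report(rep, dir, metadata = list(seed = 1, energy_mev = 100))
  per <- utils::read.csv(file.path(dir, "per_insert.csv"))
  expect_equal(nrow(per), 56)
  expect_true(all(abs(per$percent_error * 100 -
                        round(per$percent_error * 100)) < 1e-9))
  bc <- utils::read.csv(file.path(dir, "by_category.csv"))
  expect_identical(bc$category[nrow(bc)], "overall")
  meta <- jsonlite::read_json(file.path(dir, "run_metadata.json"))
  expect_equal(meta$seed, 1)
  expect_true(!is.null(meta$package_version))
})
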