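edge_gap <- function(spec, a, b) {
  nm <- vapply(spec$inserts, function(x) x$name, character(1))
  ia <- spec$inserts[[match(a, nm)]]; ib <- spec$inserts[[match(b, nm)]]
  sqrt(sum((ia$center - ib$center)^2)) - (ia$diameter + ib$diameter) / 2
}

test_that("preset insert complements match the published benchmark", {
  counts <- c(model467 = 16, george_body = 6, george_head = 8,
              aed_body = 16, aed_head = 10)
  ref <- load_insert_reference()
  for (p in names(counts)) {
    spec <- preset_phantom(p)
    nm <- sort(vapply(spec$inserts, function(x) x$name, character(1)))
    expect_length(spec$inserts, counts[[p]])
    expect_identical(nm, sort(ref$insert[ref$phantom == p]))
    for (ins in spec$inserts) {
      row <- ref[ref$phantom == p & ref$insert == ins$name, ]
      expect_equal(ins$assigned_red, row$red_ref)
      expect_equal(ins$assigned_zeff, row$zeff_ref)
    }
  }
  expect_equal(preset_phantom("model467")$outline$diameter, 33)
  expect_equal(preset_phantom("george_body")$outline$diameter, 27)
  expect_equal(preset_phantom("george_head")$outline$diameter, 18)
  expect_equal(preset_phantom("aed_head")$outline$diameter, 20)
  ell <- preset_phantom("aed_body")$outline
  expect_equal(c(ell$width, ell$height), c(40, 30))
  expect_equal(ell$equivalent_diameter, sqrt(40 * 30), tolerance = 0.01)
  expect_error(preset_phantom("nope"))
})

test_that("preset geometry honors the published distances within one voxel", {
  tol <- 0.1  # cm, one 1 mm voxel
  m  <- preset_phantom("model467")
  nm <- vapply(m$inserts, function(x) x$name, character(1))
  # outer plugs: edge 12 cm from center, 5 cm apart; inner: 7 cm, 1.4 cm apart
  outer <- c("Adipose", "Breast", "LN-300", "LN-450", "Solid Water 1",
             "Solid Water 2", "B-200", "Inner bone")
  for (x in outer) {
    ins <- m$inserts[[match(x, nm)]]
    expect_equal(sqrt(sum(ins$center^2)) + ins$diameter / 2, 12,
                 tolerance = 1e-9)
  }
  expect_equal(edge_gap(m, "Adipose", "Breast"), 5, tolerance = tol)
  expect_lt(abs(edge_gap(m, "Brain", "Cortical bone") - 1.4), tol)
  # closest outer-inner distance is 3 cm
  inner <- setdiff(nm, outer)
  gaps <- c(outer(match(outer, nm), match(inner, nm),
                  Vectorize(function(i, j) edge_gap(m, nm[i], nm[j]))))
  expect_lt(abs(min(gaps) - 3), tol)

  gb <- preset_phantom("george_body")
  expect_equal(edge_gap(gb, "Brain", "Spinal cord"), 3.5, tolerance = 1e-9)
  expect_equal(sqrt(sum(gb$inserts[[1]]$center^2)) +
                 gb$inserts[[1]]$diameter / 2, 10, tolerance = 1e-9)

  gh <- preset_phantom("george_head")
  expect_equal(edge_gap(gh, "Dentin", "Enamel"), 3.3, tolerance = 1e-9)
  expect_equal(edge_gap(gh, "Enamel", "Cortical bone"), 3.3, tolerance = 1e-9)
  # sinus sits between enamel and cortical bone, 1.6 cm from each edge
  expect_equal(edge_gap(gh, "Sinus", "Enamel"), 1.6, tolerance = 1e-9)
  expect_equal(edge_gap(gh, "Sinus", "Cortical bone"), 1.6, tolerance = 1e-9)
})

test_that("voxelization labels voxels by the voxel-center rule", {
  # one 28 mm insert: labeled area per slice within 3% of pi * 14^2
  solo <- phantom_spec("solo", list(type = "circle", diameter = 20),
                       background = list(zeff = 7.5, red = 1.0),
                       inserts = list(insert_spec("plug", c(0, 3), 2.8,
                                                  assigned_zeff = 10,
                                                  assigned_red = 1.2)))
  lab <- build_label_volume(solo, 1, 2.5, 3)
  per_slice <- sum(lab$values[, , 1] == 2L)
  expect_lt(abs(per_slice - pi * 14^2) / (pi * 14^2), 0.03)
  # labels identical across slices
  expect_identical(lab$values[, , 1], lab$values[, , 3])
  # model467 center is background; corners (outside outline) are labeled 0
  m467 <- build_label_volume(preset_phantom("model467"), 1, 2.5, 1)
  d <- dim(m467)
  expect_identical(m467$values[ceiling(d[1] / 2), ceiling(d[2] / 2), 1], 1L)
  expect_identical(m467$values[1, 1, 1], 0L)
  # overlapping inserts fail at spec construction already
  expect_error(phantom_spec("bad", list(type = "circle", diameter = 20),
                            background = list(zeff = 7.5, red = 1.0),
                            inserts = list(
                              insert_spec("a", c(0, 0), 3, 8, 1),
                              insert_spec("b", c(1, 0), 3, 8, 1))),
               "overlap")
  expect_error(phantom_spec("out", list(type = "circle", diameter = 10),
                            background = list(zeff = 7.5, red = 1.0),
                            inserts = list(insert_spec("a", c(4.5, 0), 3, 8, 1))),
               "outside")
})

test_that("rendered property maps are piecewise constant with the assigned values", {
  gh <- preset_phantom("george_head")
  lab <- build_label_volume(gh, 1, 2.5, 2)
  maps <- render_property_maps(lab, gh)
  nm <- vapply(gh$inserts, function(x) x$name, character(1))
  sinus_lab <- match("Sinus", nm) + 1L
  expect_true(all(maps$red$values[lab$values == sinus_lab] == 0.200))
  expect_true(all(maps$zeff$values[lab$values == sinus_lab] == 7.42))
  # outside voxels carry air values
  expect_true(all(maps$red$values[lab$values == 0L] == 0.001))
  # model467 true-water plug renders RED 1.00, Zeff 7.42
  m <- preset_phantom("model467")
  labm <- build_label_volume(m, 1, 2.5, 1)
  mm <- render_property_maps(labm, m)
  tw <- match("True Water", vapply(m$inserts, function(x) x$name,
                                   character(1))) + 1L
  expect_true(all(mm$red$values[labm$values == tw] == 1.00))
  expect_true(all(mm$zeff$values[labm$values == tw] == 7.42))
  # an insert-free phantom renders constant inside the outline
  solo <- phantom_spec("bg", list(type = "circle", diameter = 12),
                       background = list(zeff = 7.5, red = 1.0),
                       inserts = list())
  ms <- render_property_maps(build_label_volume(solo, 1, 2.5, 1), solo)
  expect_identical(unique(as.numeric(ms$red$values)), c(0.001, 1.0))
})
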