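#' Cylindrical insert specification
#'
#' One tissue-equivalent plug: in-plane position and diameter (cm, phantom
#' centered coordinates) plus the Zeff/RED values the synthetic generator
#' assigns to its voxels and the reference values it is scored against.
#'
#' @param name Insert name.
#' @param center In-plane center `(x, y)` in cm.
#' @param diameter Insert diameter in cm (> 0).
#' @param assigned_zeff,assigned_red Noise-free values painted into the
#'   synthetic Zeff/RED maps (> 0).
#' @param red_ref,zeff_ref,rsp_ref,rsp_ref_sd Reference values used by the
#'   evaluation; default to the assigned values where they apply.
#' @return An object of class `insert_spec`.
#' @export
insert_spec <- function(name, center, diameter, assigned_zeff, assigned_red,
                        red_ref = assigned_red, zeff_ref = assigned_zeff,
                        rsp_ref = NA_real_, rsp_ref_sd = NA_real_) {
  stopifnot(length(center) == 2L, is.finite(diameter), diameter > 0,
            assigned_zeff > 0, assigned_red > 0)
  structure(list(name = name, center = as.numeric(center),
                 diameter = diameter, assigned_zeff = assigned_zeff,
                 assigned_red = assigned_red, red_ref = red_ref,
                 zeff_ref = zeff_ref, rsp_ref = rsp_ref,
                 rsp_ref_sd = rsp_ref_sd),
            class = "insert_spec")
}

#' Phantom specification
#'
#' Outer shape, background material values, and positioned inserts. The
#' constructor validates that inserts are pairwise non-overlapping and lie
#' fully inside the outline.
#'
#' @param name Phantom name.
#' @param outline Either `list(type = "circle", diameter = <cm>)` or
#'   `list(type = "ellipse", width = <cm>, height = <cm>)`; for an ellipse the
#'   equivalent-circle diameter `sqrt(width * height)` is recorded.
#' @param background List with `zeff` and `red` for the background material.
#' @param inserts List of [insert_spec()] objects.
#' @param height Phantom height (cm).
#' @param slice_thickness Native scanning slice thickness (cm).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(name, outline, background, inserts, height = 5,
                         slice_thickness = 0.25) {
  stopifnot(outline$type %in% c("circle", "ellipse"),
            is.numeric(background$zeff), is.numeric(background$red))
  if (outline$type == "circle") {
    stopifnot(outline$diameter > 0)
    outline$equivalent_diameter <- outline$diameter
  } else {
    stopifnot(outline$width > 0, outline$height > 0)
    outline$equivalent_diameter <- sqrt(outline$width * outline$height)
  }
  for (ins in inserts) {
    stopifnot(inherits(ins, "insert_spec"))
    r <- ins$diameter / 2
    inside <- if (outline$type == "circle") {
      sqrt(sum(ins$center^2)) + r <= outline$diameter / 2 + 1e-9
    } else {
      a <- outline$width / 2 - r; b <- outline$height / 2 - r
      (ins$center[1] / a)^2 + (ins$center[2] / b)^2 <= 1 + 1e-9
    }
    if (!inside)
      stop(sprintf("insert '%s' extends outside the phantom outline", ins$name),
           call. = FALSE)
  }
  if (length(inserts) > 1L) {
    for (i in seq_len(length(inserts) - 1L)) for (j in (i + 1L):length(inserts)) {
      d <- sqrt(sum((inserts[[i]]$center - inserts[[j]]$center)^2))
      if (d < (inserts[[i]]$diameter + inserts[[j]]$diameter) / 2 - 1e-9)
        stop(sprintf("inserts '%s' and '%s' overlap", inserts[[i]]$name,
                     inserts[[j]]$name), call. = FALSE)
    }
  }
  structure(list(name = name, outline = outline, background = background,
                 inserts = inserts, height = height,
                 slice_thickness = slice_thickness),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  shape <- if (x$outline$type == "circle")
    sprintf("circle %.1f cm", x$outline$diameter)
  else sprintf("ellipse %.1f x %.1f cm", x$outline$width, x$outline$height)
  cat(sprintf("<phantom_spec> %s: %s, %d inserts\n", x$name, shape,
              length(x$inserts)))
  invisible(x)
}

# place n inserts sequentially on a ring: exact chord spacing between
# neighbors (chord = diameter + printed edge gap), starting at theta0
ring_centers <- function(radius, chord, n, theta0 = pi / 2) {
  dtheta <- 2 * asin(chord / (2 * radius))
  th <- theta0 + (seq_len(n) - 1) * dtheta
  cbind(radius * cos(th), radius * sin(th))
}

# assigned/reference values for a preset's inserts, from the bundled benchmark
preset_insert_values <- function(phantom) {
  ref <- load_insert_reference()
  ref[ref$phantom == phantom, , drop = FALSE]
}

make_inserts <- function(phantom, names, centers, diameter) {
  vals <- preset_insert_values(phantom)
  idx <- match(names, vals$insert)
  if (any(is.na(idx)))
    stop("unknown insert name(s) for ", phantom, ": ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  lapply(seq_along(names), function(i) {
    v <- vals[idx[i], ]
    insert_spec(v$insert, centers[i, ], diameter,
                assigned_zeff = v$zeff_ref, assigned_red = v$red_ref,
                rsp_ref = v$rsp_ref, rsp_ref_sd = v$rsp_ref_sd)
  })
}

#' Preset phantom geometries
#'
#' Builds one of the five benchmark phantoms with the insert complement of the
#' bundled per-insert reference table and the published geometry:
#'
#' * `model467` -- 33 cm disk; outer ring of 8 plugs 12 cm from center to plug
#'   edge with 5 cm edge gaps, inner ring of 8 plugs 7 cm from center to plug
#'   edge with 1.4 cm edge gaps, rings interleaved so the closest outer-inner
#'   edge distance is 3 cm.
#' * `george_body` -- 27 cm disk; single ring 10 cm from center to plug edge,
#'   3.5 cm edge gaps.
#' * `george_head` -- 18 cm disk; single ring 7 cm from center to plug edge,
#'   3.3 cm edge gaps; the sinus plug sits between enamel and cortical bone,
#'   1.6 cm from each plug edge. Plugs are 2.0 cm in diameter (eight 2.8 cm
#'   plugs cannot honor the printed spacings inside an 18 cm outline).
#' * `aed_body` -- 40 x 30 cm ellipse; 20 cm head region at center holding a
#'   central solid-water plug and a ring of 9, plus 6 outer plugs in the body
#'   section.
#' * `aed_head` -- 20 cm disk with the same 10-plug head layout.
#'
#' Plug diameters default to 2.8 cm. Angular start positions are arbitrary
#' (the captions constrain only distances) and documented here as chosen.
#'
#' @param name Preset name.
#' @return A [phantom_spec()].
#' @examples
#' preset_phantom("george_head")
#' @export
preset_phantom <- function(name = c("model467", "aed_body", "aed_head",
                                    "george_body", "george_head")) {
  name <- match.arg(name)
  d <- 2.8
  air <- list(zeff = 7.69, red = 0.001)
  switch(name,
    model467 = {
      outer_names <- c("Adipose", "Breast", "LN-300", "LN-450",
                       "Solid Water 1", "Solid Water 2", "B-200", "Inner bone")
      inner_names <- c("Brain", "Cortical bone", "CB2-30%", "CB2-50%",
                       "Liver", "Solid Water 3", "Solid Water 4", "True Water")
      r_out <- 12 - d / 2; r_in <- 7 - d / 2
      # shared angular increment set by the outer-ring 5 cm gap; the half-step
      # interleave puts the closest outer-inner edge distance at 3 cm and the
      # inner neighbors at 1.4 cm, all within half a voxel of the published
      # distances
      dtheta <- 2 * asin((d + 5) / (2 * r_out))
      th_o <- pi / 2 + (0:7) * dtheta
      th_i <- pi / 2 + dtheta / 2 + (0:7) * dtheta
      centers <- rbind(cbind(r_out * cos(th_o), r_out * sin(th_o)),
                       cbind(r_in * cos(th_i), r_in * sin(th_i)))
      phantom_spec("model467", list(type = "circle", diameter = 33),
                   background = list(zeff = 7.59, red = 0.99),
                   inserts = make_inserts("model467",
                                          c(outer_names, inner_names),
                                          centers, d))
    },
    george_body = {
      nm <- c("Brain", "Spinal cord", "Spinal disk", "Trabecular bone",
              "Cortical bone", "Enamel")
      centers <- ring_centers(10 - d / 2, d + 3.5, length(nm))
      phantom_spec("george_body", list(type = "circle", diameter = 27),
                   background = list(zeff = 6.20, red = 0.96),
                   inserts = make_inserts("george_body", nm, centers, d))
    },
    george_head = {
      dg <- 2.0
      nm <- c("Brain", "Spinal cord", "Spinal disk", "Trabecular bone",
              "Dentin", "Enamel", "Cortical bone")
      r <- 7 - dg / 2
      chord <- dg + 3.3
      dtheta <- 2 * asin(chord / (2 * r))
      centers <- ring_centers(r, chord, length(nm))
      # sinus: between enamel (k=6) and cortical bone (k=7), 1.6 cm from each
      # plug edge, displaced toward the phantom center
      gap_c <- 1.6 + dg            # center-to-center distance to each neighbor
      th_mid <- pi / 2 + 5.5 * dtheta
      r_mid <- r * cos(dtheta / 2)
      r_sinus <- r_mid - sqrt(gap_c^2 - (chord / 2)^2)
      centers <- rbind(centers, c(r_sinus * cos(th_mid), r_sinus * sin(th_mid)))
      phantom_spec("george_head", list(type = "circle", diameter = 18),
                   background = list(zeff = 6.20, red = 0.96),
                   inserts = make_inserts("george_head", c(nm, "Sinus"),
                                          centers, dg))
    },
    aed_body = {
      head_nm <- c("Adipose", "Brain", "Breast", "CaCO3 30%", "CaCO3 50%",
                   "Cortical bone", "Solid Water 2", "Solid Water 3",
                   "True Water 1")
      body_nm <- c("Inner bone", "Liver", "LN-300", "LN-450", "Solid Water 4",
                   "True Water 2")
      th <- pi / 2 + (0:8) * 2 * pi / 9
      head_centers <- cbind(6.5 * cos(th), 6.5 * sin(th))
      tb <- pi / 2 + (0:5) * pi / 3
      body_centers <- cbind(16.5 * cos(tb), 11.5 * sin(tb))
      centers <- rbind(c(0, 0), head_centers, body_centers)
      phantom_spec("aed_body", list(type = "ellipse", width = 40, height = 30),
                   background = list(zeff = 7.45, red = 1.00),
                   inserts = make_inserts("aed_body",
                                          c("Solid Water 1", head_nm, body_nm),
                                          centers, d),
                   height = 16.5)
    },
    aed_head = {
      head_nm <- c("Adipose", "Brain", "Breast", "CaCO3 30%", "CaCO3 50%",
                   "Cortical bone", "Solid Water 2", "Solid Water 3",
                   "True Water 1")
      th <- pi / 2 + (0:8) * 2 * pi / 9
      centers <- rbind(c(0, 0), cbind(6.5 * cos(th), 6.5 * sin(th)))
      phantom_spec("aed_head", list(type = "circle", diameter = 20),
                   background = list(zeff = 7.45, red = 1.00),
                   inserts = make_inserts("aed_head",
                                          c("Solid Water 1", head_nm),
                                          centers, d),
                   height = 16.5)
    })
}

#' Voxelize a phantom into a label volume
#'
#' Labels every voxel by the voxel-center-in-shape rule: `0` outside the
#' outline, `1` background, `1 + k` for insert `k` (in `spec$inserts` order).
#' Labels are identical across slices. The grid is centered on the phantom
#' with a 10 mm in-plane margin around the outline.
#'
#' @param spec A [phantom_spec()].
#' @param in_plane_spacing In-plane voxel size in mm (default 1).
#' @param slice_thickness Slice thickness in mm (default 2.5).
#' @param n_slices Number of slices (default 10).
#' @return A [property_volume()] with `quantity = "label"`.
#' @export
build_label_volume <- function(spec, in_plane_spacing = 1,
                               slice_thickness = 2.5, n_slices = 10) {
  stopifnot(inherits(spec, "phantom_spec"), in_plane_spacing > 0,
            slice_thickness > 0, n_slices >= 1)
  ext <- if (spec$outline$type == "circle")
    c(spec$outline$diameter, spec$outline$diameter) * 10
  else c(spec$outline$width, spec$outline$height) * 10
  margin <- 10
  nx <- ceiling((ext[1] + 2 * margin) / in_plane_spacing)
  ny <- ceiling((ext[2] + 2 * margin) / in_plane_spacing)
  x <- (seq_len(nx) - (nx + 1) / 2) * in_plane_spacing   # mm, phantom center 0
  y <- (seq_len(ny) - (ny + 1) / 2) * in_plane_spacing
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  inside <- if (spec$outline$type == "circle") {
    X^2 + Y^2 <= (spec$outline$diameter * 10 / 2)^2
  } else {
    (X / (spec$outline$width * 10 / 2))^2 +
      (Y / (spec$outline$height * 10 / 2))^2 <= 1
  }
  lab <- matrix(0L, nx, ny)
  lab[inside] <- 1L
  for (k in seq_along(spec$inserts)) {
    ins <- spec$inserts[[k]]
    m <- (X - ins$center[1] * 10)^2 + (Y - ins$center[2] * 10)^2 <=
      (ins$diameter * 10 / 2)^2
    if (any(lab[m] > 1L))
      stop(sprintf("insert '%s' overlaps another insert after voxelization",
                   ins$name), call. = FALSE)
    lab[m] <- k + 1L
  }
  arr <- array(lab, dim = c(nx, ny, n_slices))
  vol <- property_volume(arr, spacing = c(in_plane_spacing, in_plane_spacing,
                                          slice_thickness),
                         origin = c(x[1], y[1], 0), quantity = "label")
  vol
}

#' Render piecewise-constant Zeff and RED maps from a label volume
#'
#' Each insert voxel takes the insert's assigned Zeff/RED, background voxels
#' the background-material values, and outside-outline voxels air values
#' (Zeff 7.69, RED 0.001; a small positive RED floor avoids downstream
#' division by zero).
#'
#' @param labels Label volume from [build_label_volume()].
#' @param spec The matching [phantom_spec()].
#' @return A list with elements `zeff` and `red` ([property_volume()]s on the
#'   label grid).
#' @export
render_property_maps <- function(labels, spec) {
  stopifnot(inherits(labels, "property_volume"), labels$quantity == "label",
            inherits(spec, "phantom_spec"))
  k <- length(spec$inserts)
  if (max(labels$values) > k + 1L)
    stop("label volume refers to more inserts than the spec defines",
         call. = FALSE)
  az <- vapply(spec$inserts, function(i) i$assigned_zeff, numeric(1))
  ar <- vapply(spec$inserts, function(i) i$assigned_red, numeric(1))
  if (any(!is.finite(az)) || any(!is.finite(ar)))
    stop("every insert needs assigned zeff and red values", call. = FALSE)
  zeff_lut <- c(7.69, spec$background$zeff, az)      # labels 0, 1, 1+k
  red_lut <- c(0.001, spec$background$red, ar)
  idx <- as.integer(labels$values) + 1L
  mk <- function(lut, q) property_volume(
    array(lut[idx], dim = dim(labels$values)), spacing = labels$spacing,
    origin = labels$origin, quantity = q)
  list(zeff = mk(zeff_lut, "zeff"), red = mk(red_lut, "red"))
}
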