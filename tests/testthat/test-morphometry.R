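test_that("tight phantom measurements recover the generator dimensions", {
  ph <- canonical_ribbon_phantom("tight")   # identity imaging
  rb <- measure_ribbon(ph$grid, ph$lines)
  expect_equal(rb$n_sheets, 2L)
  expect_lt(abs(rb$om_to_closest_sheet_nm - 16), 0.35)
  expect_length(rb$intersheet_nm, 1)
  expect_lt(abs(rb$intersheet_nm - 16), 0.35)
  expect_equal(rb$configuration, "tight")

  bl <- measure_belt(ph$grid, ph$lines)
  expect_equal(bl$n_layers, 3L)
  expect_lt(abs(bl$im_to_belt_nm - 24), 0.35)
  expect_length(bl$belt_interlayer_nm, 2)
  expect_lt(max(abs(bl$belt_interlayer_nm - 15)), 0.35)

  rec <- tidy(rb, tomogram_id = "tight_1")
  expect_setequal(rec$quantity, c("om_to_sheet", "intersheet_1"))
  expect_true(all(rec$value_nm > 0))
})

test_that("loose phantom is measured and classified as loose", {
  ph <- canonical_ribbon_phantom("loose")
  rb <- measure_ribbon(ph$grid, ph$lines)
  expect_equal(rb$n_sheets, 1L)
  expect_lt(abs(rb$om_to_closest_sheet_nm - 99), 0.35)
  expect_equal(rb$configuration, "loose")
})

test_that("a membrane-only phantom yields zero sheets and no configuration", {
  vox <- 0.7
  spec <- phantom_spec(c(24, 128, 24), vox,
                       layers = layer_spec("OM", 0, 6, amplitude = 1))
  ph <- render_phantom(spec)
  ext <- (dim(ph$grid$data) - 1) * vox
  ln <- line_annotation("r1", c(ext[1] / 2, ph$reference_nm - 12, ext[3] / 2),
                        c(ext[1] / 2, ext[2] - 2, ext[3] / 2),
                        averaging_width_nm = 6, averaging_depth_nm = 6,
                        role = "ribbon_normal")
  rb <- measure_ribbon(ph$grid, ln)
  expect_equal(rb$n_sheets, 0L)
  expect_true(rb$configuration_undefined)
  expect_true(is.na(rb$configuration))
})

test_that("featureless lines are rejected naming the line", {
  g <- voxel_grid(array(0, c(16, 64, 16)), 1)
  ln <- line_annotation("empty1", c(7, 5, 7), c(7, 55, 7),
                        averaging_width_nm = 4, averaging_depth_nm = 4,
                        role = "ribbon_normal")
  expect_error(measure_ribbon(g, ln), "empty1")
  ln_b <- dplyr::mutate(ln, role = "belt_normal")
  expect_error(measure_belt(g, ln_b), "empty1")
})

test_that("single-layer belts have an empty interlayer list", {
  vox <- 0.7
  spec <- phantom_spec(
    c(24, 128, 24), vox,
    layers = rbind(layer_spec("IM", 0, 6, amplitude = 1),
                   layer_spec("belt_layer", -24, 6, amplitude = 0.7))
  )
  ph <- render_phantom(spec)
  ext <- (dim(ph$grid$data) - 1) * vox
  ln <- line_annotation("b1", c(ext[1] / 2, 2, ext[3] / 2),
                        c(ext[1] / 2, ph$reference_nm + 12, ext[3] / 2),
                        averaging_width_nm = 6, averaging_depth_nm = 6,
                        role = "belt_normal")
  bl <- measure_belt(ph$grid, ln)
  expect_equal(bl$n_layers, 1L)
  expect_length(bl$belt_interlayer_nm, 0)
  expect_lt(abs(bl$im_to_belt_nm - 24), 0.35)
})

test_that("configuration classification is a strict 40 nm boundary", {
  expect_equal(classify_configuration(16), "tight")
  expect_equal(classify_configuration(99), "loose")
  expect_equal(classify_configuration(40), "tight")
  expect_equal(classify_configuration(40.01), "loose")
  expect_error(classify_configuration(-3), "> 0")
  # monotone: increasing distance never flips loose back to tight
  d <- seq(1, 120, by = 0.5)
  cls <- classify_configuration(d)
  expect_true(all(diff(cls == "loose") >= 0))
})

test_that("fibril diameter is recovered by FWHM within the blur uncertainty", {
  ph <- canonical_ribbon_phantom("fibril")
  ln <- ph$lines[ph$lines$role == "fibril", ]
  d0 <- estimate_fibril_diameter(ph$grid, ln)
  expect_equal(d0, 11, tolerance = 0.7 / 11)

  # a 2 nm blur rounds the disc profile: the estimate moves by well under
  # the reported 2 nm spread (FWHM grows monotonically only for slab-like
  # profiles; a disc cross-section loses its shoulders instead)
  blurred <- apply_psf(ph$grid, 2)
  d2 <- estimate_fibril_diameter(blurred, ln)
  expect_lt(abs(d2 - 11), 2)

  along_axis <- line_annotation("bad", c(10, 50, 10), c(10, 120, 10))
  expect_error(estimate_fibril_diameter(ph$grid, along_axis, c(0, 1, 0)),
               "perpendicular")
})

test_that("masked threshold segmentation matches analytic slab fractions", {
  vox <- 1
  spec <- phantom_spec(c(20, 100, 20), vox,
                       layers = layer_spec("sheet", 0, thickness_nm = 10,
                                           amplitude = 1),
                       reference_nm = 49.5)
  ph <- render_phantom(spec)
  mask <- array(TRUE, dim(ph$grid$data))

  expect_equal(masked_threshold_segment(ph$grid, mask,
                                        min(ph$grid$data))$volume_fraction, 1)

  # mask away the slab region entirely: nothing above background remains
  mask_bg <- mask
  mask_bg[, 30:70, ] <- FALSE
  expect_equal(masked_threshold_segment(ph$grid, mask_bg, 0.5)$volume_fraction, 0)

  # 10-voxel slab in a 100-voxel column = 10% of the full mask
  seg <- masked_threshold_segment(ph$grid, mask, 0.5)
  expect_equal(seg$volume_fraction, 0.10, tolerance = 0.01 / 0.10)

  # fraction is non-increasing in threshold
  fr <- vapply(seq(0.05, 1, by = 0.05), function(th) {
    masked_threshold_segment(ph$grid, mask, th)$volume_fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))

  expect_error(masked_threshold_segment(ph$grid, mask & FALSE, 0.5),
               "empty mask")
  expect_error(masked_threshold_segment(ph$grid, mask[, , 1:5], 0.5), "shape")
})
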