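test_that("a uniform volume yields a flagged degenerate profile of 0.5", {
  g <- voxel_grid(array(1.3, c(16, 64, 16)), 1)
  ln <- line_annotation("l", c(7, 5, 7), c(7, 55, 7),
                        averaging_width_nm = 4, averaging_depth_nm = 4)
  pr <- extract_profile(g, ln)
  expect_true(attr(pr, "degenerate"))
  expect_true(all(pr$density == 0.5))
})

test_that("profiles are normalised to [0, 1] and normalisation is idempotent", {
  ph <- two_sheet_fixture()
  pr <- extract_profile(ph$grid, ph$line)
  expect_equal(range(pr$density), c(0, 1))
  renorm <- (pr$density - min(pr$density)) /
    (max(pr$density) - min(pr$density))
  expect_equal(renorm, pr$density)
  expect_equal(unique(round(diff(pr$position_nm), 10)),
               attr(pr, "step_nm"))
})

test_that("a two-slab phantom shows exactly two maxima at the slab offsets", {
  ph <- two_sheet_fixture(sep_nm = 16)
  pr <- extract_profile(ph$grid, ph$line)
  pk <- detect_peaks(pr)
  expect_equal(nrow(pk), 2)
  # slabs sit at reference and reference + 16 in grid coordinates; the
  # line starts at y = 2 nm
  expected <- ph$reference_nm + c(0, 16) - 2
  expect_lt(max(abs(pk$position_nm - expected)), 0.5 * 0.7)
})

test_that("widening the averaging rectangle does not increase noise variance", {
  ph <- slab_fixture()
  ext <- (dim(ph$grid$data) - 1) * 0.7
  narrow <- line_annotation("n", c(ext[1] / 2, 2, ext[3] / 2),
                            c(ext[1] / 2, ext[2] - 2, ext[3] / 2),
                            averaging_width_nm = 2, averaging_depth_nm = 2)
  wide <- line_annotation("w", c(ext[1] / 2, 2, ext[3] / 2),
                          c(ext[1] / 2, ext[2] - 2, ext[3] / 2),
                          averaging_width_nm = 8, averaging_depth_nm = 8)
  resid_var <- function(grid, ln) {
    pr <- extract_profile(grid, ln)
    rng <- attr(pr, "raw_range")
    tail_region <- pr$density[pr$position_nm > 60]  # pure background
    var(tail_region) * diff(rng)^2                  # raw intensity scale
  }
  worse <- 0
  for (s in 1:20) {
    noisy <- add_noise(ph$grid, 0.5, s)
    if (resid_var(noisy, wide) > resid_var(noisy, narrow)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("lines exiting the grid are rejected", {
  g <- voxel_grid(array(0, c(8, 32, 8)), 1)
  ln <- line_annotation("out", c(3, 5, 3), c(3, 80, 3))
  expect_error(extract_profile(g, ln), "exits the grid")
})

test_that("step size larger than a voxel is rejected", {
  g <- voxel_grid(array(0, c(8, 32, 8)), 1)
  ln <- line_annotation("l", c(3, 5, 3), c(3, 25, 3),
                        averaging_width_nm = 2, averaging_depth_nm = 2)
  expect_error(extract_profile(g, ln, step_nm = 2), "step_nm")
})

test_that("a Gaussian bump is detected at its centre to 0.1 nm", {
  x <- seq(0, 100, by = 0.35)
  pr <- make_profile(x, exp(-(x - 50)^2 / (2 * 9)))
  pk <- detect_peaks(pr)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$position_nm - 50), 0.1)
})

test_that("separation and prominence thresholds gate peak detection", {
  x <- seq(0, 60, by = 0.35)
  two_bumps <- 0.5 * exp(-(x - 20)^2 / 8) + 0.5 * exp(-(x - 36)^2 / 8)
  pr <- make_profile(x, two_bumps)
  expect_equal(nrow(detect_peaks(pr, min_prominence = 0.1,
                                 min_separation_nm = 8)), 2)
  expect_equal(nrow(detect_peaks(pr, min_prominence = 0.9,
                                 min_separation_nm = 8)), 0)
  # separation above the bump spacing keeps only the higher peak
  expect_equal(nrow(detect_peaks(pr, min_prominence = 0.1,
                                 min_separation_nm = 20)), 1)
})

test_that("peak_to_peak is symmetric plain arithmetic with index checks", {
  pk <- tibble::tibble(position_nm = c(10, 26), height = 1, prominence = 1)
  expect_equal(peak_to_peak(pk, 1, 2), 16)
  expect_equal(peak_to_peak(pk, 2, 1), 16)
  expect_error(peak_to_peak(pk, 1, 1), "differ")
  expect_error(peak_to_peak(pk, 1, 3), "out of range")
})

test_that("pipeline recovers a 16 nm spacing to half a voxel without noise", {
  ph <- two_sheet_fixture(sep_nm = 16)
  pk <- detect_peaks(extract_profile(ph$grid, ph$line))
  expect_lt(abs(peak_to_peak(pk, 1, 2) - 16), 0.35)
})

test_that("FWHM matches analytic widths for Gaussian and top-hat peaks", {
  x <- seq(0, 60, by = 0.35)
  gauss <- make_profile(x, exp(-(x - 30)^2 / (2 * 9)))   # sigma = 3
  pk <- detect_peaks(gauss)
  expect_equal(profile_fwhm(gauss, pk[1, ]), 2 * sqrt(2 * log(2)) * 3,
               tolerance = 0.1 / 7.06)

  ph <- slab_fixture(thickness_nm = 10)
  pr <- extract_profile(ph$grid, ph$line)
  pk <- detect_peaks(pr)
  expect_equal(profile_fwhm(pr, pk[1, ]), 10, tolerance = 0.7 / 10)
})

test_that("slab FWHM grows monotonically with blur", {
  ph <- slab_fixture(thickness_nm = 10)
  w <- vapply(c(2, 4), function(s) {
    pr <- extract_profile(apply_psf(ph$grid, s), ph$line)
    pk <- detect_peaks(pr)
    profile_fwhm(pr, pk[which.max(pk$height), ])
  }, numeric(1))
  expect_gt(w[2], w[1])
})

test_that("truncated peaks are rejected by the width estimator", {
  x <- seq(0, 20, by = 0.5)
  rising <- make_profile(x, x / 20)   # monotone: no left crossing for end peak
  pk <- tibble::tibble(position_nm = 20, height = 1, prominence = 1)
  expect_error(profile_fwhm(rising, pk), "truncated")
})

test_that("peak spacings are invariant to affine intensity rescaling", {
  ph <- two_sheet_fixture(sep_nm = 16)
  rescaled <- voxel_grid(2.7 * ph$grid$data + 5, ph$grid$voxel_size_nm)
  pk1 <- detect_peaks(extract_profile(ph$grid, ph$line))
  pk2 <- detect_peaks(extract_profile(rescaled, ph$line))
  expect_equal(peak_to_peak(pk1, 1, 2), peak_to_peak(pk2, 1, 2),
               tolerance = 1e-10)
})

test_that("reversing the line leaves pairwise distances unchanged", {
  ph <- two_sheet_fixture(sep_nm = 16)
  fwd <- ph$line
  rev <- line_annotation("rev", fwd$end_nm[[1]], fwd$start_nm[[1]],
                         fwd$averaging_width_nm, fwd$averaging_depth_nm)
  pk_f <- detect_peaks(extract_profile(ph$grid, fwd))
  pk_r <- detect_peaks(extract_profile(ph$grid, rev))
  expect_equal(peak_to_peak(pk_f, 1, 2), peak_to_peak(pk_r, 1, 2),
               tolerance = 1e-6)
})
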