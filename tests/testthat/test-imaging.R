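# Direct-space circular separable convolution with a sampled Gaussian:
# brute-force oracle for apply_psf.
direct_gauss_blur <- function(a, sigma_vox) {
  n_half <- ceiling(6 * sigma_vox)
  offs <- (-n_half):n_half
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  conv_axis <- function(arr, axis) {
    out <- array(0, dim(arr))
    n <- dim(arr)[axis]
    for (j in seq_along(offs)) {
      shift <- ((seq_len(n) - 1 + offs[j]) %% n) + 1
      idx <- switch(axis,
                    list(shift, TRUE, TRUE),
                    list(TRUE, shift, TRUE),
                    list(TRUE, TRUE, shift))
      out <- out + k[j] * do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    }
    out
  }
  conv_axis(conv_axis(conv_axis(a, 1), 2), 3)
}

grid_fwhm_along <- function(grid, axis, at) {
  prof <- switch(axis,
                 grid$data[, at[1], at[2]],
                 grid$data[at[1], , at[2]],
                 grid$data[at[1], at[2], ])
  x <- (seq_along(prof) - 1) * grid$voxel_size_nm
  trace_fwhm(x, prof)
}

test_that("zero-sigma blur and full tilt range are identities", {
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
  expect_identical(apply_psf(g, 0)$data, g$data)
  expect_equal(apply_missing_wedge(g, 90)$data, g$data, tolerance = 1e-12)
  expect_identical(add_noise(g, 0, 1)$data, g$data)
  expect_equal(apply_imaging(g, imaging_model())$data, g$data,
               tolerance = 1e-12)
})

test_that("blurring an impulse gives the Gaussian FWHM 2*sqrt(2 ln 2)*sigma", {
  a <- array(0, c(32, 32, 32)); a[17, 17, 17] <- 1
  g <- apply_psf(voxel_grid(a, 1), 2)
  fw <- grid_fwhm_along(g, 2, c(17, 17))
  expect_equal(fw, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.1 / 4.71)
})

test_that("blur conserves summed density and never shrinks a slab FWHM", {
  ph <- slab_fixture(thickness_nm = 8)
  total0 <- sum(ph$grid$data)
  fw <- vapply(c(0, 1, 2, 4), function(s) {
    blurred <- apply_psf(ph$grid, s)
    expect_lt(abs(sum(blurred$data) - total0) / total0, 1e-3)
    mid <- round(dim(blurred$data) / 2)
    grid_fwhm_along(blurred, 2, mid[c(1, 3)])
  }, numeric(1))
  expect_gte(fw[1], 8 - 0.7)            # rendered slab is ~its thickness
  # non-decreasing in sigma up to the sampling step (rounding of the
  # soft render edge can move the half-crossing by a fraction of a voxel)
  expect_true(all(diff(fw) > -0.35))
  expect_true(all(diff(fw[-1]) > 0))    # strictly wider once blur dominates
  expect_gt(fw[4], fw[1] + 1)
  expect_true(all(fw[-1] >= 8))         # blur never shrinks below truth
})

test_that("apply_psf equals the direct-space convolution oracle", {
  set.seed(42)
  a <- array(rnorm(12 * 10 * 8), c(12, 10, 8))
  g <- voxel_grid(a, 1)
  expect_equal(apply_psf(g, 1.5)$data, direct_gauss_blur(a, 1.5),
               tolerance = 1e-10)
})

test_that("the Fourier operators are linear", {
  set.seed(7)
  g1 <- array(rnorm(8^3), c(8, 8, 8))
  g2 <- array(rnorm(8^3), c(8, 8, 8))
  lin <- function(op) {
    lhs <- op(voxel_grid(3 * g1 + g2, 1))$data
    rhs <- 3 * op(voxel_grid(g1, 1))$data + op(voxel_grid(g2, 1))$data
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  lin(function(g) apply_psf(g, 1))
  lin(function(g) apply_missing_wedge(g, 60, "y"))
})

test_that("a +/-60 degree wedge elongates a point source along the beam", {
  # the analytic elongation factor sqrt((a + sin a cos a)/(a - sin a cos a))
  # at a = 60 degrees is the oracle for the measured FWHM ratio
  alpha <- 60 * pi / 180
  eyring <- sqrt((alpha + sin(alpha) * cos(alpha)) /
                   (alpha - sin(alpha) * cos(alpha)))
  a <- array(0, c(64, 32, 64)); a[33, 17, 33] <- 1
  blob <- apply_psf(voxel_grid(a, 1), 2)   # smooth so FWHM is well defined
  wedged <- apply_missing_wedge(blob, 60, "y")
  fw_beam <- grid_fwhm_along(wedged, 1, c(17, 33))
  fw_inplane <- grid_fwhm_along(wedged, 3, c(33, 17))
  ratio <- fw_beam / fw_inplane
  expect_gt(ratio, 1.4)
  expect_equal(ratio, eyring, tolerance = 0.12)
})

test_that("a beam-normal slab appears thicker than the same slab in-plane", {
  # finite (ribbon-like) slabs: an infinite beam-normal slab is pure
  # beam-axis frequency and is wiped out entirely by the wedge
  mk <- function(axis) {
    a <- array(0, c(64, 32, 64))
    if (axis == 1) a[29:36, , 17:48] <- 1 else a[17:48, , 29:36] <- 1
    apply_missing_wedge(apply_psf(voxel_grid(a, 1), 1), 60, "y")
  }
  fw_beam_normal <- grid_fwhm_along(mk(1), 1, c(17, 33))
  fw_inplane <- grid_fwhm_along(mk(3), 3, c(33, 17))
  expect_gt(fw_beam_normal, fw_inplane)
})

test_that("distances along the tilt axis are untouched by the wedge", {
  vox <- 0.7
  ph <- two_sheet_fixture(sep_nm = 16)        # sheets stacked along axis 2
  wedged <- apply_missing_wedge(ph$grid, 60, tilt_axis = "y")
  pr <- extract_profile(wedged, ph$line)
  pk <- detect_peaks(pr)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(peak_to_peak(pk, 1, 2) - 16), 0.5 * vox)
})

test_that("noise is seeded, reproducible, and has the stated SD", {
  g <- voxel_grid(array(0, c(256, 256, 256)), 1)
  n1 <- add_noise(g, 0.5, 11)
  n2 <- add_noise(g, 0.5, 11)
  expect_identical(n1$data, n2$data)
  s <- sd(n1$data)
  expect_gte(s, 0.497); expect_lte(s, 0.503)
  expect_lt(abs(mean(n1$data)), 3 * 0.5 / sqrt(length(g$data)))
  expect_false(identical(add_noise(g, 0.5, 12)$data, n1$data))
})

test_that("add_noise leaves the caller's RNG state alone", {
  set.seed(99)
  before <- .Random.seed
  invisible(add_noise(voxel_grid(array(0, c(4, 4, 4)), 1), 1, 5))
  expect_identical(.Random.seed, before)
})

test_that("apply_imaging matches the sequential operators", {
  set.seed(3)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
  im <- imaging_model(1.5, 60, "y", 0.3, seed = 21)
  combined <- apply_imaging(g, im)
  seq_path <- apply_missing_wedge(apply_psf(add_noise(g, 0.3, 21), 1.5), 60, "y")
  expect_equal(combined$data, seq_path$data, tolerance = 1e-10)
})

test_that("invalid imaging parameters are rejected", {
  g <- voxel_grid(array(0, c(4, 4, 4)), 1)
  expect_error(apply_psf(g, -1), ">= 0")
  expect_error(apply_missing_wedge(g, 0), "\\(0, 90]")
  expect_error(apply_missing_wedge(g, 95), "\\(0, 90]")
  expect_error(imaging_model(psf_sigma_nm = -2), ">= 0")
  expect_error(imaging_model(noise_sigma = -1), ">= 0")
})
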