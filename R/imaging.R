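#' Cryo-ET imaging model
#'
#' Bundles the three artifact operators applied to a rendered phantom:
#' an isotropic Gaussian point-spread blur standing in for defocus
#' (defocus is only used qualitatively here -- it inflates apparent
#' thicknesses, which Gaussian blur reproduces), a hard binary
#' missing-wedge mask in Fourier space for the limited tilt range, and
#' additive white Gaussian noise. The identity model is
#' `psf_sigma_nm = 0, tilt_range_deg = 90, noise_sigma = 0`.
#'
#' @param psf_sigma_nm Gaussian blur sigma (nm), >= 0.
#' @param tilt_range_deg half tilt range in degrees, in (0, 90]; 60 means
#'   a +/-60 degree tilt series.
#' @param tilt_axis `"x"` or `"y"`: the in-plane grid axis about which the
#'   stage tilts (frequencies along it stay fully sampled). The beam is
#'   always array axis 1.
#' @param noise_sigma SD of additive zero-mean Gaussian noise, >= 0.
#' @param seed integer seed controlling the noise realisation.
#' @return An `imaging_model` object (list).
#' @examples
#' imaging_model()                        # identity
#' imaging_model(2, 60, "y", 0.5, seed = 1)  # canonical conditions
#' @export
imaging_model <- function(psf_sigma_nm = 0, tilt_range_deg = 90,
                          tilt_axis = c("y", "x"), noise_sigma = 0,
                          seed = 1L) {
  tilt_axis <- match.arg(tilt_axis)
  if (!is.finite(psf_sigma_nm) || psf_sigma_nm < 0) {
    stop("psf_sigma_nm must be >= 0", call. = FALSE)
  }
  if (!is.finite(tilt_range_deg) || tilt_range_deg <= 0 || tilt_range_deg > 90) {
    stop("tilt_range_deg must be in (0, 90]", call. = FALSE)
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  structure(
    list(
      psf_sigma_nm = as.numeric(psf_sigma_nm),
      tilt_range_deg = as.numeric(tilt_range_deg),
      tilt_axis = tilt_axis,
      noise_sigma = as.numeric(noise_sigma),
      seed = as.integer(seed)
    ),
    class = "imaging_model"
  )
}

# DFT frequencies in cycles/voxel for an axis of length n.
fft_freq <- function(n) {
  f <- 0:(n - 1)
  f[f > n / 2] <- f[f > n / 2] - n
  f / n
}

# Wrapped, sum-normalised 1-D Gaussian kernel of length n (centre at [1]),
# returned as its DFT. Multiplying a volume's FFT by the outer product of
# these per-axis transforms is exactly circular separable convolution with
# the sampled kernel.
gauss_kernel_fft <- function(n, sigma_vox) {
  half <- ceiling(6 * sigma_vox)
  offs <- (-half):half
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  wrapped <- numeric(n)
  idx <- (offs %% n) + 1
  for (j in seq_along(k)) wrapped[idx[j]] <- wrapped[idx[j]] + k[j]
  stats::fft(wrapped)
}

# Fourier multiplier of the PSF (complex 3-D array), or NULL when sigma 0.
psf_multiplier <- function(d, sigma_vox) {
  if (sigma_vox <= 0) return(NULL)
  k1 <- gauss_kernel_fft(d[1], sigma_vox)
  k2 <- gauss_kernel_fft(d[2], sigma_vox)
  k3 <- gauss_kernel_fft(d[3], sigma_vox)
  array(outer(outer(k1, k2), k3), d)
}

# Binary keep-mask of the missing wedge (3-D 0/1 array), or NULL when the
# tilt range is the full 90 degrees. The wedge lives in the plane spanned
# by the beam axis and the in-plane axis perpendicular to the tilt axis:
# a coefficient is zeroed when its direction in that plane lies closer to
# the beam axis than (90 - tilt_range) degrees. The tilt-axis frequency
# line (both plane components zero) is always sampled and kept.
wedge_mask <- function(d, tilt_range_deg, tilt_axis) {
  if (tilt_range_deg >= 90) return(NULL)
  kz <- fft_freq(d[1])
  perp_axis <- if (tilt_axis == "y") 3L else 2L
  kp <- fft_freq(d[perp_axis])
  ang <- atan2(abs(rep(kp, each = d[1])), abs(rep(kz, times = length(kp))))
  keep2 <- matrix(ang >= (90 - tilt_range_deg) * pi / 180, nrow = d[1])
  keep2[1, 1] <- TRUE  # kz = kperp = 0 line along the tilt axis
  if (perp_axis == 3L) {
    # mask varies over (axis1, axis3); constant along axis 2
    aperm(array(rep(keep2, times = d[2]), c(d[1], d[3], d[2])), c(1, 3, 2))
  } else {
    array(rep(keep2, times = d[3]), d) * 1
  }
}

apply_fourier_multiplier <- function(grid, mult) {
  d <- dim(grid$data)
  out <- Re(stats::fft(stats::fft(grid$data) * mult, inverse = TRUE)) / prod(d)
  voxel_grid(out, grid$voxel_size_nm, grid$origin_nm)
}

#' Apply a Gaussian defocus-blur proxy
#'
#' Isotropic Gaussian smoothing with a physical sigma, implemented as
#' circular (periodic) convolution with a sampled, sum-normalised
#' separable kernel. The periodic boundary makes the total summed density
#' exactly conserved.
#'
#' @param grid a [voxel_grid()].
#' @param psf_sigma_nm blur sigma in nm, >= 0; 0 returns the input.
#' @return A blurred [voxel_grid()].
#' @export
apply_psf <- function(grid, psf_sigma_nm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.finite(psf_sigma_nm) || psf_sigma_nm < 0) {
    stop("psf_sigma_nm must be >= 0", call. = FALSE)
  }
  if (psf_sigma_nm == 0) return(grid)
  mult <- psf_multiplier(dim(grid$data), psf_sigma_nm / grid$voxel_size_nm)
  apply_fourier_multiplier(grid, mult)
}

#' Apply the missing-wedge Fourier mask
#'
#' Zeroes the Fourier coefficients a single-axis tilt series of the given
#' half-range never samples. The unsampled wedge straddles the beam axis
#' (array axis 1) in the plane perpendicular to the tilt axis; features
#' consequently appear elongated along the beam axis while distances along
#' the tilt axis are untouched. `tilt_range_deg = 90` is the identity.
#'
#' @inheritParams imaging_model
#' @param grid a [voxel_grid()].
#' @return A filtered [voxel_grid()] (real-valued).
#' @export
apply_missing_wedge <- function(grid, tilt_range_deg, tilt_axis = c("y", "x")) {
  stopifnot(inherits(grid, "voxel_grid"))
  tilt_axis <- match.arg(tilt_axis)
  if (!is.finite(tilt_range_deg) || tilt_range_deg <= 0 || tilt_range_deg > 90) {
    stop("tilt_range_deg must be in (0, 90]", call. = FALSE)
  }
  mask <- wedge_mask(dim(grid$data), tilt_range_deg, tilt_axis)
  if (is.null(mask)) return(grid)
  apply_fourier_multiplier(grid, mask)
}

#' Add white Gaussian noise
#'
#' Additive, zero-mean, seeded: the same seed always yields a bit-identical
#' volume, and the caller's RNG state is left untouched.
#'
#' @param grid a [voxel_grid()].
#' @param noise_sigma noise SD, >= 0; 0 returns the input.
#' @param seed integer seed.
#' @return A noisy [voxel_grid()].
#' @export
add_noise <- function(grid, noise_sigma, seed) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  if (noise_sigma == 0) return(grid)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  noisy <- grid$data + array(stats::rnorm(length(grid$data), 0, noise_sigma),
                             dim(grid$data))
  voxel_grid(noisy, grid$voxel_size_nm, grid$origin_nm)
}

#' Apply a full imaging model to a volume
#'
#' Composes the three artifact operators the way the real data chain
#' does: noise enters at acquisition, and the reconstruction filters act
#' on the noisy data. Concretely, [add_noise()] is applied first, then
#' the PSF blur and the missing-wedge mask (combined into a single
#' Fourier forward/inverse pair; identical to calling [apply_psf()] and
#' [apply_missing_wedge()] in sequence). The blur thus stands both for
#' defocus contrast loss and for the explicit low-pass/denoising filters
#' tomogram reconstruction applies to the noisy tilt series -- white
#' noise in the output volume would correspond to a reconstruction
#' without any such filtering.
#'
#' @param grid a [voxel_grid()].
#' @param imaging an [imaging_model()].
#' @return The imaged [voxel_grid()].
#' @export
apply_imaging <- function(grid, imaging) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(imaging, "imaging_model"))
  combined <- imaging_multiplier(dim(grid$data), grid$voxel_size_nm, imaging)
  out <- add_noise(grid, imaging$noise_sigma, imaging$seed)
  if (is.null(combined)) out else apply_fourier_multiplier(out, combined)
}

# Combined Fourier multiplier of the deterministic part of an imaging
# model (PSF times wedge mask), or NULL for the identity.
imaging_multiplier <- function(d, voxel_size_nm, imaging) {
  mult <- psf_multiplier(d, imaging$psf_sigma_nm / voxel_size_nm)
  mask <- wedge_mask(d, imaging$tilt_range_deg, imaging$tilt_axis)
  if (!is.null(mult) && !is.null(mask)) mult * mask else mult %||% mask
}
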