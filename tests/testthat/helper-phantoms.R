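# Small phantom fixtures built in code, shared across test files.

# Two full-width sheets `sep_nm` apart on a compact grid, with a line
# normal to them through the grid centre.
two_sheet_fixture <- function(sep_nm = 16, voxel = 0.7,
                              grid_shape = c(24, 128, 24)) {
  spec <- phantom_spec(
    grid_shape, voxel,
    layers = layer_spec("sheet", c(0, sep_nm), thickness_nm = 8,
                        amplitude = 0.8)
  )
  ph <- render_phantom(spec)
  ext <- (grid_shape - 1) * voxel
  ph$line <- line_annotation(
    "normal", c(ext[1] / 2, 2, ext[3] / 2), c(ext[1] / 2, ext[2] - 2, ext[3] / 2),
    averaging_width_nm = 6, averaging_depth_nm = 6
  )
  ph
}

# A single slab of given thickness on a compact grid, plus its normal line.
slab_fixture <- function(thickness_nm = 8, voxel = 0.7,
                         grid_shape = c(24, 128, 24), amplitude = 1) {
  spec <- phantom_spec(
    grid_shape, voxel,
    layers = layer_spec("sheet", 0, thickness_nm = thickness_nm,
                        amplitude = amplitude)
  )
  ph <- render_phantom(spec)
  ext <- (grid_shape - 1) * voxel
  ph$line <- line_annotation(
    "normal", c(ext[1] / 2, 2, ext[3] / 2), c(ext[1] / 2, ext[2] - 2, ext[3] / 2),
    averaging_width_nm = 6, averaging_depth_nm = 6
  )
  ph
}

# Numeric FWHM of a 1-D trace by linear interpolation at half maximum
# (independent of the package's profile_fwhm; used as an oracle).
trace_fwhm <- function(x, v) {
  level <- max(v) / 2
  i_max <- which.max(v)
  li <- max(which(v[seq_len(i_max)] < level))
  ri <- i_max - 1 + min(which(v[i_max:length(v)] < level))
  left <- x[li] + (level - v[li]) / (v[li + 1] - v[li]) * (x[li + 1] - x[li])
  right <- x[ri - 1] + (v[ri - 1] - level) / (v[ri - 1] - v[ri]) * (x[ri] - x[ri - 1])
  right - left
}

# Synthetic density-profile object for detector-level tests.
make_profile <- function(positions, values, step = positions[2] - positions[1]) {
  out <- tibble::tibble(position_nm = positions, density = values)
  class(out) <- c("density_profile", class(out))
  attr(out, "step_nm") <- step
  attr(out, "line_id") <- "synthetic"
  attr(out, "degenerate") <- FALSE
  out
}

# Independent brute-force oracle: iterate over all 2^N subsets of the
# pooled sample, keep those of size n1, and compute the deviation-based
# two-sided p for the rank-sum of the subset.
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n_tot <- length(pooled)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * (n_tot + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0; total <- 0
  for (code in 0:(2^n_tot - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n_tot) - 1)) > 0)
    if (length(members) != n1) next
    total <- total + 1
    if (abs(sum(r[members]) - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / total
}

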