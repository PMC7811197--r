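#' Extract an averaged, normalized density profile along a line
#'
#' This is the package's core measurement: the density is sampled by
#' trilinear interpolation at constant steps along the annotated line and
#' averaged over a rectangle of parallel lines centred on it
#' (`averaging_width_nm` by `averaging_depth_nm`, perpendicular to the
#' line), then min-max normalised to \[0, 1\]. It mirrors how distances
#' between subcellular features are read off tomographic slices from
#' averaged density-profile plots.
#'
#' The two averaging directions are chosen deterministically: the width
#' direction is the first of the transverse, profile and beam axes that is
#' not parallel to the line (orthogonalised against it), and the depth
#' direction completes the right-handed frame. For the common case of a
#' line along the profile axis this puts the averaging width in-plane and
#' the averaging depth along the beam -- the analogue of averaging over
#' the thickness of a displayed tomographic slice.
#'
#' @param grid a [voxel_grid()].
#' @param line a one-row line-annotation tibble from [line_annotation()].
#' @param step_nm sampling step along the line; defaults to half the voxel
#'   size and must not exceed it.
#' @return A `density_profile`: a tibble with columns `position_nm`
#'   (distance from the line start) and `density` (normalised), carrying
#'   attributes `step_nm`, `line_id`, `degenerate` and `raw_range` (the
#'   pre-normalisation density range). A constant raw profile is returned
#'   as all 0.5 with `degenerate = TRUE`.
#' @examples
#' ph <- render_phantom(phantom_spec(
#'   c(16, 96, 16), 0.7,
#'   layers = rbind(layer_spec("sheet", 0, 8, amplitude = 0.8),
#'                  layer_spec("sheet", 16, 8, amplitude = 0.8))
#' ))
#' ln <- line_annotation("l", c(5, 5, 5), c(5, 60, 5),
#'                       averaging_width_nm = 4, averaging_depth_nm = 4)
#' pr <- extract_profile(ph$grid, ln)
#' range(pr$density)
#' @export
extract_profile <- function(grid, line, step_nm = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.data.frame(line) || nrow(line) != 1L) {
    stop("`line` must be a one-row line annotation", call. = FALSE)
  }
  step_nm <- step_nm %||% (grid$voxel_size_nm / 2)
  if (step_nm <= 0 || step_nm > grid$voxel_size_nm + 1e-9) {
    stop("step_nm must be in (0, voxel_size_nm]", call. = FALSE)
  }
  p0 <- line$start_nm[[1]]
  p1 <- line$end_nm[[1]]
  len <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / len
  frame <- averaging_frame(u)
  t_pos <- seq(0, len, by = step_nm)
  spacing <- grid$voxel_size_nm
  offs_w <- centered_offsets(line$averaging_width_nm, spacing)
  offs_d <- centered_offsets(line$averaging_depth_nm, spacing)
  grid_off <- expand.grid(w = offs_w, dpt = offs_d)
  n_t <- length(t_pos)
  n_o <- nrow(grid_off)
  pts <- matrix(0, n_t * n_o, 3)
  base <- outer(t_pos, u)  # n_t x 3
  for (j in seq_len(3)) {
    pts[, j] <- rep(p0[j] + base[, j], times = n_o) +
      rep(grid_off$w * frame$v[j] + grid_off$dpt * frame$w[j], each = n_t)
  }
  vals <- tryCatch(
    interp_trilinear(grid, pts),
    error = function(e) {
      stop("line '", line$id, "' (with its averaging rectangle) exits the grid",
           call. = FALSE)
    }
  )
  raw <- rowMeans(matrix(vals, nrow = n_t))
  rng <- range(raw)
  degenerate <- (rng[2] - rng[1]) < 1e-12
  dens <- if (degenerate) rep(0.5, n_t) else (raw - rng[1]) / (rng[2] - rng[1])
  out <- tibble::tibble(position_nm = t_pos, density = dens)
  class(out) <- c("density_profile", class(out))
  attr(out, "step_nm") <- step_nm
  attr(out, "line_id") <- line$id
  attr(out, "degenerate") <- degenerate
  attr(out, "raw_range") <- rng   # pre-normalisation density range
  out
}

# Offsets spanning [-extent/2, extent/2] at roughly `spacing`, always
# including the centre line.
centered_offsets <- function(extent_nm, spacing) {
  n_side <- max(0, floor(extent_nm / 2 / spacing))
  s <- extent_nm / 2 / max(n_side, 1)
  if (n_side == 0) 0 else seq(-n_side, n_side) * s
}

# Orthonormal (width, depth) frame perpendicular to unit vector u.
# Width direction prefers transverse (axis 3), then profile, then beam.
averaging_frame <- function(u) {
  candidates <- list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  a <- NULL
  for (cand in candidates) {
    if (abs(sum(cand * u)) < 0.99) { a <- cand; break }
  }
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(v = v, w = w)
}

#' Detect density peaks with sub-sample refinement
#'
#' Finds local maxima of a [extract_profile()] trace with prominence at
#' least `min_prominence` and mutual separation at least
#' `min_separation_nm` (closer peaks are resolved in favour of the higher
#' one). Each retained peak position and height is refined to sub-sample
#' precision by a 3-point parabolic fit; ties between equal adjacent
#' samples break toward the lower index.
#'
#' @param profile a `density_profile`.
#' @param min_prominence minimum topographic prominence, in normalised
#'   density units.
#' @param min_separation_nm minimum distance between reported peaks (nm).
#' @return A tibble of peaks sorted by position: `position_nm`, `height`,
#'   `prominence`. May be empty.
#' @export
detect_peaks <- function(profile, min_prominence = 0.1, min_separation_nm = 5) {
  v <- profile$density
  x <- profile$position_nm
  n <- length(v)
  if (isTRUE(attr(profile, "degenerate")) || n < 3) {
    return(tibble::tibble(position_nm = numeric(0), height = numeric(0),
                          prominence = numeric(0)))
  }
  cand <- which(v[-c(1, n)] > v[seq_len(n - 2)] &
                  v[-c(1, n)] >= v[-(1:2)]) + 1L
  if (!length(cand)) {
    return(tibble::tibble(position_nm = numeric(0), height = numeric(0),
                          prominence = numeric(0)))
  }
  # plateau handling: flat-topped features (slabs sampled without noise)
  # produce runs of equal values; collapse each run to one candidate
  # located at the run centre, where the feature centre actually is
  eps <- 1e-9 * max(abs(v), 1)
  runs <- lapply(cand, function(i) {
    a <- i; while (a > 1 && abs(v[a - 1] - v[i]) <= eps) a <- a - 1
    b <- i; while (b < n && abs(v[b + 1] - v[i]) <= eps) b <- b + 1
    c(a, b)
  })
  first <- !duplicated(vapply(runs, `[`, numeric(1), 1))
  runs <- runs[first]
  # represent each run by its highest sample (ties toward the lower index)
  # so prominence is evaluated at the actual local maximum
  cand <- vapply(runs, function(r) {
    as.integer(r[1] + which.max(v[r[1]:r[2]]) - 1L)
  }, integer(1))
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  runs <- runs[keep]
  prom <- prom[keep]
  if (length(cand) > 1) {
    ord <- order(v[cand], decreasing = TRUE)
    kept <- integer(0)
    for (ii in ord) {
      if (!length(kept) ||
          all(abs(x[cand[ii]] - x[cand[kept]]) >= min_separation_nm)) {
        kept <- c(kept, ii)
      }
    }
    kept <- sort(kept)
    cand <- cand[kept]
    runs <- runs[kept]
    prom <- prom[kept]
  }
  refined <- vapply(seq_along(cand), function(k) {
    run <- runs[[k]]
    if (run[2] > run[1]) {
      c((x[run[1]] + x[run[2]]) / 2, v[cand[k]])
    } else {
      parabolic_refine(x, v, cand[k])
    }
  }, numeric(2))
  tibble::tibble(
    position_nm = refined[1, ],
    height = refined[2, ],
    prominence = prom
  ) |> dplyr::arrange(.data$position_nm)
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles, each taken as the minimum between the
# peak and the nearest higher sample (or the profile end).
peak_prominence <- function(v, i) {
  left_higher <- which(v[seq_len(i - 1)] > v[i])
  left_min <- if (length(left_higher)) {
    min(v[(max(left_higher)):(i - 1)])
  } else {
    min(v[seq_len(i)])
  }
  right <- v[(i + 1):length(v)]
  right_higher <- which(right > v[i])
  right_min <- if (length(right_higher)) {
    min(right[seq_len(min(right_higher))])
  } else {
    min(right)
  }
  v[i] - max(left_min, right_min)
}

# 3-point parabolic sub-sample refinement: returns c(position, height).
parabolic_refine <- function(x, v, i) {
  if (i <= 1 || i >= length(v)) return(c(x[i], v[i]))
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(c(x[i], v[i]))
  dx <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  dx <- max(min(dx, 0.5), -0.5)
  step <- x[i + 1] - x[i]
  c(x[i] + dx * step, v[i] - 0.25 * (v[i - 1] - v[i + 1]) * dx)
}

#' Peak-to-peak distance
#'
#' The spacing metric between two detected peaks: the absolute difference
#' of their (sub-sample refined) positions. Symmetric in `i`, `j`.
#'
#' @param peaks a peak tibble from [detect_peaks()].
#' @param i,j distinct row indices into `peaks`.
#' @return Distance in nm.
#' @examples
#' pk <- tibble::tibble(position_nm = c(10, 26), height = 1, prominence = 1)
#' peak_to_peak(pk, 1, 2)
#' @export
peak_to_peak <- function(peaks, i, j) {
  n <- nrow(peaks)
  if (!all(c(i, j) >= 1) || !all(c(i, j) <= n)) {
    stop("peak index out of range (", n, " peaks)", call. = FALSE)
  }
  if (i == j) stop("peak indices must differ", call. = FALSE)
  abs(peaks$position_nm[j] - peaks$position_nm[i])
}

#' Full width at half prominence-height of a peak
#'
#' The width estimator used for sheet widths and fibril diameters: the
#' profile is scanned outward from the peak for the two crossings of the
#' level `height - prominence / 2`, each located by linear interpolation
#' between the flanking samples. If a crossing is not found before the
#' profile ends, the measurement is rejected as truncated.
#'
#' @param profile a `density_profile`.
#' @param peak a one-row tibble (one row of [detect_peaks()] output).
#' @return Width in nm.
#' @export
profile_fwhm <- function(profile, peak) {
  if (!is.data.frame(peak) || nrow(peak) != 1L) {
    stop("`peak` must be a single peak row", call. = FALSE)
  }
  x <- profile$position_nm
  v <- profile$density
  pos <- peak$position_nm
  if (pos < x[1] || pos > x[length(x)]) {
    stop("peak position lies outside the profile", call. = FALSE)
  }
  level <- peak$height - peak$prominence / 2
  i0 <- which.min(abs(x - pos))
  left <- NA_real_
  if (i0 >= 2) {
    for (k in i0:2) {
      if (v[k - 1] < level && v[k] >= level) {
        left <- x[k - 1] + (level - v[k - 1]) / (v[k] - v[k - 1]) * (x[k] - x[k - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (i0 <= length(v) - 1) {
    for (k in i0:(length(v) - 1)) {
      if (v[k + 1] < level && v[k] >= level) {
        right <- x[k] + (v[k] - level) / (v[k] - v[k + 1]) * (x[k + 1] - x[k])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    stop("half-height crossing not found inside the profile (truncated peak)",
         call. = FALSE)
  }
  right - left
}
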