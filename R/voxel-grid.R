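#' 3-D density volume with physical voxel size
#'
#' A `voxel_grid` carries a 3-D scalar density array together with its
#' isotropic voxel size in nanometres. The array axis order is fixed:
#' axis 1 is the electron-beam axis (the poorly sampled direction of a
#' tomogram), axis 2 is the profile axis along which layered features of
#' the cell envelope are stacked, and axis 3 is the in-plane transverse
#' axis. All physical coordinates in the package are 3-vectors in this
#' same (beam, profile, transverse) order, in nanometres.
#'
#' A voxel's physical position is its centre:
#' `pos_nm = origin_nm + (index - 1) * voxel_size_nm` (R's 1-based index).
#'
#' @param data numeric 3-D array of densities.
#' @param voxel_size_nm positive scalar, isotropic voxel edge in nm.
#' @param origin_nm numeric 3-vector, physical position of voxel (1,1,1).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), voxel_size_nm = 0.7)
#' dim(g$data)
#' @export
voxel_grid <- function(data, voxel_size_nm, origin_nm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (beam, profile, transverse)", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("`data` contains non-finite values", call. = FALSE)
  }
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0) {
    stop("`voxel_size_nm` must be a single positive number", call. = FALSE)
  }
  if (length(origin_nm) != 3L || !all(is.finite(origin_nm))) {
    stop("`origin_nm` must be a finite 3-vector", call. = FALSE)
  }
  structure(
    list(
      data = data,
      voxel_size_nm = as.numeric(voxel_size_nm),
      origin_nm = as.numeric(origin_nm)
    ),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels (beam, profile, transverse), %.4g nm/voxel\n",
    d[1], d[2], d[3], x$voxel_size_nm
  ))
  cat(sprintf(
    "  extent: %.1f x %.1f x %.1f nm; density range [%.4g, %.4g]\n",
    (d[1] - 1) * x$voxel_size_nm, (d[2] - 1) * x$voxel_size_nm,
    (d[3] - 1) * x$voxel_size_nm, min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Convert between voxel indices and physical coordinates
#'
#' Centralised index/coordinate conversion for a [voxel_grid()]. Indices are
#' R's 1-based array indices; positions are nm at the voxel centre.
#'
#' @param grid a [voxel_grid()].
#' @param index numeric vector or n-by-3 matrix of (possibly fractional)
#'   voxel indices.
#' @param pos_nm numeric vector or n-by-3 matrix of physical positions (nm).
#' @return The converted vector or matrix.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), voxel_size_nm = 2)
#' index_to_nm(g, c(1, 1, 1))  # origin voxel centre
#' nm_to_index(g, c(2, 4, 6))
#' @export
index_to_nm <- function(grid, index) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.matrix(index)) {
    sweep((index - 1) * grid$voxel_size_nm, 2, grid$origin_nm, "+")
  } else {
    grid$origin_nm + (index - 1) * grid$voxel_size_nm
  }
}

#' @rdname index_to_nm
#' @export
nm_to_index <- function(grid, pos_nm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.matrix(pos_nm)) {
    sweep(pos_nm, 2, grid$origin_nm, "-") / grid$voxel_size_nm + 1
  } else {
    (pos_nm - grid$origin_nm) / grid$voxel_size_nm + 1
  }
}

# Trilinear interpolation of grid density at an n-by-3 matrix of physical
# positions (nm). Positions outside the voxel-centre bounding box are an
# error: callers are expected to validate line placement.
interp_trilinear <- function(grid, pos_nm) {
  d <- dim(grid$data)
  idx <- nm_to_index(grid, pos_nm)
  eps <- 1e-9
  if (any(idx < 1 - eps) || any(sweep(idx, 2, d + eps, ">"))) {
    stop("sample positions fall outside the volume", call. = FALSE)
  }
  i0 <- pmin(pmax(floor(idx[, 1]), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(idx[, 2]), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(idx[, 3]), 1), d[3] - 1)
  fz <- idx[, 1] - i0
  fy <- idx[, 2] - j0
  fx <- idx[, 3] - k0
  a <- grid$data
  v000 <- a[cbind(i0, j0, k0)]
  v100 <- a[cbind(i0 + 1, j0, k0)]
  v010 <- a[cbind(i0, j0 + 1, k0)]
  v110 <- a[cbind(i0 + 1, j0 + 1, k0)]
  v001 <- a[cbind(i0, j0, k0 + 1)]
  v101 <- a[cbind(i0 + 1, j0, k0 + 1)]
  v011 <- a[cbind(i0, j0 + 1, k0 + 1)]
  v111 <- a[cbind(i0 + 1, j0 + 1, k0 + 1)]
  (1 - fx) * ((1 - fy) * ((1 - fz) * v000 + fz * v100) +
                fy * ((1 - fz) * v010 + fz * v110)) +
    fx * ((1 - fy) * ((1 - fz) * v001 + fz * v101) +
            fy * ((1 - fz) * v011 + fz * v111))
}
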