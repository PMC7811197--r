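#' Specify layered/cylindrical phantom geometry
#'
#' A phantom emulates the measured geometry of a cellulose-producing
#' Gram-negative cell seen side-on in a tomogram: planar layers stacked
#' along the profile axis (outer membrane `OM`, inner membrane `IM`,
#' extracellular cellulose `sheet`s, cytoplasmic cortical `belt_layer`s)
#' plus optional cylindrical microfibrils. Layer positions are given as
#' signed offsets (nm) along the profile axis relative to a common
#' reference; by default the rendered structure is centred in the grid and
#' the absolute reference position is reported back.
#'
#' @param grid_shape integer 3-vector (beam, profile, transverse) voxels.
#' @param voxel_size_nm positive isotropic voxel size (nm).
#' @param layers tibble from [layer_spec()] rows (may be empty).
#' @param cylinders tibble from [cylinder_spec()] rows (may be empty).
#' @param background constant background density.
#' @param reference_nm absolute profile-axis position (nm) that offset 0
#'   maps to, or `NULL` to centre the layer stack automatically.
#' @return A `phantom_spec` object (list).
#' @examples
#' ps <- phantom_spec(
#'   grid_shape = c(32, 128, 32), voxel_size_nm = 0.7,
#'   layers = rbind(layer_spec("OM", 0), layer_spec("sheet", 16))
#' )
#' @export
phantom_spec <- function(grid_shape, voxel_size_nm,
                         layers = NULL, cylinders = NULL,
                         background = 0, reference_nm = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L))
  if (!is.finite(voxel_size_nm) || voxel_size_nm <= 0) {
    stop("voxel_size_nm must be > 0", call. = FALSE)
  }
  layers <- layers %||% layer_spec(character(0), numeric(0))
  cylinders <- cylinders %||% cylinder_spec(numeric(0))
  structure(
    list(
      grid_shape = grid_shape,
      voxel_size_nm = as.numeric(voxel_size_nm),
      layers = layers,
      cylinders = cylinders,
      background = as.numeric(background),
      reference_nm = reference_nm
    ),
    class = "phantom_spec"
  )
}

#' @param label layer kind: one of `"OM"`, `"IM"`, `"sheet"`, `"belt_layer"`.
#' @param center_offset_nm signed offset of the layer centre along the
#'   profile axis (nm).
#' @param thickness_nm layer thickness along the profile axis (nm), > 0.
#' @param width_nm extent along the transverse axis (nm); `Inf` for a
#'   layer spanning the whole grid.
#' @param amplitude density amplitude of the layer, > 0. Features are
#'   rendered as positive peaks (bright = dense), matching profile plots
#'   where subcellular features appear as peaks; inverting real cryo-ET
#'   contrast is the caller's responsibility at import.
#' @rdname phantom_spec
#' @export
layer_spec <- function(label, center_offset_nm, thickness_nm = 6,
                       width_nm = Inf, amplitude = 1) {
  n <- length(label)
  if (n > 0) {
    if (!all(label %in% c("OM", "IM", "sheet", "belt_layer"))) {
      stop("layer label must be OM, IM, sheet or belt_layer", call. = FALSE)
    }
    if (any(!is.finite(thickness_nm) | thickness_nm <= 0)) {
      stop("layer thickness_nm must be > 0", call. = FALSE)
    }
    if (any(!is.finite(amplitude) | amplitude <= 0)) {
      stop("layer amplitude must be > 0", call. = FALSE)
    }
    if (any(width_nm <= 0)) stop("layer width_nm must be > 0", call. = FALSE)
  }
  tibble::tibble(
    label = as.character(label),
    center_offset_nm = as.numeric(center_offset_nm),
    thickness_nm = rep_len(as.numeric(thickness_nm), n),
    width_nm = rep_len(as.numeric(width_nm), n),
    amplitude = rep_len(as.numeric(amplitude), n)
  )
}

#' @param diameter_nm cylinder diameter (nm), > 0.
#' @param axis_direction unit 3-vector of the cylinder axis
#'   (beam, profile, transverse).
#' @param center_nm 3-vector centre; the profile component is an offset in
#'   the same frame as `center_offset_nm`, the beam/transverse components
#'   are offsets from the grid centre.
#' @param length_nm cylinder length (nm).
#' @rdname phantom_spec
#' @export
cylinder_spec <- function(diameter_nm, axis_direction = c(0, 1, 0),
                          center_nm = c(0, 0, 0), length_nm = 30,
                          amplitude = 0.8) {
  n <- length(diameter_nm)
  if (n > 0) {
    if (any(!is.finite(diameter_nm) | diameter_nm <= 0)) {
      stop("cylinder diameter_nm must be > 0", call. = FALSE)
    }
    if (any(amplitude <= 0)) stop("cylinder amplitude must be > 0", call. = FALSE)
  }
  tibble::tibble(
    diameter_nm = as.numeric(diameter_nm),
    axis_direction = if (n) list(as.numeric(axis_direction)) else list(),
    center_nm = if (n) list(as.numeric(center_nm)) else list(),
    length_nm = rep_len(as.numeric(length_nm), n),
    amplitude = rep_len(as.numeric(amplitude), n)
  )
}

# Absolute profile-axis position (nm) of offset 0 for a spec on its grid.
phantom_reference_nm <- function(spec) {
  if (!is.null(spec$reference_nm)) return(spec$reference_nm)
  center <- (spec$grid_shape[2] - 1) * spec$voxel_size_nm / 2
  offs <- spec$layers$center_offset_nm
  if (nrow(spec$cylinders)) {
    offs <- c(offs, vapply(spec$cylinders$center_nm, `[`, numeric(1), 2))
  }
  if (!length(offs)) return(center)
  center - mean(range(offs))
}

#' Render a phantom into a density volume with ground truth
#'
#' Renders every layer and cylinder of a [phantom_spec()] as a soft-edged
#' (edge width one voxel) positive density feature added to the constant
#' background, and derives the ground-truth morphometric quantities
#' implied by the geometry: every peak-to-peak distance between layer
#' centres, finite feature widths, fibril diameters and the sheet count.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `grid` (a [voxel_grid()]), `truth` (named
#'   list of true quantities, nm) and `reference_nm` (absolute position of
#'   offset 0 on the profile axis).
#' @examples
#' ph <- render_phantom(phantom_spec(
#'   c(16, 96, 16), 0.7,
#'   layers = rbind(layer_spec("sheet", 0, 8, amplitude = 0.8),
#'                  layer_spec("sheet", 16, 8, amplitude = 0.8))
#' ))
#' ph$truth$intersheet
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vx <- spec$voxel_size_nm
  ref <- phantom_reference_nm(spec)
  extent <- (d - 1) * vx
  y_nm <- (seq_len(d[2]) - 1) * vx
  x_nm <- (seq_len(d[3]) - 1) * vx
  x_center <- extent[3] / 2
  z_center <- extent[1] / 2
  edge <- vx

  # layers are separable f(y) * g(x) fields constant along the beam:
  # accumulate one profile-by-transverse plane and expand to 3-D once
  plane_yx <- matrix(0, d[2], d[3])
  ly <- spec$layers
  for (i in seq_len(nrow(ly))) {
    yc <- ref + ly$center_offset_nm[i]
    half <- ly$thickness_nm[i] / 2
    if (yc - half < 0 || yc + half > extent[2]) {
      stop("layer '", ly$label[i], "' at offset ", ly$center_offset_nm[i],
           " nm lies outside the grid (absolute centre ", round(yc, 2),
           " nm, profile extent ", round(extent[2], 2), " nm)", call. = FALSE)
    }
    fy <- pmin(pmax((half - abs(y_nm - yc)) / edge + 0.5, 0), 1)
    if (is.finite(ly$width_nm[i])) {
      wh <- ly$width_nm[i] / 2
      if (x_center - wh < 0 || x_center + wh > extent[3]) {
        stop("layer '", ly$label[i], "' width ", ly$width_nm[i],
             " nm exceeds the transverse extent", call. = FALSE)
      }
      gx <- pmin(pmax((wh - abs(x_nm - x_center)) / edge + 0.5, 0), 1)
    } else {
      gx <- rep(1, d[3])
    }
    plane_yx <- plane_yx + ly$amplitude[i] * outer(fy, gx)
  }
  vol <- spec$background + array(rep(plane_yx, each = d[1]), d)

  cy <- spec$cylinders
  for (i in seq_len(nrow(cy))) {
    a <- cy$axis_direction[[i]]
    a <- a / sqrt(sum(a^2))
    cen <- cy$center_nm[[i]] + c(z_center, ref, x_center)
    rad <- cy$diameter_nm[i] / 2
    halflen <- cy$length_nm[i] / 2
    # per-axis extent of the capsule: axial plus radial contribution
    reach <- halflen * abs(a) + rad * sqrt(pmax(1 - a^2, 0)) + 2 * vx
    if (any(cen - reach < -vx) || any(cen + reach > extent + vx)) {
      stop("cylinder ", i, " does not fit inside the grid", call. = FALSE)
    }
    lo <- pmax(floor((cen - reach) / vx) + 1, 1)
    hi <- pmin(ceiling((cen + reach) / vx) + 1, d)
    box <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
    p <- cbind((box$z - 1) * vx - cen[1],
               (box$y - 1) * vx - cen[2],
               (box$x - 1) * vx - cen[3])
    t_ax <- p %*% a
    radial <- sqrt(pmax(rowSums(p^2) - t_ax^2, 0))
    f_r <- pmin(pmax((rad - radial) / edge + 0.5, 0), 1)
    f_t <- pmin(pmax((halflen - abs(t_ax)) / edge + 0.5, 0), 1)
    val <- cy$amplitude[i] * f_r * f_t
    keep <- val > 0
    if (any(keep)) {
      idx <- cbind(box$z[keep], box$y[keep], box$x[keep])
      vol[idx] <- vol[idx] + val[keep]
    }
  }

  list(
    grid = voxel_grid(vol, voxel_size_nm = vx),
    truth = phantom_ground_truth(spec),
    reference_nm = ref
  )
}

# Ground-truth quantities implied by a phantom_spec's geometry.
phantom_ground_truth <- function(spec) {
  ly <- spec$layers
  off <- function(lbl) sort(ly$center_offset_nm[ly$label == lbl])
  om <- off("OM"); im <- off("IM")
  sheets <- off("sheet"); belts <- off("belt_layer")
  truth <- list()
  if (length(om) && length(sheets)) {
    truth$om_to_sheet <- min(sheets - om[1])
  }
  if (length(sheets) > 1) truth$intersheet <- mean(diff(sheets))
  if (length(im) && length(belts)) truth$im_to_belt <- im[1] - max(belts)
  if (length(belts) > 1) truth$belt_interlayer <- mean(diff(belts))
  if (length(om) && length(im)) truth$im_om_separation <- om[1] - im[1]
  sw <- ly$width_nm[ly$label == "sheet" & is.finite(ly$width_nm)]
  if (length(sw)) truth$sheet_width <- sw[1]
  bw <- ly$width_nm[ly$label == "belt_layer" & is.finite(ly$width_nm)]
  if (length(bw)) truth$belt_width <- bw[1]
  if (nrow(spec$cylinders)) truth$fibril_diameter <- spec$cylinders$diameter_nm[1]
  truth$n_sheets <- length(sheets)
  bad <- names(truth)[vapply(truth, function(v) !is.finite(v) || v < 0, TRUE)]
  if (length(bad)) {
    stop("non-positive ground-truth quantity: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  truth
}

#' Write a ground-truth JSON sidecar for a rendered phantom
#'
#' @param phantom result of [render_phantom()] or [canonical_ribbon_phantom()].
#' @param imaging the [imaging_model()] applied (echoed into the sidecar).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(phantom, imaging, path) {
  jsonlite::write_json(
    list(
      quantities = phantom$truth,
      reference_nm = phantom$reference_nm,
      imaging = unclass(imaging),
      seed = imaging$seed
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
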