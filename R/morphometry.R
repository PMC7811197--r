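#' Measure the cellulose ribbon on a tomogram
#'
#' Runs the profile pipeline on every `ribbon_normal` line (drawn from the
#' cytoplasm toward the exterior, so the first detected peak is the outer
#' membrane and subsequent peaks are cellulose sheets), assembles the
#' named quantities, and classifies the tight/loose configuration of the
#' OM-ribbon interface. When a `sheet_width`/`ribbon_width` transverse
#' line is present, sheet width is estimated by FWHM of its single peak.
#' Per-quantity values are averaged over lines; the sheet count is the
#' modal peak count, and intersheet spacings are averaged over the lines
#' showing that count.
#'
#' @param grid a [voxel_grid()].
#' @param lines a line-annotation tibble ([line_annotation()] rows). Lines
#'   with role `NA` are treated as `ribbon_normal`.
#' @param min_prominence,min_separation_nm peak-detection settings, see
#'   [detect_peaks()].
#' @param step_nm profile sampling step, see [extract_profile()].
#' @param threshold_nm tight/loose boundary, see [classify_configuration()].
#' @return A `ribbon_measurement` list: `om_to_closest_sheet_nm`,
#'   `intersheet_nm` (vector of consecutive spacings), `n_sheets`,
#'   `sheet_width_nm` (or `NA`), `configuration` (`"tight"`, `"loose"`, or
#'   `NA` with `configuration_undefined = TRUE` when no sheet is found),
#'   and `per_line` (tibble of per-line peak counts).
#' @export
measure_ribbon <- function(grid, lines, min_prominence = 0.1,
                           min_separation_nm = 5, step_nm = NULL,
                           threshold_nm = 40) {
  normals <- lines[is.na(lines$role) | lines$role == "ribbon_normal", ]
  if (!nrow(normals)) stop("no ribbon_normal lines supplied", call. = FALSE)
  per <- purrr::map(seq_len(nrow(normals)), function(k) {
    ln <- normals[k, ]
    pk <- detect_peaks(extract_profile(grid, ln, step_nm),
                       min_prominence, min_separation_nm)
    if (nrow(pk) == 0) {
      stop("no OM peak found on line '", ln$id, "'", call. = FALSE)
    }
    list(
      id = ln$id,
      om_pos = pk$position_nm[1],
      sheet_pos = pk$position_nm[-1],
      n_sheets = nrow(pk) - 1L
    )
  })
  counts <- vapply(per, `[[`, integer(1), "n_sheets")
  n_sheets <- as.integer(stats::median(counts))
  consistent <- per[counts == n_sheets]
  om_to_sheet <- if (n_sheets >= 1) {
    mean(vapply(consistent, function(p) p$sheet_pos[1] - p$om_pos, numeric(1)))
  } else {
    NA_real_
  }
  intersheet <- if (n_sheets >= 2) {
    gaps <- vapply(consistent, function(p) diff(p$sheet_pos),
                   numeric(n_sheets - 1))
    rowMeans(matrix(gaps, nrow = n_sheets - 1))
  } else {
    numeric(0)
  }
  width <- measure_width(grid, lines, c("sheet_width", "ribbon_width"),
                         min_prominence, min_separation_nm, step_nm)
  undefined <- n_sheets == 0
  structure(
    list(
      om_to_closest_sheet_nm = om_to_sheet,
      intersheet_nm = as.numeric(intersheet),
      n_sheets = n_sheets,
      sheet_width_nm = width,
      configuration = if (undefined) NA_character_ else
        classify_configuration(om_to_sheet, threshold_nm),
      configuration_undefined = undefined,
      per_line = tibble::tibble(
        id = vapply(per, `[[`, character(1), "id"),
        n_peaks = counts + 1L
      )
    ),
    class = "ribbon_measurement"
  )
}

#' Measure the cortical belt on a tomogram
#'
#' As [measure_ribbon()], for `belt_normal` lines: drawn cytoplasm ->
#' exterior and truncated between the membranes, so the last detected peak
#' is the inner membrane and the preceding peaks are cortical-belt layers.
#' Belt width uses a `belt_width` transverse line when present.
#'
#' @inheritParams measure_ribbon
#' @return A `belt_measurement` list: `im_to_belt_nm`,
#'   `belt_interlayer_nm` (vector), `n_layers`, `belt_width_nm` (or `NA`),
#'   `per_line`.
#' @export
measure_belt <- function(grid, lines, min_prominence = 0.1,
                         min_separation_nm = 5, step_nm = NULL) {
  normals <- lines[!is.na(lines$role) & lines$role == "belt_normal", ]
  if (!nrow(normals)) stop("no belt_normal lines supplied", call. = FALSE)
  per <- purrr::map(seq_len(nrow(normals)), function(k) {
    ln <- normals[k, ]
    pk <- detect_peaks(extract_profile(grid, ln, step_nm),
                       min_prominence, min_separation_nm)
    if (nrow(pk) < 2) {
      stop("no belt_layer peak found on line '", ln$id,
           "' (need IM plus at least one belt layer)", call. = FALSE)
    }
    n <- nrow(pk)
    list(
      id = ln$id,
      im_to_belt = pk$position_nm[n] - pk$position_nm[n - 1],
      interlayer = diff(pk$position_nm[seq_len(n - 1)]),
      n_layers = n - 1L
    )
  })
  counts <- vapply(per, `[[`, integer(1), "n_layers")
  n_layers <- as.integer(stats::median(counts))
  consistent <- per[counts == n_layers]
  interlayer <- if (n_layers >= 2) {
    gaps <- vapply(consistent, `[[`, numeric(n_layers - 1), "interlayer")
    rowMeans(matrix(gaps, nrow = n_layers - 1))
  } else {
    numeric(0)
  }
  structure(
    list(
      im_to_belt_nm = mean(vapply(consistent, `[[`, numeric(1), "im_to_belt")),
      belt_interlayer_nm = as.numeric(interlayer),
      n_layers = n_layers,
      belt_width_nm = measure_width(grid, lines, "belt_width",
                                    min_prominence, min_separation_nm, step_nm),
      per_line = tibble::tibble(
        id = vapply(per, `[[`, character(1), "id"),
        n_peaks = counts + 1L
      )
    ),
    class = "belt_measurement"
  )
}

# FWHM of the single (highest) peak on each matching width line, averaged.
measure_width <- function(grid, lines, roles, min_prominence,
                          min_separation_nm, step_nm) {
  wl <- lines[!is.na(lines$role) & lines$role %in% roles, ]
  if (!nrow(wl)) return(NA_real_)
  mean(vapply(seq_len(nrow(wl)), function(k) {
    pr <- extract_profile(grid, wl[k, ], step_nm)
    pk <- detect_peaks(pr, min_prominence, min_separation_nm)
    if (!nrow(pk)) {
      stop("no peak found on width line '", wl$id[k], "'", call. = FALSE)
    }
    profile_fwhm(pr, pk[which.max(pk$height), ])
  }, numeric(1)))
}

#' Classify the OM-ribbon interface as tight or loose
#'
#' The interface is loose when the OM-to-closest-sheet distance strictly
#' exceeds the threshold (default 40 nm, where disorganised aggregates
#' appear between the detached ribbon and the cell), tight otherwise; a
#' distance of exactly 40 nm is tight.
#'
#' @param om_to_closest_sheet_nm positive distance(s), nm.
#' @param threshold_nm classification boundary (nm).
#' @return Character vector of `"tight"` / `"loose"`.
#' @examples
#' classify_configuration(c(16, 99, 40))
#' @export
classify_configuration <- function(om_to_closest_sheet_nm, threshold_nm = 40) {
  if (any(!is.finite(om_to_closest_sheet_nm) | om_to_closest_sheet_nm <= 0)) {
    stop("om_to_closest_sheet_nm must be > 0", call. = FALSE)
  }
  ifelse(om_to_closest_sheet_nm > threshold_nm, "loose", "tight")
}

#' Estimate a microfibril diameter from a transverse profile
#'
#' FWHM of the single fibril peak on a line crossing the cylinder
#' perpendicular to its axis. Under defocus blur this is an upper-bound
#' estimator: blur inflates apparent thickness, so the value can only
#' overestimate the true diameter.
#'
#' @param grid a [voxel_grid()].
#' @param line a one-row line annotation crossing the fibril.
#' @param axis_direction unit 3-vector of the fibril axis; the line must
#'   be perpendicular to it (within ~6 degrees).
#' @inheritParams measure_ribbon
#' @return Diameter estimate (nm).
#' @export
estimate_fibril_diameter <- function(grid, line, axis_direction = c(0, 1, 0),
                                     min_prominence = 0.1,
                                     min_separation_nm = 5, step_nm = NULL) {
  u <- line$end_nm[[1]] - line$start_nm[[1]]
  u <- u / sqrt(sum(u^2))
  a <- axis_direction / sqrt(sum(axis_direction^2))
  if (abs(sum(u * a)) > 0.1) {
    stop("line '", line$id, "' is not perpendicular to the fibril axis",
         call. = FALSE)
  }
  pr <- extract_profile(grid, line, step_nm)
  pk <- detect_peaks(pr, min_prominence, min_separation_nm)
  if (!nrow(pk)) stop("no fibril peak found on line '", line$id, "'",
                      call. = FALSE)
  profile_fwhm(pr, pk[which.max(pk$height), ])
}

#' Masked threshold segmentation
#'
#' Mirrors masked isosurface thresholding on a tomogram: a voxel is
#' selected iff it lies inside the previously drawn mask and its density
#' is at or above the threshold. The mask restricts segmentation to the
#' annotated structure so the threshold can be raised without picking up
#' background.
#'
#' @param grid a [voxel_grid()].
#' @param mask logical (or 0/1) array of the same shape as the volume.
#' @param threshold density threshold.
#' @return A list: `selection` (logical array) and `volume_fraction`
#'   (selected voxels / mask voxels).
#' @export
masked_threshold_segment <- function(grid, mask, threshold) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(mask), dim(grid$data))) {
    stop("mask shape does not match the volume", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim(mask))
  n_mask <- sum(mask)
  if (n_mask == 0) stop("empty mask", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  sel <- mask & (grid$data >= threshold)
  list(selection = sel, volume_fraction = sum(sel) / n_mask)
}

#' @export
print.ribbon_measurement <- function(x, ...) {
  cat("<ribbon_measurement>\n")
  cat(sprintf("  OM-to-closest-sheet: %.2f nm (%s)\n",
              x$om_to_closest_sheet_nm,
              if (isTRUE(x$configuration_undefined)) "undefined"
              else x$configuration))
  cat(sprintf("  sheets: %d; intersheet: %s nm; width: %s nm\n",
              x$n_sheets,
              paste(sprintf("%.2f", x$intersheet_nm), collapse = ", "),
              ifelse(is.na(x$sheet_width_nm), "-",
                     sprintf("%.2f", x$sheet_width_nm))))
  invisible(x)
}

#' @export
print.belt_measurement <- function(x, ...) {
  cat("<belt_measurement>\n")
  cat(sprintf("  IM-to-belt: %.2f nm; layers: %d; interlayer: %s nm\n",
              x$im_to_belt_nm, x$n_layers,
              paste(sprintf("%.2f", x$belt_interlayer_nm), collapse = ", ")))
  invisible(x)
}

#' Tidy a ribbon or belt measurement into measurement records
#'
#' @param x a `ribbon_measurement` or `belt_measurement`.
#' @param tomogram_id identifier recorded in the output.
#' @param ... unused.
#' @return A tibble in the measurement-record layout (`tomogram_id`,
#'   `line_id`, `quantity`, `value_nm`, `method`, `n_peaks_used`).
#' @method tidy ribbon_measurement
#' @export
tidy.ribbon_measurement <- function(x, tomogram_id = "tomogram", ...) {
  rec <- tibble::tibble(
    quantity = c("om_to_sheet",
                 if (length(x$intersheet_nm))
                   paste0("intersheet_", seq_along(x$intersheet_nm)),
                 if (!is.na(x$sheet_width_nm)) "sheet_width"),
    value_nm = c(x$om_to_closest_sheet_nm, x$intersheet_nm,
                 if (!is.na(x$sheet_width_nm)) x$sheet_width_nm),
    method = c("peak_to_peak",
               rep("peak_to_peak", length(x$intersheet_nm)),
               if (!is.na(x$sheet_width_nm)) "fwhm"),
    n_peaks_used = c(2L, rep(2L, length(x$intersheet_nm)),
                     if (!is.na(x$sheet_width_nm)) 1L)
  )
  tibble::tibble(tomogram_id = tomogram_id, line_id = "aggregate", rec)
}

#' @rdname tidy.ribbon_measurement
#' @method tidy belt_measurement
#' @export
tidy.belt_measurement <- function(x, tomogram_id = "tomogram", ...) {
  rec <- tibble::tibble(
    quantity = c("im_to_belt",
                 if (length(x$belt_interlayer_nm))
                   paste0("belt_interlayer_", seq_along(x$belt_interlayer_nm)),
                 if (!is.na(x$belt_width_nm)) "belt_width"),
    value_nm = c(x$im_to_belt_nm, x$belt_interlayer_nm,
                 if (!is.na(x$belt_width_nm)) x$belt_width_nm),
    method = c("peak_to_peak",
               rep("peak_to_peak", length(x$belt_interlayer_nm)),
               if (!is.na(x$belt_width_nm)) "fwhm"),
    n_peaks_used = c(2L, rep(2L, length(x$belt_interlayer_nm)),
                     if (!is.na(x$belt_width_nm)) 1L)
  )
  tibble::tibble(tomogram_id = tomogram_id, line_id = "aggregate", rec)
}
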