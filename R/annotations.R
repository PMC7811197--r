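#' Construct a line annotation
#'
#' A line annotation is the package's equivalent of the "red line" drawn on
#' a tomographic slice: a segment in physical coordinates along which an
#' averaged density profile is extracted. Coordinates are nm 3-vectors in
#' (beam, profile, transverse) order, matching [voxel_grid()].
#'
#' @param id character identifier.
#' @param start_nm,end_nm numeric 3-vectors (nm); must differ.
#' @param averaging_width_nm,averaging_depth_nm positive extents (nm) of
#'   the rectangle of parallel lines averaged perpendicular to the line.
#' @param role optional label used by the morphometry layer to route lines
#'   (e.g. `"ribbon_normal"`, `"belt_normal"`, `"ribbon_width"`).
#' @return A one-row tibble with list-columns `start_nm`, `end_nm`.
#' @examples
#' line_annotation("l1", c(10, 0, 10), c(10, 50, 10))
#' @export
line_annotation <- function(id, start_nm, end_nm,
                            averaging_width_nm = 20,
                            averaging_depth_nm = 10,
                            role = NA_character_) {
  start_nm <- as.numeric(start_nm)
  end_nm <- as.numeric(end_nm)
  if (length(start_nm) != 3L || length(end_nm) != 3L ||
      !all(is.finite(c(start_nm, end_nm)))) {
    stop("line '", id, "': start_nm and end_nm must be finite 3-vectors",
         call. = FALSE)
  }
  if (sqrt(sum((end_nm - start_nm)^2)) <= 0) {
    stop("line '", id, "': degenerate line (start equals end)", call. = FALSE)
  }
  if (!is.finite(averaging_width_nm) || averaging_width_nm <= 0 ||
      !is.finite(averaging_depth_nm) || averaging_depth_nm <= 0) {
    stop("line '", id, "': averaging extents must be > 0", call. = FALSE)
  }
  tibble::tibble(
    id = as.character(id),
    start_nm = list(start_nm),
    end_nm = list(end_nm),
    averaging_width_nm = averaging_width_nm,
    averaging_depth_nm = averaging_depth_nm,
    role = role
  )
}

#' Read line/cell/lamella annotations from JSON
#'
#' The annotation file is a single UTF-8 JSON document with any of the
#' keys `lines`, `cells` and `geometry`. Lines carry nm coordinates
#' (never voxel indices). Unknown keys are ignored. Every record is
#' validated against its type invariants; a degenerate line or a
#' non-positive averaging extent is rejected naming the offending id.
#'
#' @param path path to a JSON annotation file.
#' @return A list with elements `lines` (tibble, possibly empty),
#'   `cells` (tibble or `NULL`) and `geometry` (list or `NULL`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lines <- purrr::map_dfr(doc$lines %||% list(), function(l) {
    line_annotation(
      id = l$id %||% stop("line annotation without id", call. = FALSE),
      start_nm = unlist(l$start_nm),
      end_nm = unlist(l$end_nm),
      averaging_width_nm = l$averaging_width_nm %||% 20,
      averaging_depth_nm = l$averaging_depth_nm %||% 10,
      role = l$role %||% NA_character_
    )
  })
  cells <- NULL
  if (!is.null(doc$cells)) {
    cells <- purrr::map_dfr(doc$cells, function(cl) {
      st <- cl$state %||% NA_character_
      if (!st %in% c("live", "dead")) {
        stop("cell '", cl$id, "': state must be 'live' or 'dead'", call. = FALSE)
      }
      area <- cl$area_um2 %||% NA_real_
      if (is.finite(area) && area < 0) {
        stop("cell '", cl$id, "': area_um2 must be >= 0", call. = FALSE)
      }
      tibble::tibble(
        id = as.character(cl$id),
        x_nm = as.numeric(cl$centroid_nm[[1]]),
        y_nm = as.numeric(cl$centroid_nm[[2]]),
        state = st,
        area_um2 = as.numeric(area)
      )
    })
  }
  geometry <- NULL
  if (!is.null(doc$geometry)) {
    g <- doc$geometry
    geometry <- lamella_geometry(
      milling_angle_deg = g$milling_angle_deg,
      leading_edge = matrix(unlist(g$leading_edge), ncol = 2, byrow = TRUE),
      lamella_area_um2 = g$lamella_area_um2 %||% NA_real_
    )
  }
  list(lines = lines, cells = cells, geometry = geometry)
}

#' Read and write morphometric measurement tables
#'
#' Measurement tables are plain CSV (comma-separated, header row, `.`
#' decimal) with one row per named morphometric quantity and columns
#' `tomogram_id`, `line_id`, `quantity`, `value_nm`, `method`,
#' `n_peaks_used`. The write/read round trip is lossless.
#'
#' @param measurements a tibble with the columns above.
#' @param path CSV file path.
#' @return `read_measurements()` returns a tibble; `write_measurements()`
#'   returns `path` invisibly.
#' @export
write_measurements <- function(measurements, path) {
  need <- c("tomogram_id", "line_id", "quantity", "value_nm", "method",
            "n_peaks_used")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurement table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(measurements[need], path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      tomogram_id = readr::col_character(),
      line_id = readr::col_character(),
      quantity = readr::col_character(),
      value_nm = readr::col_double(),
      method = readr::col_character(),
      n_peaks_used = readr::col_integer()
    )
  )
}
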