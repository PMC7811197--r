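#' FIB-lamella geometry
#'
#' Describes a focused-ion-beam-milled lamella for the biofilm census: the
#' milling angle between the grid surface and the ion gun, the leading
#' edge (a 2-D line perpendicular to the trench walls, where the platinum
#' coat meets the frozen material), and the lamella area.
#'
#' @param milling_angle_deg angle in degrees, strictly between 0 and 90.
#' @param leading_edge 2 x 2 numeric matrix; rows are two distinct points
#'   (x, y) in nm on the leading-edge line.
#' @param lamella_area_um2 lamella area in square micrometres.
#' @return A `lamella_geometry` list.
#' @export
lamella_geometry <- function(milling_angle_deg, leading_edge,
                             lamella_area_um2 = NA_real_) {
  if (!is.finite(milling_angle_deg) || milling_angle_deg <= 0 ||
      milling_angle_deg >= 90) {
    stop("milling_angle_deg must be strictly between 0 and 90", call. = FALSE)
  }
  leading_edge <- matrix(as.numeric(leading_edge), ncol = 2)
  if (nrow(leading_edge) != 2L || !all(is.finite(leading_edge))) {
    stop("leading_edge must be two finite (x, y) points", call. = FALSE)
  }
  if (sqrt(sum((leading_edge[2, ] - leading_edge[1, ])^2)) <= 0) {
    stop("degenerate leading edge: the two points coincide", call. = FALSE)
  }
  if (is.finite(lamella_area_um2) && lamella_area_um2 <= 0) {
    stop("lamella_area_um2 must be > 0", call. = FALSE)
  }
  structure(
    list(
      milling_angle_deg = as.numeric(milling_angle_deg),
      leading_edge = leading_edge,
      lamella_area_um2 = as.numeric(lamella_area_um2)
    ),
    class = "lamella_geometry"
  )
}

#' Perpendicular distance from a cell centroid to the leading edge
#'
#' @param centroid_nm numeric (x, y) point in the lamella plane (nm), in
#'   the same coordinate frame as the geometry's leading edge.
#' @param geom a [lamella_geometry()].
#' @return Non-negative distance in nm.
#' @examples
#' g <- lamella_geometry(15, rbind(c(0, 0), c(0, 1)), 100)
#' leading_edge_distance(c(500, 20), g)
#' @export
leading_edge_distance <- function(centroid_nm, geom) {
  stopifnot(inherits(geom, "lamella_geometry"))
  p1 <- geom$leading_edge[1, ]
  p2 <- geom$leading_edge[2, ]
  e <- p2 - p1
  r <- as.numeric(centroid_nm) - p1
  abs(e[1] * r[2] - e[2] * r[1]) / sqrt(sum(e^2))
}

#' Real depth of a cell below the sample surface
#'
#' Converts the in-lamella-plane distance from the leading edge into the
#' true depth below the original sample surface using the milling
#' geometry: `depth = tan(a) * d`, where `a` is the milling angle. Linear
#' in `d` and strictly increasing in `a` on (0, 90).
#'
#' @param d_nm distance from the leading-edge line (nm), >= 0.
#' @param milling_angle_deg milling angle in degrees, in (0, 90).
#' @return Depth in nm.
#' @examples
#' cell_depth(100, 45)  # 100
#' cell_depth(500, 15)  # tan(15 deg) * 500
#' @export
cell_depth <- function(d_nm, milling_angle_deg) {
  if (any(!is.finite(d_nm) | d_nm < 0)) {
    stop("d_nm must be >= 0", call. = FALSE)
  }
  if (!is.finite(milling_angle_deg) || milling_angle_deg <= 0 ||
      milling_angle_deg >= 90) {
    stop("milling_angle_deg must be strictly between 0 and 90", call. = FALSE)
  }
  tan(milling_angle_deg * pi / 180) * d_nm
}

#' Biofilm lamella census
#'
#' Summarises annotated cells on a lamella: cell density (cells per square
#' micrometre of lamella), occupancy (summed annotated cell area over
#' lamella area -- an area fraction, which is what a single lamella
#' section supports), the live fraction live/(live+dead), the live-to-dead
#' count ratio, and the per-cell depth distribution via [cell_depth()].
#' Both live-cell summaries are emitted because the two conventions
#' disagree whenever dead cells are present; neither is privileged.
#'
#' @param cells tibble with columns `id`, `x_nm`, `y_nm`, `state`
#'   (`"live"`/`"dead"`) and `area_um2` (may have zero rows).
#' @param geom a [lamella_geometry()].
#' @return A `lamella_census` list with `cells` (input augmented with
#'   `edge_distance_nm` and `depth_nm`) and `summary` (one-row tibble:
#'   `n_cells`, `n_live`, `n_dead`, `density_per_um2`, `occupancy`,
#'   `live_fraction`, `live_dead_ratio`, `fractions_undefined`). Fractions
#'   are `NA` with `fractions_undefined = TRUE` for an empty census.
#' @examples
#' g <- lamella_geometry(15, rbind(c(0, 0), c(0, 1)), 100)
#' cells <- tibble::tibble(
#'   id = as.character(1:27), x_nm = 100 * (1:27), y_nm = 0,
#'   state = rep(c("live", "dead"), c(24, 3)), area_um2 = 0.5
#' )
#' glance(census(cells, g))
#' @export
census <- function(cells, geom) {
  stopifnot(inherits(geom, "lamella_geometry"))
  if (!is.finite(geom$lamella_area_um2) || geom$lamella_area_um2 <= 0) {
    stop("census requires a positive lamella_area_um2", call. = FALSE)
  }
  n <- nrow(cells)
  if (n) {
    if (!all(cells$state %in% c("live", "dead"))) {
      stop("cell state must be 'live' or 'dead'", call. = FALSE)
    }
    d <- vapply(seq_len(n), function(k) {
      leading_edge_distance(c(cells$x_nm[k], cells$y_nm[k]), geom)
    }, numeric(1))
    cells <- dplyr::mutate(
      cells,
      edge_distance_nm = d,
      depth_nm = cell_depth(d, geom$milling_angle_deg)
    )
  } else {
    cells <- dplyr::mutate(cells, edge_distance_nm = numeric(0),
                           depth_nm = numeric(0))
  }
  n_live <- sum(cells$state == "live")
  n_dead <- sum(cells$state == "dead")
  undefined <- n == 0
  structure(
    list(
      cells = cells,
      geometry = geom,
      summary = tibble::tibble(
        n_cells = n,
        n_live = n_live,
        n_dead = n_dead,
        density_per_um2 = n / geom$lamella_area_um2,
        occupancy = sum(cells$area_um2, na.rm = TRUE) / geom$lamella_area_um2,
        live_fraction = if (undefined) NA_real_ else n_live / n,
        live_dead_ratio = if (undefined || n_dead == 0) NA_real_ else
          n_live / n_dead,
        fractions_undefined = undefined
      )
    ),
    class = "lamella_census"
  )
}

#' @export
print.lamella_census <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<lamella_census> %d cells (%d live, %d dead); %.3g cells/um^2; occupancy %.3g\n",
    s$n_cells, s$n_live, s$n_dead, s$density_per_um2, s$occupancy
  ))
  invisible(x)
}

#' Glance at a lamella census
#'
#' @param x a `lamella_census`.
#' @param ... unused.
#' @return The one-row summary tibble.
#' @method glance lamella_census
#' @export
glance.lamella_census <- function(x, ...) x$summary

#' @rdname tidy.ribbon_measurement
#' @method tidy lamella_census
#' @export
tidy.lamella_census <- function(x, ...) x$cells
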