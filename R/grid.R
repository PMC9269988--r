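## 1-D finite-volume grids (Cartesian slab or spherically symmetric).

#' 1-D finite-volume grid
#'
#' Cell-centered grid with half-open cells `[r_k, r_{k+1})`.  Spherical
#' grids carry exact shell volumes `4/3 pi (r_{k+1}^3 - r_k^3)` and face
#' areas `4 pi r^2`; Cartesian grids use unit cross-section.
#'
#' @param edges strictly increasing cell-edge coordinates (m), length
#'   `n_cells + 1`.
#' @param geometry `"cartesian"` or `"spherical"`.
#' @return object of class `grid_1d` with `edges`, `centers`, `volumes`,
#'   `face_areas`, `n`, `geometry`.
#' @export
grid_1d <- function(edges, geometry = c("cartesian", "spherical")) {
  geometry <- match.arg(geometry)
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least two entries")
  if (geometry == "spherical" && edges[1] < 0)
    stop("spherical grids require nonnegative radii")
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  if (geometry == "cartesian") {
    volumes <- diff(edges)
    face_areas <- rep(1, length(edges))
  } else {
    volumes <- 4 / 3 * pi * diff(edges^3)
    face_areas <- 4 * pi * edges^2
  }
  if (any(volumes <= 0)) stop("non-positive cell volume")
  structure(list(edges = edges, centers = centers, volumes = volumes,
                 face_areas = face_areas, n = length(centers),
                 geometry = geometry),
            class = "grid_1d")
}

#' Uniform grid helper
#'
#' @param n_cells number of cells (>= 1).
#' @param length domain extent (outer radius for spherical grids), m.
#' @param geometry `"cartesian"` or `"spherical"`.
#' @return a [grid_1d()].
#' @export
uniform_grid <- function(n_cells, length, geometry = "cartesian") {
  grid_1d(seq(0, length, length.out = n_cells + 1), geometry)
}

#' @export
print.grid_1d <- function(x, ...) {
  cat(sprintf("<grid_1d> %s, %d cells, extent [%g, %g] m\n",
              x$geometry, x$n, x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}
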