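# Crypt geometry: fixed basal membrane (hemispherical cap + cylinder) and
# the axial position metric P (geodesic meridian arc from the bottom pole,
# in cell radii).

#' Crypt basal-membrane surface
#'
#' The basal membrane is the union of a hemispherical cap (the crypt
#' bottom, radius `cap_radius`, bottom pole at the origin) and a cylinder of
#' the same radius extending upward (+z, toward the villus). The two pieces
#' join smoothly at the cap equator. Position along the crypt-villus axis is
#' measured by `P`, the geodesic arc distance from the bottom pole along a
#' meridian, in cell radii (1 cell radius = 5 um). Cells with `P >
#' exit_position` have left the crypt.
#'
#' @param cap_radius Radius of the hemispherical cap (and the cylinder), in
#'   cell radii.
#' @param exit_position Axial position `P` beyond which cells are removed
#'   (strict inequality).
#' @return A `crypt_surface` object.
#' @examples
#' surf <- crypt_surface()
#' axial_position(c(0, 0, 0), surf)        # bottom pole: P = 0
#' axial_position(c(4, 0, 4), surf)        # cap equator: P = 4 * pi / 2
#' @export
crypt_surface <- function(cap_radius = 4, exit_position = 30) {
  stopifnot(cap_radius > 0, exit_position > cap_radius * pi / 2)
  crypt_length <- cap_radius + (exit_position - cap_radius * pi / 2)
  structure(
    list(cap_radius = cap_radius,
         cylinder_radius = cap_radius,
         crypt_length = crypt_length,
         exit_position = exit_position,
         orientation = c(0, 0, 1)),
    class = "crypt_surface")
}

#' @export
print.crypt_surface <- function(x, ...) {
  cat("<crypt_surface>  cap radius", x$cap_radius,
      "cell radii; exit at P >", x$exit_position, "\n")
  invisible(x)
}

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3)
  points
}

#' Axial position P of points on (or near) the crypt surface
#'
#' `P` is the geodesic meridian arc distance from the bottom pole: on the
#' cap, `P = cap_radius * theta` with `theta` the polar angle from the pole;
#' on the cylinder, `P = cap_radius * pi/2 + height above the equator`.
#' Off-surface points are first projected.
#'
#' @param points Numeric vector of length 3, or an n x 3 matrix.
#' @param surface A [crypt_surface()].
#' @return Numeric vector of nonnegative positions, in cell radii.
#' @export
axial_position <- function(points, surface = crypt_surface()) {
  .cpp_axial_position(.as_points(points), surface$cap_radius)
}

#' Project points onto the crypt surface
#'
#' Returns the nearest point on the basal membrane: radial projection onto
#' the cylinder above the cap equator, central projection onto the
#' hemisphere below it. Idempotent for points already on the surface.
#' Degenerate on-axis inputs resolve to a fixed fallback direction (+x on
#' the cylinder axis, the bottom pole for the cap centre), so the map is
#' deterministic everywhere.
#'
#' @inheritParams axial_position
#' @return An n x 3 matrix of surface points.
#' @export
project_to_surface <- function(points, surface = crypt_surface()) {
  .cpp_project(.as_points(points), surface$cap_radius)
}

#' Substrate (basal membrane) contact test
#'
#' A cell keeps substrate contact while its centre lies within
#' `radius + tolerance` of the membrane (boundary inclusive). Cells that
#' lose substrate contact undergo anoikis.
#'
#' @param cells A [cell_population()] data frame.
#' @param surface A [crypt_surface()].
#' @param tolerance Extra allowance beyond the cell radius, in cell radii.
#' @return Logical vector, one entry per cell.
#' @export
has_substrate_contact <- function(cells, surface = crypt_surface(),
                                  tolerance = 0.1) {
  pts <- as.matrix(cells[, c("x", "y", "z")])
  proj <- .cpp_project(pts, surface$cap_radius)
  d <- sqrt(rowSums((pts - proj)^2))
  d <= cell_radius(cells$volume) + tolerance
}

#' Sphere-equivalent cell radius from volume
#'
#' @param volume Cell volume(s) in cubic cell radii.
#' @return Radii in cell radii: `(3 V / 4 pi)^(1/3)`.
#' @export
cell_radius <- function(volume) (3 * volume / (4 * pi))^(1 / 3)
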