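# Root-aligned oriented-bounding-box morphometry.
#
# The measurement frame is anatomically constrained: the z-axis is the
# canonical superior direction of the mesh frame, and the box is rotated about
# z so that its x-axis is parallel to the projection of the anterior-posterior
# root line onto the x-y plane. Extents are then tightened to the min/max
# vertex projections, which leaves no residual freedom.

#' Meniscus width/length/height triple
#'
#' @param width medio-lateral extent (mm, y-axis of the oriented box).
#' @param length anterior-posterior extent (mm, x-axis).
#' @param height inferior-superior extent (mm, z-axis); `NA` for 2D
#'   measurements.
#' @return An object of class `meniscus_dimensions`.
#' @export
meniscus_dimensions <- function(width, length, height = NA_real_) {
  if (width <= 0 || length <= 0 || (!is.na(height) && height <= 0))
    stopf("all present dimensions must be positive")
  structure(list(width = width, length = length, height = height),
            class = "meniscus_dimensions")
}

#' @export
print.meniscus_dimensions <- function(x, ...) {
  cat(sprintf("<meniscus_dimensions> width %.2f mm, length %.2f mm, height %s\n",
              x$width, x$length,
              if (is.na(x$height)) "-" else sprintf("%.2f mm", x$height)))
  invisible(x)
}

#' Root-aligned oriented bounding box of a meniscus
#'
#' Builds the measurement box: z-axis fixed to the canonical superior
#' direction, x-axis parallel to the x-y projection of the anterior-to-
#' posterior root line, y-axis completing the right-handed frame; extents are
#' the min/max vertex projections on the three axes so the box exactly
#' encloses the mesh and every box face touches the surface.
#'
#' @param mesh a [meniscus_mesh()] with valid root landmarks.
#' @return An object of class `oriented_box` with fields `center` (3-vector),
#'   `axes` (3 x 3 matrix, columns = x/y/z box axes) and `extents`
#'   (named lengths in mm: `length`, `width`, `height`).
#' @export
compute_obb <- function(mesh) {
  r <- mesh$root_anterior - mesh$root_posterior
  rxy <- c(r[1], r[2])
  if (sqrt(sum((mesh$root_anterior - mesh$root_posterior)^2)) < 1) {
    stopf("root landmarks are coincident (< 1 mm apart); cannot align box")
  }
  if (sqrt(sum(rxy^2)) < 1e-9)
    stopf("root line is vertical; no x-y projection to align to")
  ex <- c(rxy / sqrt(sum(rxy^2)), 0)
  ez <- c(0, 0, 1)
  ey <- c(-ex[2], ex[1], 0)   # ez x ex, right-handed
  axes <- cbind(ex, ey, ez, deparse.level = 0)
  proj <- mesh$vertices %*% axes
  lo <- apply(proj, 2L, min)
  hi <- apply(proj, 2L, max)
  center <- as.numeric(axes %*% ((lo + hi) / 2))
  ext <- hi - lo
  structure(list(center = center, axes = axes,
                 extents = c(length = ext[1], width = ext[2], height = ext[3])),
            class = "oriented_box")
}

#' @export
print.oriented_box <- function(x, ...) {
  cat(sprintf("<oriented_box> length %.2f x width %.2f x height %.2f mm\n",
              x$extents["length"], x$extents["width"], x$extents["height"]))
  invisible(x)
}

#' Measure meniscal width, length and height
#'
#' The three extents of the root-aligned oriented bounding box, mapped to
#' anatomical roles: width = y extent, length = x extent, height = z extent.
#'
#' @param mesh a [meniscus_mesh()].
#' @return A [meniscus_dimensions()].
#' @export
measure_dimensions <- function(mesh) {
  box <- compute_obb(mesh)
  meniscus_dimensions(width = unname(box$extents["width"]),
                      length = unname(box$extents["length"]),
                      height = unname(box$extents["height"]))
}

#' Measure 2D (axial) meniscal width and length
#'
#' The in-silico equivalent of the axial-slice MRI measurement: the mesh
#' footprint is projected onto the x-y plane and enclosed in a 2D box aligned
#' to the root line. Optional Gaussian noise emulates manual reading error.
#'
#' @param mesh a [meniscus_mesh()].
#' @param noise_sd standard deviation of additive measurement noise (mm);
#'   0 (default) gives a deterministic measurement.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A [meniscus_dimensions()] with `height = NA`.
#' @export
measure_dimensions_2d <- function(mesh, noise_sd = 0, seed = 1L) {
  box <- compute_obb(mesh)
  w <- unname(box$extents["width"])
  l <- unname(box$extents["length"])
  if (noise_sd > 0) {
    e <- with_seed(seed, rnorm(2L, 0, noise_sd))
    w <- w + e[1]
    l <- l + e[2]
  }
  meniscus_dimensions(width = w, length = l)
}
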