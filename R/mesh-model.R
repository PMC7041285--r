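#' Construct a meniscus surface mesh
#'
#' The atomic object of the sizing pipeline: a triangulated surface of one
#' meniscus in millimetres, together with its anatomical metadata and the
#' anterior/posterior root landmarks used to orient the measurement frame.
#' Coordinates live in the canonical right-handed anatomical frame:
#' x = anterior-posterior (length), y = medio-lateral (width),
#' z = inferior-superior (height).
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based triangle indices.
#' @param patient_id opaque patient identifier.
#' @param side `"medial"` or `"lateral"`.
#' @param laterality `"left"` or `"right"`.
#' @param root_anterior,root_posterior length-3 numeric; root landmark
#'   coordinates (mm), each within 2 mm of the mesh surface.
#' @param validate check mesh invariants (connectivity, non-degenerate
#'   triangles, landmark proximity). Disable only for meshes known valid.
#' @return An object of class `meniscus_mesh`.
#' @export
meniscus_mesh <- function(vertices, faces, patient_id = "unknown",
                          side = c("medial", "lateral"),
                          laterality = c("right", "left"),
                          root_anterior, root_posterior, validate = TRUE) {
  side <- match.arg(side)
  laterality <- match.arg(laterality)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stopf("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stopf("faces must be an m x 3 matrix")
  root_anterior <- as.numeric(root_anterior)
  root_posterior <- as.numeric(root_posterior)
  if (length(root_anterior) != 3L || length(root_posterior) != 3L)
    stopf("root landmarks must be 3D points")
  mesh <- structure(
    list(vertices = vertices, faces = faces, patient_id = as.character(patient_id),
         side = side, laterality = laterality,
         root_anterior = root_anterior, root_posterior = root_posterior),
    class = "meniscus_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate meniscus mesh invariants
#'
#' Checks face indexing, triangle non-degeneracy, single connectivity and that
#' both root landmarks lie within `landmark_tol` of the surface. Each failure
#' raises a distinct error.
#'
#' @param mesh a [meniscus_mesh()].
#' @param landmark_tol maximal allowed landmark-to-surface distance (mm).
#' @return The mesh, invisibly.
#' @export
validate_mesh <- function(mesh, landmark_tol = 2) {
  nv <- nrow(mesh$vertices)
  if (nv < 3L || nrow(mesh$faces) < 1L)
    stopf("mesh must have at least 3 vertices and 1 face")
  if (any(mesh$faces < 1L) || any(mesh$faces > nv))
    stopf("face index out of range: faces must reference existing vertices")
  areas <- cpp_tri_areas(mesh$vertices, mesh$faces - 1L)
  if (any(areas <= 1e-12))
    stopf("mesh contains %d degenerate (zero-area) triangle(s)",
          sum(areas <= 1e-12))
  if (cpp_n_components(mesh$faces - 1L, nv) != 1L)
    stopf("mesh is not a single connected component")
  d <- cpp_point_surface_distance(
    rbind(mesh$root_anterior, mesh$root_posterior),
    mesh$vertices, mesh$faces - 1L)
  if (any(d > landmark_tol))
    stopf("root landmark lies %.2f mm from the mesh surface (limit %g mm)",
          max(d), landmark_tol)
  invisible(mesh)
}

#' @export
print.meniscus_mesh <- function(x, ...) {
  cat(sprintf("<meniscus_mesh> %s %s %s: %d vertices, %d faces\n",
              x$patient_id, x$side, x$laterality,
              nrow(x$vertices), nrow(x$faces)))
  av <- cpp_area_volume(x$vertices, x$faces - 1L)
  cat(sprintf("  surface area %.1f mm^2, enclosed volume %.1f mm^3\n",
              av[1], abs(av[2])))
  invisible(x)
}

#' Surface area and enclosed volume of a mesh
#'
#' @param mesh a [meniscus_mesh()].
#' @return Named numeric vector with `area` (mm^2) and `volume` (mm^3, by the
#'   divergence theorem; meaningful for closed, consistently oriented meshes).
#' @export
mesh_area_volume <- function(mesh) {
  av <- cpp_area_volume(mesh$vertices, mesh$faces - 1L)
  c(area = av[1], volume = av[2])
}

#' Mirror a left meniscus to a right-sided model
#'
#' Left menisci are reflected across the sagittal (x-z) plane so that all bank
#' entries share one laterality: the y coordinate changes sign, triangle
#' winding is flipped to preserve outward normals, the root landmarks are
#' reflected and the laterality flag is set to `"right"`. Right meshes pass
#' through unchanged.
#'
#' @param mesh a [meniscus_mesh()].
#' @return A right-sided `meniscus_mesh`.
#' @export
mirror_to_right <- function(mesh) {
  if (mesh$laterality == "right") return(mesh)
  reflect_mesh(mesh, laterality = "right")
}

# reflection across the x-z plane with winding flip; used both for
# left-to-right mirroring and for synthesising left sides
reflect_mesh <- function(mesh, laterality) {
  v <- mesh$vertices
  v[, 2] <- -v[, 2]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  ra <- mesh$root_anterior * c(1, -1, 1)
  rp <- mesh$root_posterior * c(1, -1, 1)
  meniscus_mesh(v, f, mesh$patient_id, mesh$side, laterality,
                ra, rp, validate = FALSE)
}

# rigidly transform mesh and landmarks (rotation 3x3, translation length 3)
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  meniscus_mesh(v, mesh$faces, mesh$patient_id, mesh$side, mesh$laterality,
                as.numeric(rotation %*% mesh$root_anterior + translation),
                as.numeric(rotation %*% mesh$root_posterior + translation),
                validate = FALSE)
}
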