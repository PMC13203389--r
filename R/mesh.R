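#' Triangular surface mesh
#'
#' Container for a single organ (or machine part) surface: vertices in
#' patient coordinates (mm) and triangular faces indexing them. Degenerate
#' (zero-area) faces are dropped at construction.
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates in mm.
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (nrow(faces)) {
    a <- face_areas(vertices, faces)
    faces <- faces[a > 1e-12, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, volume %.1f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

face_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Outward unit face normals
#'
#' @param mesh a [surface_mesh()].
#' @return F x 3 matrix of unit normals (right-hand rule over vertex order).
#' @export
face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' Enclosed mesh volume
#'
#' Signed-tetrahedron (divergence theorem) volume; the absolute value is
#' returned so vertex winding does not change the magnitude.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (!nrow(F)) return(0)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(a * cr)) / 6
}

#' Total surface area
#' @param mesh a [surface_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Euler characteristic V - E + F
#'
#' Counts unique undirected edges; 2 for a closed genus-0 surface.
#'
#' @param mesh a [surface_mesh()].
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nrow(mesh$vertices) - ne + nrow(F)
}

#' Point-in-mesh test by ray-crossing parity
#'
#' Casts a ray from each query point in a fixed generic direction and counts
#' surface crossings; odd parity means inside. Requires a closed mesh.
#'
#' @param points N x 3 matrix of query points (mm).
#' @param mesh a closed [surface_mesh()].
#' @return logical vector of length N.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  dir <- c(0.5812381937, 0.6589669726, 0.4779795443)  # generic direction
  dir <- dir / sqrt(sum(dir^2))
  apply(points, 1, function(p) {
    h <- .cpp_ray_mesh(p, dir, mesh$vertices, mesh$faces, 1e-9, 1e-6)
    (nrow(h) %% 2L) == 1L
  })
}

#' Rigid transform of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @return transformed [surface_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  V <- mesh$vertices %*% t(rotation)
  V <- sweep(V, 2, translation, `+`)
  surface_mesh(V, mesh$faces)
}
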