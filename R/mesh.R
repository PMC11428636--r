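#' Triangulated surface mesh
#'
#' Container for a triangulated vessel-wall surface. Cell areas and unit
#' normals are computed from the cross-product formula at construction (or
#' validated against it when supplied). Vertex indices are 1-based, the R
#' convention; file writers convert to the 0-based convention of VTK.
#'
#' @param vertices Numeric matrix, `V x 3`, coordinates in m.
#' @param triangles Integer matrix, `F x 3`, 1-based vertex indices.
#' @param nominal_element_size Optional metadata: nominal edge length, mm.
#' @return Object of class `"surface_mesh"` with `vertices`, `triangles`,
#'   `cell_areas` (m2), `cell_normals` (unit vectors, `F x 3`),
#'   `nominal_element_size`.
#' @export
surface_mesh <- function(vertices, triangles, nominal_element_size = NA_real_) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  if (ncol(vertices) != 3L) stop("'vertices' must be V x 3", call. = FALSE)
  if (ncol(triangles) != 3L) stop("'triangles' must be F x 3", call. = FALSE)
  if (!is.numeric(vertices) || anyNA(vertices))
    stop("invalid vertex coordinates", call. = FALSE)
  storage.mode(triangles) <- "integer"
  V <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > V))
    stop("triangle indices out of range (1-based expected)", call. = FALSE)
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm2 <- sqrt(rowSums(cr^2))
  if (any(nrm2 <= 0)) stop("mesh contains zero-area cells", call. = FALSE)
  structure(list(vertices = vertices, triangles = triangles,
                 cell_areas = nrm2 / 2, cell_normals = cr / nrm2,
                 nominal_element_size = nominal_element_size),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d triangles, area %.6g m^2",
              nrow(x$vertices), nrow(x$triangles), sum(x$cell_areas)))
  if (!is.na(x$nominal_element_size))
    cat(sprintf(" (nominal element size %g mm)", x$nominal_element_size))
  cat("\n")
  invisible(x)
}

#' Cell centroids of a surface mesh
#' @param mesh A [surface_mesh()].
#' @return `F x 3` matrix of triangle centroids, m.
#' @export
cell_centroids <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  (mesh$vertices[mesh$triangles[, 1], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 2], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 3], , drop = FALSE]) / 3
}
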