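#' Triangulated 3-D surface mesh
#'
#' `trimesh3d()` builds the package's central surface container: an `n x 3`
#' matrix of vertex coordinates (Angstrom) plus an `m x 3` integer matrix of
#' 1-based vertex indices, one row per triangle.  Optional per-vertex slots
#' carry outward unit normals and, for MSMS surfaces, the 1-based index of the
#' nearest atom in the source structure.
#'
#' @param vertices numeric matrix, `n x 3`, one vertex per row (Angstrom).
#' @param faces integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @param atom_index optional integer vector of length `n`; 1-based nearest-atom
#'   index as reported by MSMS.
#' @param normals optional numeric matrix, `n x 3`, per-vertex unit normals.
#' @param colors optional integer matrix, `n x 3`, per-vertex RGB in 0..255.
#' @return an object of class `trimesh3d`.
#' @examples
#' m <- trimesh3d(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' n_vertices(m)
#' @export
trimesh3d <- function(vertices, faces, atom_index = NULL, normals = NULL,
                      colors = NULL) {
  vertices <- as_coord_matrix(vertices, 3L, "vertices")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L,
                  nrow = NROW(faces), dimnames = NULL)
  n <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (anyNA(faces) || any(faces < 1L) || any(faces > n))
      stop("face indices must lie in [1, ", n, "]", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
              faces[, 1] == faces[, 3]))
      stop("faces must not repeat a vertex", call. = FALSE)
  }
  if (!is.null(atom_index)) {
    atom_index <- as.integer(atom_index)
    stopifnot(length(atom_index) == n)
  }
  if (!is.null(normals)) {
    normals <- as_coord_matrix(normals, 3L, "normals")
    stopifnot(nrow(normals) == n)
  }
  if (!is.null(colors)) colors <- check_vertex_colors(colors, n)
  structure(list(vertices = vertices, faces = faces,
                 atom_index = atom_index, normals = normals, colors = colors),
            class = "trimesh3d")
}

as_coord_matrix <- function(x, d, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (ncol(x) != d) stop(what, " must have ", d, " columns", call. = FALSE)
  if (nrow(x) > 0L && !all(is.finite(x)))
    stop(what, " must be finite", call. = FALSE)
  x
}

check_vertex_colors <- function(colors, n) {
  colors <- as.matrix(colors)
  if (nrow(colors) != n || ncol(colors) != 3L)
    stop("vertex colors must be an n x 3 matrix aligned with the vertices",
         call. = FALSE)
  if (anyNA(colors) || any(colors < 0) || any(colors > 255))
    stop("vertex colors must lie in [0, 255]", call. = FALSE)
  storage.mode(colors) <- "integer"
  colors
}

#' @rdname trimesh3d
#' @param mesh a `trimesh3d`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname trimesh3d
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @export
print.trimesh3d <- function(x, ...) {
  cat(sprintf("<trimesh3d> %d vertices, %d faces", n_vertices(x), n_faces(x)))
  if (!is.null(x$atom_index)) cat(", with atom indices")
  if (!is.null(x$colors)) cat(", colored")
  cat("\n")
  invisible(x)
}

# Unique undirected edges of the face graph, as a 2-column matrix with
# edge[, 1] < edge[, 2].
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

# Drop vertices not referenced by any face and reindex the faces.
# Attaches the old->kept index map as attribute "vertex_map"
# (kept vertex i came from vertex_map[i] of the input).
drop_unreferenced <- function(mesh) {
  keep <- sort(unique(as.vector(mesh$faces)))
  map <- integer(n_vertices(mesh))
  map[keep] <- seq_along(keep)
  out <- trimesh3d(mesh$vertices[keep, , drop = FALSE],
                   matrix(map[mesh$faces], ncol = 3L),
                   atom_index = mesh$atom_index[keep],
                   normals = if (!is.null(mesh$normals))
                     mesh$normals[keep, , drop = FALSE],
                   colors = if (!is.null(mesh$colors))
                     mesh$colors[keep, , drop = FALSE])
  attr(out, "vertex_map") <- keep
  out
}
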