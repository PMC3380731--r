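#' Triangle areas of a mesh in 2-D or 3-D
#'
#' Half the magnitude of the edge cross product per face.  2-D point sets are
#' lifted to the `z = 0` plane, so the same faces can be measured before and
#' after flattening.
#'
#' @param points numeric matrix of coordinates, `n x 2` or `n x 3`.
#' @param faces integer matrix, `m x 3`, 1-based indices into `points`.
#' @return numeric vector of non-negative areas (squared length units).
#' @export
triangle_areas <- function(points, faces) {
  points <- as.matrix(points)
  if (ncol(points) == 2) points <- cbind(points, 0)
  stopifnot(ncol(points) == 3)
  faces <- as.matrix(faces)
  a <- points[faces[, 2], , drop = FALSE] - points[faces[, 1], , drop = FALSE]
  b <- points[faces[, 3], , drop = FALSE] - points[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Area score of a flattening
#'
#' Pearson's correlation coefficient between the areas of the surface
#' triangles measured in 3-D and re-measured under the 2-D map coordinates.
#' Ranges over `[-1, 1]`; 1 means the flattening rescales all triangles by a
#' common factor (no relative areal distortion).  Invariant to rigid motions
#' and uniform scalings of either side.
#'
#' @param mesh a [trimesh3d] with at least 3 faces.
#' @param emb an [embedding2d] aligned with `mesh`.
#' @return the correlation (dimensionless).
#' @export
area_score <- function(mesh, emb) {
  check_aligned(mesh, emb)
  if (n_faces(mesh) < 3) stop("need at least 3 faces", call. = FALSE)
  a3 <- triangle_areas(mesh$vertices, mesh$faces)
  a2 <- triangle_areas(emb$coords, mesh$faces)
  if (sd(a3) == 0 || sd(a2) == 0)
    stop("area score undefined: zero variance in triangle areas",
         call. = FALSE)
  cor(a3, a2)
}

check_aligned <- function(mesh, emb) {
  stopifnot(inherits(mesh, "trimesh3d"), inherits(emb, "embedding2d"))
  if (nrow(emb$coords) != n_vertices(mesh))
    stop("embedding is not aligned with the mesh (",
         nrow(emb$coords), " vs ", n_vertices(mesh), " vertices)",
         call. = FALSE)
}

#' k-nearest-neighbor connectivity bits
#'
#' For each vertex the `k` nearest other vertices under the supplied distance
#' matrix are marked.  Distances are rounded to 10 significant digits before
#' ranking and ties broken by ascending vertex index: regular meshes are full
#' of exactly equidistant neighbors, and without the rounding two embeddings
#' identical up to a rigid rotation could tie-break differently on
#' floating-point noise.  By default the
#' resulting directed connectivity matrix is linearized as-is over all
#' ordered vertex pairs (each vertex contributes exactly `k` bits);
#' `symmetrize = "union"` instead ors the matrix with its transpose and
#' linearizes the unordered pairs.  These bit vectors are the `X` and `Y`
#' of the Tanimoto neighbor score.
#'
#' `knn_connectivity_3d()` uses geodesic distances over the mesh edges;
#' `knn_connectivity_2d()` uses Euclidean distances in the map plane.
#'
#' @param distances symmetric `n x n` distance matrix.
#' @param k number of neighbors to mark per vertex (`k < n`).
#' @param symmetrize `"none"` (default) or `"union"`.
#' @return object of class `connectivity_bits`: list with `n`, `k`,
#'   `symmetrize`, the logical `adjacency` matrix, and the linearized
#'   `bits`.
#' @export
knn_connectivity <- function(distances, k = 3,
                             symmetrize = c("none", "union")) {
  symmetrize <- match.arg(symmetrize)
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n <= k) stop("need more than k vertices", call. = FALSE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- signif(distances[i, ], 10)
    d[i] <- Inf
    adj[i, order(d)[seq_len(k)]] <- TRUE   # order() breaks ties by index
  }
  if (symmetrize == "union") {
    adj <- adj | t(adj)
    bits <- adj[upper.tri(adj)]
  } else {
    bits <- adj[row(adj) != col(adj)]
  }
  structure(list(n = n, k = k, symmetrize = symmetrize, adjacency = adj,
                 bits = bits),
            class = "connectivity_bits")
}

#' @rdname knn_connectivity
#' @param mesh a connected [trimesh3d].
#' @export
knn_connectivity_3d <- function(mesh, k = 3,
                                symmetrize = c("none", "union")) {
  knn_connectivity(geodesic_distances(mesh), k = k, symmetrize = symmetrize)
}

#' @rdname knn_connectivity
#' @param emb an [embedding2d].
#' @export
knn_connectivity_2d <- function(emb, k = 3,
                                symmetrize = c("none", "union")) {
  knn_connectivity(as.matrix(dist(emb$coords)), k = k,
                   symmetrize = symmetrize)
}

#' Tanimoto coefficient of two bit vectors
#'
#' `T(X, Y) = X.Y / (|X|^2 + |Y|^2 - X.Y)` for 0/1 vectors, which equals the
#' Jaccard similarity of the corresponding pair sets.  Both-empty input is
#' defined as 1 (identical empty neighborhoods).
#'
#' @param x,y logical/0-1 vectors of equal length, or `connectivity_bits`.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(x, y) {
  if (inherits(x, "connectivity_bits")) x <- x$bits
  if (inherits(y, "connectivity_bits")) y <- y$bits
  x <- as.logical(x)
  y <- as.logical(y)
  if (length(x) != length(y))
    stop("bit vectors must have equal length", call. = FALSE)
  both <- sum(x & y)
  denom <- sum(x) + sum(y) - both
  if (denom == 0) return(1)
  both / denom
}

#' Neighbor score of a flattening
#'
#' Tanimoto similarity between the 3-D connectivity bits (k nearest by
#' geodesic distance over the mesh) and the 2-D connectivity bits (k nearest
#' by Euclidean distance in the map).  Ranges over `[0, 1]`; 1 means every
#' geodesic neighborhood survived the flattening.
#'
#' @inheritParams area_score
#' @inheritParams knn_connectivity
#' @param k neighbors per vertex (the reference evaluation uses 3).
#' @return the similarity (dimensionless).
#' @export
neighbor_score <- function(mesh, emb, k = 3,
                           symmetrize = c("none", "union")) {
  check_aligned(mesh, emb)
  tanimoto(knn_connectivity_3d(mesh, k, symmetrize = symmetrize),
           knn_connectivity_2d(emb, k, symmetrize = symmetrize))
}

#' Score one (mesh, embedding) pair
#'
#' Convenience wrapper computing both fidelity metrics at once.
#'
#' @inheritParams neighbor_score
#' @return object of class `score_report` with fields `area_score`,
#'   `neighbor_score`, `k`, `method`, `n_vertices`, `n_faces`.
#' @examples
#' hemi <- cut_halfspace(make_icosphere(2), "z", "+", origin = c(0, 0, 0))
#' score_map(hemi, embed_pca(hemi))
#' @export
score_map <- function(mesh, emb, k = 3) {
  structure(list(area_score = area_score(mesh, emb),
                 neighbor_score = neighbor_score(mesh, emb, k = k),
                 k = as.integer(k), method = emb$method,
                 n_vertices = n_vertices(mesh), n_faces = n_faces(mesh)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s: area %.3f, neighbor %.3f (k=%d, %d vertices / %d faces)\n",
              x$method, x$area_score, x$neighbor_score, x$k,
              x$n_vertices, x$n_faces))
  invisible(x)
}
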