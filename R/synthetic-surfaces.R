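#' Subdivided icosahedral sphere
#'
#' Builds a unit sphere by recursively subdividing a regular icosahedron and
#' projecting every vertex back onto the sphere.  Level `L` yields
#' `10 * 4^L + 2` vertices and `20 * 4^L` triangles; level 2 gives the
#' 162-vertex / 320-triangle sphere used as the synthetic benchmark surface.
#' The icosahedron uses the standard cyclic golden-ratio coordinates
#' `(+/-1, +/-phi, 0)`, so four of its vertices (and their subdivision
#' midpoints) lie exactly on the `z = 0` plane.
#'
#' @param subdivision_level non-negative integer, at most 6.
#' @return a [trimesh3d] with all vertices at unit radius.
#' @examples
#' sph <- make_icosphere(2)
#' c(n_vertices(sph), n_faces(sph))  # 162 320
#' @export
make_icosphere <- function(subdivision_level) {
  if (length(subdivision_level) != 1L || is.na(subdivision_level) ||
        subdivision_level < 0 || subdivision_level != round(subdivision_level))
    stop("subdivision_level must be a single non-negative integer",
         call. = FALSE)
  if (subdivision_level > 6) stop("subdivision_level must be <= 6",
                                  call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  v <- v / sqrt(rowSums(v^2))
  for (lev in seq_len(subdivision_level)) {
    sub <- subdivide_once(v, f)
    v <- sub$vertices / sqrt(rowSums(sub$vertices^2))
    f <- sub$faces
  }
  trimesh3d(v, f, normals = v)
}

# One loop-style 1->4 subdivision with shared edge midpoints deduplicated.
subdivide_once <- function(v, f) {
  midpoint_id <- new.env(hash = TRUE, parent = emptyenv())
  verts <- vector("list", 4L * nrow(f))
  n <- nrow(v)
  get_mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    id <- midpoint_id[[key]]
    if (is.null(id)) {
      n <<- n + 1L
      id <- n
      verts[[n - nrow(v)]] <<- (v[a, ] + v[b, ]) / 2
      midpoint_id[[key]] <- id
    }
    id
  }
  newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    newf[4L * i - 3L, ] <- c(a, ab, ca)
    newf[4L * i - 2L, ] <- c(b, bc, ab)
    newf[4L * i - 1L, ] <- c(c, ca, bc)
    newf[4L * i, ] <- c(ab, bc, ca)
  }
  list(vertices = rbind(v, do.call(rbind, verts[seq_len(n - nrow(v))])),
       faces = newf)
}

#' Cut a mesh with an axis-aligned half-space
#'
#' Keeps exactly the faces whose three vertices all lie on the requested side
#' of the plane through `origin` perpendicular to `axis`.  Faces straddling
#' the plane are dropped (no edge clipping); vertices lying exactly on the
#' plane satisfy both half-spaces, so complementary cuts share the boundary
#' ring.  Unreferenced vertices are removed; the surviving vertices' original
#' indices are attached as attribute `"vertex_map"`.
#'
#' @param mesh a [trimesh3d].
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param sign `"+"` to keep the side of larger coordinates, `"-"` the other.
#' @param origin point on the cutting plane; defaults to the vertex centroid.
#' @param tol on-plane tolerance (absolute, Angstrom).
#' @return the cut [trimesh3d].
#' @examples
#' hemi <- cut_halfspace(make_icosphere(2), "z", "+", origin = c(0, 0, 0))
#' @export
cut_halfspace <- function(mesh, axis = c("x", "y", "z"), sign = c("+", "-"),
                          origin = NULL, tol = 1e-9) {
  axis <- match.arg(axis)
  sign <- match.arg(sign)
  if (is.null(origin)) origin <- mesh_centroid(mesh)
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  ax <- match(axis, c("x", "y", "z"))
  s <- if (sign == "+") 1 else -1
  pass <- s * (mesh$vertices[, ax] - origin[ax]) >= -tol
  keep_face <- pass[mesh$faces[, 1]] & pass[mesh$faces[, 2]] &
    pass[mesh$faces[, 3]]
  if (!any(keep_face))
    stop("empty section: no face lies entirely in the ", sign, axis,
         " half-space", call. = FALSE)
  out <- mesh
  out$faces <- mesh$faces[keep_face, , drop = FALSE]
  drop_unreferenced(out)
}

#' Open cylinder sector mesh
#'
#' `n_u x n_v` grid on an open cylinder sector, triangulated with
#' checkerboard-alternating quad diagonals (so the edge graph carries both
#' diagonal directions and graph geodesics are nearly isotropic).  Being
#' developable, the patch flattens isometrically to the plane by unrolling
#' (`u = radius * theta`, `v = z`); the analytic development is attached as
#' attribute `"uv"` and serves as a ground-truth flattening for embedding
#' tests.  By default both grid spacings grow linearly (largest step twice
#' the smallest): a perfectly uniform grid makes every triangle congruent
#' (the area score, a correlation of areas, would be undefined) and fills
#' the patch with exactly equidistant neighbor pairs whose k-NN ranking is
#' decided by floating-point noise rather than geometry.  `graded = FALSE`
#' gives the uniform grid.
#'
#' @param radius cylinder radius (Angstrom).
#' @param height patch height (Angstrom).
#' @param n_u,n_v number of grid points around and along the axis (>= 2).
#' @param angular_extent sector angle in radians, strictly inside (0, 2*pi);
#'   a full cylinder is not simply flattenable.
#' @param graded linearly grade the grid steps (default) or space them
#'   uniformly.
#' @return a [trimesh3d] with attribute `"uv"` (the unrolled coordinates).
#' @export
make_cylinder_patch <- function(radius = 1, height = 2, n_u = 8, n_v = 8,
                                angular_extent = pi, graded = TRUE) {
  stopifnot(radius > 0, height > 0)
  if (n_u < 2 || n_v < 2) stop("n_u and n_v must be >= 2", call. = FALSE)
  if (!(angular_extent > 0 && angular_extent < 2 * pi))
    stop("angular_extent must lie strictly within (0, 2*pi)", call. = FALSE)
  graded_steps <- function(extent, n) {
    if (graded && n > 2) {
      w <- 1 + (seq_len(n - 1) - 1) / (n - 2)   # step sizes, ratio 2
      extent * c(0, cumsum(w)) / sum(w)
    } else {
      seq(0, extent, length.out = n)
    }
  }
  theta <- graded_steps(angular_extent, n_u)
  z <- graded_steps(height, n_v)
  grid <- expand.grid(u = seq_len(n_u), v = seq_len(n_v))
  th <- theta[grid$u]
  zz <- z[grid$v]
  v <- cbind(radius * cos(th), radius * sin(th), zz)
  idx <- function(i, j) (j - 1L) * n_u + i
  faces <- matrix(0L, ncol = 3L, nrow = 2L * (n_u - 1L) * (n_v - 1L))
  r <- 0L
  for (j in seq_len(n_v - 1L)) {
    for (i in seq_len(n_u - 1L)) {
      if ((i + j) %% 2L == 0L) {
        faces[r + 1L, ] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
        faces[r + 2L, ] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L),
                             idx(i, j + 1L))
      } else {
        faces[r + 1L, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
        faces[r + 2L, ] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
      }
      r <- r + 2L
    }
  }
  out <- trimesh3d(v, faces)
  attr(out, "uv") <- cbind(radius * th, zz)
  out
}
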