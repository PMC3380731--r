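#' 2-D embedding of a mesh's vertices
#'
#' Container for a planar map of a surface: an `n x 2` coordinate matrix in
#' the same order as the source mesh's vertices, together with the method
#' name, its parameters and (for stochastic methods) the seed, so any
#' embedding can be regenerated deterministically.
#'
#' @param coords numeric `n x 2` matrix of map coordinates (unitless).
#' @param method method tag, e.g. `"pca"`.
#' @param params named list of method parameters.
#' @param seed integer seed, or `NULL` for deterministic methods.
#' @return an object of class `embedding2d`.
#' @export
embedding2d <- function(coords, method, params = list(), seed = NULL) {
  coords <- as_coord_matrix(coords, 2L, "coords")
  structure(list(coords = coords, method = method, params = params,
                 seed = seed),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %s, %d vertices\n", x$method, nrow(x$coords)))
  invisible(x)
}

# Fix the sign of each embedding column so that the entry with the largest
# magnitude is positive; makes spectral methods reproducible across BLAS
# implementations (eigenvectors are defined only up to sign).
fix_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

check_embeddable <- function(mesh) {
  if (n_vertices(mesh) < 3)
    stop("at least 3 vertices are required", call. = FALSE)
}

#' Principal component analysis map
#'
#' Centers the vertices and projects them onto the top two principal axes
#' (ordered by decreasing variance).  Linear, deterministic, and the
#' initialization of [embed_sammon()].
#'
#' @param mesh a [trimesh3d].
#' @return an [embedding2d].
#' @export
embed_pca <- function(mesh) {
  check_embeddable(mesh)
  x <- scale(mesh$vertices, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 2, nv = 2)
  if (sv$d[2] <= sv$d[1] * 1e-10)
    stop("degenerate geometry: vertex cloud has rank < 2", call. = FALSE)
  coords <- fix_signs(sv$u %*% diag(sv$d[1:2]))
  embedding2d(coords, "pca",
              params = list(var_explained = sum(sv$d[1:2]^2) / sum(sv$d^2)))
}

#' Classical multidimensional scaling map
#'
#' Torgerson scaling of the Euclidean vertex distance matrix: the squared
#' distances are double-centered and the top-2 spectral embedding taken.
#' For Euclidean input this is equivalent to PCA up to an orthogonal
#' transform, which is why PCA and MDS always score identically.
#'
#' @inheritParams embed_pca
#' @return an [embedding2d].
#' @export
embed_mds <- function(mesh) {
  check_embeddable(mesh)
  fit <- cmdscale(dist(mesh$vertices), k = 2, eig = TRUE)
  if (ncol(fit$points) < 2 || fit$eig[2] <= fit$eig[1] * 1e-10)
    stop("degenerate geometry: vertex cloud has rank < 2", call. = FALSE)
  embedding2d(fix_signs(fit$points), "mds",
              params = list(eig = fit$eig[1:2]))
}

# Sammon stress of a 2-D configuration against reference distances d3
# (both "dist" objects or vectors): (1/sum d3) * sum (d3 - d2)^2 / d3.
sammon_stress <- function(d3, coords2) {
  d3 <- as.vector(d3)
  d2 <- as.vector(dist(coords2))
  sum((d3 - d2)^2 / d3) / sum(d3)
}

#' Sammon mapping
#'
#' Minimizes Sammon's stress
#' \deqn{E = \frac{1}{\sum_{i<j} d_{ij}} \sum_{i<j} \frac{(d_{ij} -
#'   \delta_{ij})^2}{d_{ij}}}{E = (1/sum d) sum (d - delta)^2 / d}
#' where \eqn{d} are the 3-D Euclidean distances and \eqn{\delta} the 2-D map
#' distances, by iterative descent (via [MASS::sammon()]) from the PCA
#' solution.  The inverse-distance weighting makes short-range errors
#' expensive, so local structure is preserved preferentially.
#'
#' @inheritParams embed_pca
#' @param max_iter maximum number of descent iterations.
#' @param tolerance stop when the stress improves by less than this.
#' @return an [embedding2d]; `params` records the initial and final stress.
#' @export
embed_sammon <- function(mesh, max_iter = 500, tolerance = 1e-7) {
  check_embeddable(mesh)
  d3 <- dist(mesh$vertices)
  if (any(d3 == 0))
    stop("duplicate vertices: Sammon stress has infinite weight at zero distance",
         call. = FALSE)
  init <- embed_pca(mesh)$coords
  dup <- duplicated(round(init, 12))
  if (any(dup)) {
    # break exact 2-D collisions in the init deterministically
    eps <- max(abs(init)) * 1e-8
    init[dup, 1] <- init[dup, 1] + eps * seq_len(sum(dup))
  }
  stress0 <- sammon_stress(d3, init)
  fit <- MASS::sammon(d3, y = init, k = 2, niter = max_iter,
                      tol = tolerance, trace = FALSE)
  coords <- fit$points
  stress1 <- sammon_stress(d3, coords)
  if (stress1 > stress0) {          # descent contract: never worse than init
    coords <- init
    stress1 <- stress0
  }
  embedding2d(coords, "sammon",
              params = list(max_iter = max_iter, tolerance = tolerance,
                            stress_init = stress0, stress = stress1))
}

#' Geodesic distances over the mesh edge graph
#'
#' Shortest-path distances over the triangulation (Dijkstra via igraph).
#' The neighborhood graph is derived purely from the mesh topology -- the
#' triangulation is the true surface topology, so no ambient-space
#' k-nearest-neighbor graph (with its shortcut-edge artifacts) is ever
#' built.  With `ring = 1` only the mesh edges are used; the default
#' `ring = 2` also connects each vertex to its neighbors' neighbors by
#' their straight-line chord, which roughly halves the crystalline
#' anisotropy bias of graph shortest paths (a path restricted to mesh edges
#' overestimates distances in directions between edge directions) while the
#' chords still span only a two-edge surface neighborhood.
#'
#' @param mesh a connected [trimesh3d].
#' @param sources optional vertex indices; rows of the result (default all).
#' @param ring topological radius of the distance graph (1 = edges only).
#' @return numeric matrix, `length(sources) x n_vertices`, in Angstrom.
#' @export
geodesic_distances <- function(mesh, sources = NULL, ring = 2) {
  n <- n_vertices(mesh)
  edges <- mesh_edges(mesh)
  if (ring > 1) {
    a <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                              j = c(edges[, 2], edges[, 1]),
                              x = 1, dims = c(n, n))
    acc <- a
    ak <- a
    for (r in seq_len(ring - 1)) {
      ak <- ak %*% a
      acc <- acc + ak
    }
    idx <- Matrix::which(acc > 0, arr.ind = TRUE)
    edges <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("mesh edge graph is disconnected (component sizes: ",
         paste(comp$csize, collapse = ", "), ")", call. = FALSE)
  w <- sqrt(rowSums((mesh$vertices[edges[, 1], , drop = FALSE] -
                       mesh$vertices[edges[, 2], , drop = FALSE])^2))
  if (is.null(sources)) sources <- seq_len(n)
  igraph::distances(g, v = sources, weights = w, algorithm = "dijkstra")
}

#' Isomap
#'
#' Classical scaling of the geodesic distance matrix: Dijkstra shortest paths
#' over the mesh edges followed by Torgerson double-centering and a top-2
#' spectral embedding.  On developable surfaces the geodesic metric is flat,
#' so Isomap recovers the isometric development.
#'
#' @inheritParams geodesic_distances
#' @return an [embedding2d].
#' @export
embed_isomap <- function(mesh, ring = 2) {
  check_embeddable(mesh)
  d <- geodesic_distances(mesh, ring = ring)
  fit <- cmdscale(d, k = 2, eig = TRUE)
  if (ncol(fit$points) < 2)
    stop("degenerate geodesic geometry: rank < 2", call. = FALSE)
  embedding2d(fix_signs(fit$points), "isomap",
              params = list(eig = fit$eig[1:2]))
}

#' Landmark Isomap
#'
#' Isomap made cheap: geodesic distances are computed only from `n_landmarks`
#' seeded uniformly-sampled vertices, the landmarks are embedded by classical
#' scaling of their mutual distances, and every other vertex is placed by
#' distance-based triangulation against the landmark embedding (the standard
#' landmark-MDS out-of-sample formula).
#'
#' @inheritParams geodesic_distances
#' @param n_landmarks number of landmarks (3 to `n_vertices`).
#' @param seed integer seed for the landmark draw.
#' @return an [embedding2d].
#' @export
embed_landmark_isomap <- function(mesh, n_landmarks = 50, seed = 0) {
  n <- n_vertices(mesh)
  check_embeddable(mesh)
  if (n_landmarks < 3 || n_landmarks > n)
    stop("n_landmarks must lie in [3, n_vertices]", call. = FALSE)
  landmarks <- with_seed(seed, sort(sample.int(n, n_landmarks)))
  dl <- geodesic_distances(mesh, sources = landmarks)   # k x n
  dll2 <- dl[, landmarks, drop = FALSE]^2
  k <- n_landmarks
  # double-center the landmark block
  b <- -0.5 * (dll2 - outer(rowMeans(dll2), rep(1, k)) -
                 outer(rep(1, k), colMeans(dll2)) + mean(dll2))
  eg <- eigen(b, symmetric = TRUE)
  if (eg$values[2] <= max(eg$values[1], 0) * 1e-10)
    stop("degenerate landmark geometry: rank < 2", call. = FALSE)
  vecs <- eg$vectors[, 1:2, drop = FALSE]
  vals <- eg$values[1:2]
  # out-of-sample placement: x_a = -1/2 * pinv(L)' (delta_a - delta_mean)
  pinv <- t(vecs) / sqrt(vals)                          # 2 x k
  mu <- rowMeans(dll2)                                  # mean sq dist per landmark
  coords <- t(-0.5 * (pinv %*% (dl^2 - mu)))            # n x 2
  embedding2d(fix_signs(coords), "landmark_isomap",
              params = list(n_landmarks = n_landmarks, landmarks = landmarks),
              seed = seed)
}

#' Stochastic neighbor embedding
#'
#' Vanilla (Gaussian) SNE: 3-D conditional neighbor probabilities
#' \eqn{p_{j|i}} with per-point bandwidths solved by bisection to match the
#' requested perplexity, Gaussian map probabilities \eqn{q_{j|i}}, and
#' gradient descent on \eqn{\sum_i KL(P_i \| Q_i)} from a seeded
#' small-noise start.  The step size starts at `learning_rate` and adapts:
#' a step that lowers the cost is accepted and the step grown by 10%, a
#' step that raises it is rejected and the step halved, so the cost is
#' monotonically non-increasing and the final cost never exceeds the
#' initial one.
#'
#' @inheritParams embed_pca
#' @param perplexity effective neighbor count; `n_vertices` must be at least
#'   `3 * perplexity`.
#' @param n_iter gradient-descent iterations.
#' @param learning_rate initial gradient step size (adapted during the
#'   descent).
#' @param seed integer seed for the initialization.
#' @return an [embedding2d]; `params` records initial and final KL cost.
#' @export
embed_sne <- function(mesh, perplexity = 15, n_iter = 1000,
                      learning_rate = 10, seed = 0) {
  n <- n_vertices(mesh)
  if (n < 3 * perplexity)
    stop("need n_vertices >= 3 * perplexity", call. = FALSE)
  d2 <- as.matrix(dist(mesh$vertices))^2
  p <- sne_affinities(d2, perplexity)
  y <- with_seed(seed, matrix(rnorm(2L * n, sd = 1e-4), ncol = 2))
  eps <- 1e-12
  kl_cost <- function(q) sum(p * log((p + eps) / (q + eps)))
  q_of <- function(y) {
    w <- exp(-as.matrix(dist(y))^2)
    diag(w) <- 0
    w / pmax(rowSums(w), eps)
  }
  q <- q_of(y)
  cost <- kl_cost(q)
  cost0 <- cost
  lr <- learning_rate
  for (it in seq_len(n_iter)) {
    m <- p - q + t(p) - t(q)
    grad <- 2 * (rowSums(m) * y - m %*% y)
    y_new <- y - lr * grad
    q_new <- q_of(y_new)
    cost_new <- kl_cost(q_new)
    if (is.finite(cost_new) && cost_new < cost) {
      y <- y_new; q <- q_new; cost <- cost_new
      lr <- lr * 1.1
    } else {
      lr <- lr / 2                  # rejected step; try a shorter one
      if (lr < 1e-12) break
    }
  }
  embedding2d(y, "sne",
              params = list(perplexity = perplexity, n_iter = n_iter,
                            learning_rate = learning_rate,
                            kl_init = cost0, kl = cost),
              seed = seed)
}

# Conditional Gaussian affinities p_{j|i} with per-point precision solved by
# bisection so each row's perplexity (2^entropy) matches the target.
sne_affinities <- function(d2, perplexity, max_bisect = 64) {
  n <- nrow(d2)
  target <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    ok <- FALSE
    for (rep in seq_len(max_bisect)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0 || !is.finite(sw)) { h <- 0 } else {
        h <- log(sw) + beta * sum(di * w) / sw   # Shannon entropy (nats)
      }
      if (!is.finite(h)) break
      if (abs(h - target) < 1e-5) { ok <- TRUE; break }
      if (h > target) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else { hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    if (!is.finite(sum(w)) || sum(w) <= 0)
      stop("perplexity bandwidth search failed at vertex ", i, call. = FALSE)
    p[i, -i] <- w / sum(w)
  }
  p
}

#' Equal-area sinusoidal projection
#'
#' Classic cartographic baseline: each vertex is converted to spherical
#' coordinates (latitude `phi`, longitude `lambda`) about the vertex
#' centroid, and mapped to
#' `x = R * (lambda - lambda0) * cos(phi)`, `y = R * phi`, with `R` the mean
#' radial distance and `lambda0` the circular mean longitude.  Unlike the
#' spectral methods this never collapses antipodes, but it tears the surface
#' at the longitude `+/- pi` seam.
#'
#' @inheritParams embed_pca
#' @return an [embedding2d].
#' @export
project_sinusoidal <- function(mesh) {
  v <- sweep(mesh$vertices, 2, mesh_centroid(mesh))
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-12))
    stop("vertex coincides with the centroid; spherical coordinates undefined",
         call. = FALSE)
  lat <- asin(pmin(1, pmax(-1, v[, 3] / r)))
  lon <- atan2(v[, 2], v[, 1])
  lon0 <- atan2(mean(sin(lon)), mean(cos(lon)))
  dlon <- (lon - lon0 + pi) %% (2 * pi) - pi
  rbar <- mean(r)
  embedding2d(cbind(rbar * dlon * cos(lat), rbar * lat), "sinusoidal",
              params = list(mean_radius = rbar, mean_longitude = lon0))
}

#' Run one embedding method by name
#'
#' Dispatcher used by the benchmark, the pipeline and the command line:
#' `"pca"`, `"mds"`, `"sammon"`, `"isomap"`, `"landmark-isomap"`, `"sne"` or
#' `"sinusoidal"`.
#'
#' @inheritParams embed_pca
#' @param method method name (see Details).
#' @param seed seed forwarded to stochastic methods.
#' @param ... further arguments for the specific method.
#' @return an [embedding2d].
#' @export
embed_map <- function(mesh, method, seed = 0, ...) {
  switch(method,
    "pca" = embed_pca(mesh),
    "mds" = embed_mds(mesh),
    "sammon" = embed_sammon(mesh, ...),
    "isomap" = embed_isomap(mesh),
    "landmark-isomap" = embed_landmark_isomap(mesh, seed = seed, ...),
    "sne" = embed_sne(mesh, seed = seed, ...),
    "sinusoidal" = project_sinusoidal(mesh),
    stop("unknown method '", method, "'; available: ",
         paste(embedding_methods(), collapse = ", "), call. = FALSE))
}

#' @rdname embed_map
#' @export
embedding_methods <- function() {
  c("pca", "mds", "sammon", "isomap", "landmark-isomap", "sne", "sinusoidal")
}
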