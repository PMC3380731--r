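hemi <- reference_hemisphere()

test_that("PCA of a planar mesh is a rigid transform of the plane", {
  g <- planar_grid_mesh(5, 5)
  e <- embed_pca(g)
  d3 <- dist(g$vertices)
  d2 <- dist(e$coords)
  expect_lt(max(abs(d3 - d2)), 1e-9)
})

test_that("PCA is linear and deterministic", {
  e1 <- embed_pca(hemi)
  doubled <- hemi
  doubled$vertices <- 2 * doubled$vertices
  e2 <- embed_pca(doubled)
  expect_equal(e2$coords, 2 * e1$coords)
  expect_identical(embed_pca(hemi)$coords, e1$coords)
})

test_that("rank-deficient geometry is rejected", {
  line <- trimesh3d(cbind(c(0, 1, 2), 0, 0), rbind(c(1, 2, 3)))
  expect_error(embed_pca(line), "rank")
  expect_error(embed_mds(line), "rank")
})

test_that("classical MDS equals PCA up to an orthogonal transform", {
  for (mesh in list(hemi, make_cylinder_patch(n_u = 10, n_v = 10))) {
    p <- embed_pca(mesh)
    m <- embed_mds(mesh)
    expect_lt(procrustes_residual(p$coords, m$coords), 1e-8)
  }
})

test_that("two points embed at their original distance under MDS", {
  # smallest full-rank config: a triangle with distinct edge lengths
  tri <- trimesh3d(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                   rbind(c(1, 2, 3)))
  e <- embed_mds(tri)
  expect_equal(as.vector(dist(e$coords)), as.vector(dist(tri$vertices)),
               tolerance = 1e-9)
})

test_that("Sammon mapping never worsens the PCA initialization", {
  e <- embed_sammon(hemi)
  expect_lte(e$params$stress, e$params$stress_init)
  expect_gt(e$params$stress_init, 0)
})

test_that("Sammon stress of a planar mesh is already near zero", {
  g <- planar_grid_mesh(5, 5)
  e <- embed_sammon(g)
  expect_lt(e$params$stress, 1e-12)
})

test_that("duplicate vertices are rejected by Sammon", {
  m <- trimesh3d(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)),
                 rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_error(embed_sammon(m), "duplicate")
})

test_that("geodesic distance of a single edge is its length", {
  tri <- trimesh3d(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                   rbind(c(1, 2, 3)))
  d <- geodesic_distances(tri)
  expect_equal(d[1, 2], 3)
  expect_equal(d[1, 3], 4)
  expect_equal(d[2, 3], 5)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("geodesics agree with an independent Floyd-Warshall oracle", {
  m <- make_icosphere(1)
  d <- geodesic_distances(m, ring = 1)
  e <- unique(rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((m$vertices[e[, 1], ] - m$vertices[e[, 2], ])^2))
  expect_equal(d, floyd_warshall(n_vertices(m), e, w), ignore_attr = TRUE)
})

test_that("geodesic distances satisfy the triangle inequality", {
  d <- geodesic_distances(make_icosphere(1))
  n <- nrow(d)
  viol <- 0
  for (i in seq_len(n))
    viol <- viol + sum(d > outer(d[, i], d[i, ], "+") + 1e-9)
  expect_identical(viol, 0)
})

test_that("disconnected meshes are diagnosed with component sizes", {
  m <- trimesh3d(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                       c(9, 9, 0), c(10, 9, 0), c(9, 10, 0)),
                 rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(geodesic_distances(m), "component sizes: 3, 3")
})

test_that("cylinder corner geodesics match the unrolled planar distances", {
  n <- 21
  cyl <- make_cylinder_patch(n_u = n, n_v = n, graded = FALSE)
  uv <- attr(cyl, "uv")
  corners <- c(1, n, n * (n - 1) + 1, n * n)
  d <- geodesic_distances(cyl, sources = corners)
  for (i in 1:3) for (j in (i + 1):4) {
    planar <- sqrt(sum((uv[corners[i], ] - uv[corners[j], ])^2))
    expect_equal(d[i, corners[j]], planar, tolerance = 0.02)
  }
})

test_that("Isomap flattens the developable patch near-isometrically", {
  cyl <- make_cylinder_patch(n_u = 20, n_v = 20)
  iso <- embed_isomap(cyl)
  expect_gte(area_score(cyl, iso), 0.99)
  expect_gte(neighbor_score(cyl, iso), 0.9)
  expect_lt(area_score(cyl, embed_pca(cyl)), area_score(cyl, iso))
})

test_that("Isomap of a planar mesh reduces to MDS", {
  # graph shortest paths slightly overestimate straight-line distances
  # between far pairs, so the match is close but not exact
  g <- planar_grid_mesh(5, 5)
  res <- procrustes_residual(embed_isomap(g)$coords, embed_mds(g)$coords)
  scale <- sqrt(mean(scale(g$vertices, scale = FALSE)^2))
  expect_lt(res / scale, 0.05)
})

test_that("landmark Isomap reaches full Isomap in the all-landmarks limit", {
  iso <- embed_isomap(hemi)
  lm <- embed_landmark_isomap(hemi, n_landmarks = n_vertices(hemi), seed = 3)
  expect_lt(procrustes_residual(iso$coords, lm$coords), 1e-8)
})

test_that("landmark Isomap is seed-reproducible and close to full Isomap", {
  a <- embed_landmark_isomap(hemi, n_landmarks = 50, seed = 7)
  b <- embed_landmark_isomap(hemi, n_landmarks = 50, seed = 7)
  expect_identical(a$coords, b$coords)
  expect_lt(abs(area_score(hemi, a) - area_score(hemi, embed_isomap(hemi))),
            0.15)
  expect_error(embed_landmark_isomap(hemi, n_landmarks = 2), "n_landmarks")
})

test_that("SNE descends its KL cost and is seed-reproducible", {
  e <- embed_sne(hemi, seed = 0)
  expect_lte(e$params$kl, e$params$kl_init)
  expect_identical(embed_sne(hemi, seed = 0)$coords, e$coords)
  scores <- vapply(0:4, function(s)
    neighbor_score(hemi, embed_sne(hemi, seed = s)), numeric(1))
  expect_lt(max(scores) - min(scores), 0.1)
})

test_that("SNE requires enough vertices for the perplexity", {
  small <- make_icosphere(0)
  expect_error(embed_sne(small, perplexity = 15), "perplexity")
})

test_that("the sinusoidal projection behaves like its map formula", {
  # ring of points on the equator plus the two poles, around the origin
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- rbind(cbind(cos(th), sin(th), 0), c(0, 0, 1), c(0, 0, -1))
  m <- trimesh3d(pts, rbind(c(1, 2, 13), c(2, 3, 13), c(1, 2, 14)))
  # centroid is at the origin by symmetry of the ring + poles
  e <- project_sinusoidal(m)
  eq <- seq_len(12)
  expect_lt(max(abs(e$coords[eq, 2])), 1e-9)          # equator maps to y = 0
  expect_lt(max(abs(e$coords[13:14, 1])), 1e-9)       # poles map to x = 0
  # x spacing proportional to longitude difference along the equator
  dx <- diff(e$coords[eq, 1][order(th)])
  expect_lt(diff(range(abs(dx[abs(dx) < 3]))), 1e-6)
})

test_that("a vertex at the centroid has no spherical coordinates", {
  m <- trimesh3d(rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                       c(0, 1, 0), c(0, -1, 0)),
                 rbind(c(1, 2, 4), c(1, 3, 5)))   # centroid = vertex 1
  expect_error(project_sinusoidal(m), "centroid")
})

test_that("every embedding preserves vertex order and count", {
  for (meth in embedding_methods()) {
    e <- embed_map(hemi, meth, seed = 0)
    expect_identical(nrow(e$coords), n_vertices(hemi))
    expect_true(all(is.finite(e$coords)))
  }
  expect_error(embed_map(hemi, "tsne"), "unknown method")
})

test_that("deterministic methods are bit-reproducible across runs", {
  for (meth in c("pca", "mds", "sammon", "isomap", "sinusoidal")) {
    expect_identical(embed_map(hemi, meth)$coords,
                     embed_map(hemi, meth)$coords, info = meth)
  }
})
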