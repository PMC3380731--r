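test_that("hydrophobicity comes straight from the Kyte-Doolittle table", {
  dir <- withr::local_tempdir()
  # poly-isoleucine fragment: every vertex must score +4.5, the scale's max
  ile <- rbind(pdb_atom_row("CA", "ILE", 1, 0, 0, 0, element = "C"),
               pdb_atom_row("CB", "ILE", 1, 1.5, 0, 0, element = "C"),
               pdb_atom_row("CA", "ILE", 2, 3.0, 0, 0, element = "C"))
  s <- read_pdb(write_pdb_fixture(ile, file.path(dir, "ile.pdb")))
  mesh <- trimesh3d(rbind(c(0, 1, 0), c(1.5, 1, 0), c(3, 1, 0)),
                    rbind(c(1, 2, 3)))
  f <- kd_hydrophobicity(s, mesh)
  expect_true(all(f$values == 4.5))
  expect_identical(f$kind, "hydrophobicity")
  expect_identical(f$clip_range, c(-4.5, 4.5))
})

test_that("one-residue structures give a constant field via atom_index", {
  dir <- withr::local_tempdir()
  s <- read_pdb(write_pdb_fixture(glycine_atoms(),
                                  file.path(dir, "gly.pdb")))
  mesh <- trimesh3d(rbind(c(0, 2, 0), c(2, 2, 0), c(1, 3, 0)),
                    rbind(c(1, 2, 3)), atom_index = c(1L, 3L, 5L))
  f <- kd_hydrophobicity(s, mesh)
  expect_identical(unique(f$values), -0.4)
})

test_that("unknown residues and distant vertices are diagnosed", {
  dir <- withr::local_tempdir()
  odd <- pdb_atom_row("C1", "LIG", 1, 0, 0, 0, element = "C")
  odd$resid <- "XXX"
  s <- read_pdb(write_pdb_fixture(odd, file.path(dir, "xxx.pdb")))
  mesh <- trimesh3d(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)),
                    rbind(c(1, 2, 3)))
  expect_error(kd_hydrophobicity(s, mesh), "XXX")
  far <- trimesh3d(rbind(c(50, 0, 0), c(51, 0, 0), c(50, 1, 0)),
                   rbind(c(1, 2, 3)))
  expect_error(kd_hydrophobicity(s, far), "no atom within")
})

test_that("the screened Coulomb potential follows q / (4 d^2)", {
  mesh <- trimesh3d(rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)),
                    rbind(c(1, 2, 3)))
  ct <- data.frame(x = 0, y = 0, z = 0, charge = 1)
  dir <- withr::local_tempdir()
  s <- read_pdb(write_pdb_fixture(glycine_atoms(),
                                  file.path(dir, "gly.pdb")))
  f <- coulomb_potential(s, mesh, charge_table = ct)
  expect_equal(f$values, rep(1 / 16, 3))   # epsilon(2) * 2 = 16

  # antisymmetry across the mirror plane of a +/- pair
  mesh2 <- trimesh3d(rbind(c(0, 3, 1), c(0, -3, 1), c(0, 0, 4)),
                     rbind(c(1, 2, 3)))
  pair <- data.frame(x = 0, y = c(3, -3), z = 0, charge = c(1, -1))
  f2 <- coulomb_potential(s, mesh2, charge_table = pair)
  expect_equal(f2$values[1], -f2$values[2], tolerance = 1e-9)
  expect_equal(f2$values[3], 0, tolerance = 1e-9)

  # no charges at all: zero field
  f3 <- coulomb_potential(s, mesh,
                          charge_table = data.frame(x = numeric(0),
                                                    y = numeric(0),
                                                    z = numeric(0),
                                                    charge = numeric(0)))
  expect_true(all(f3$values == 0))
  # a vertex sitting on a charge is rejected
  on_top <- data.frame(x = 2, y = 0, z = 0, charge = 1)
  expect_error(coulomb_potential(s, mesh, charge_table = on_top),
               "coincides")
})

test_that("default formal charges sum per residue as documented", {
  dir <- withr::local_tempdir()
  at <- rbind(pdb_atom_row("N", "ASP", 1, 0, 0, 0, element = "N"),
              pdb_atom_row("OD1", "ASP", 1, 1, 0, 0, element = "O"),
              pdb_atom_row("OD2", "ASP", 1, 2, 0, 0, element = "O"),
              pdb_atom_row("NZ", "LYS", 2, 5, 0, 0, element = "N"),
              pdb_atom_row("O", "LYS", 2, 6, 0, 0, element = "O"))
  s <- read_pdb(write_pdb_fixture(at, file.path(dir, "chg.pdb")))
  ch <- default_charges(s)
  get <- function(resno, atom) ch$charge[ch$resno == resno &
                                           ch$atom %in% atom]
  expect_equal(sum(get(1, c("OD1", "OD2"))), -1)   # Asp side chain
  expect_equal(get(1, "N"), 1)                     # N-terminus
  expect_equal(get(2, "NZ"), 1)                    # Lys side chain
  expect_equal(get(2, "O"), -1)                    # C-terminus, no OXT
})

test_that("DX grids import and interpolate linear fields exactly", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ramp.dx")
  nx <- 4; ny <- 3; nz <- 3
  vals <- numeric(nx * ny * nz)
  i <- 1
  for (ix in 0:(nx - 1)) for (iy in 0:(ny - 1)) for (iz in 0:(nz - 1)) {
    vals[i] <- 2 * ix + 0.5 * iy - iz + 1   # linear ramp in grid coords
    i <- i + 1
  }
  writeLines(c("# test grid",
               sprintf("object 1 class gridpositions counts %d %d %d",
                       nx, ny, nz),
               "origin 0.0 0.0 0.0",
               "delta 1.0 0.0 0.0", "delta 0.0 1.0 0.0",
               "delta 0.0 0.0 1.0",
               sprintf("object 2 class gridconnections counts %d %d %d",
                       nx, ny, nz),
               sprintf("object 3 class array type double rank 0 items %d data follows",
                       nx * ny * nz),
               paste(vals, collapse = " ")), p)
  grid <- load_potential_grid(p)
  mesh <- trimesh3d(rbind(c(0.5, 0.5, 0.5), c(2.25, 1.5, 0.75),
                          c(1, 1, 1)), rbind(c(1, 2, 3)))
  f <- sample_potential(grid, mesh)
  expected <- 2 * mesh$vertices[, 1] + 0.5 * mesh$vertices[, 2] -
    mesh$vertices[, 3] + 1
  expect_equal(f$values, expected, tolerance = 1e-12)

  # constant grid -> constant field
  writeLines(c(sprintf("object 1 class gridpositions counts %d %d %d",
                       2, 2, 2),
               "origin 0 0 0", "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
               "object 3 class array data follows",
               paste(rep(7, 8), collapse = " ")), p)
  inside <- trimesh3d(rbind(c(0.2, 0.2, 0.2), c(0.8, 0.3, 0.4),
                            c(0.5, 0.9, 0.1)), rbind(c(1, 2, 3)))
  fc <- sample_potential(load_potential_grid(p), inside)
  expect_equal(fc$values, rep(7, 3), tolerance = 1e-12)

  # a vertex outside the grid takes the boundary value, with one warning
  out_mesh <- trimesh3d(rbind(c(9, 9, 9), c(0.5, 0.5, 0.5), c(1, 1, 1)),
                        rbind(c(1, 2, 3)))
  expect_warning(fo <- sample_potential(load_potential_grid(p), out_mesh),
                 "1 vertices outside")
  expect_equal(fo$values[1], 7)

  writeLines(c("origin 0 0 0", "delta 1 0 0"), p)
  expect_error(load_potential_grid(p), "malformed DX")
})

test_that("sphere mean curvature approaches 1/R at every vertex", {
  sph <- make_icosphere(3)
  h1 <- mean_curvature(sph)
  expect_true(all(abs(h1$values - 1) < 0.1))
  sph2 <- sph
  sph2$vertices <- 2 * sph2$vertices
  h2 <- mean_curvature(sph2)
  expect_equal(h2$values, h1$values / 2, tolerance = 1e-6)
})

test_that("planar interiors are flat and saddles mix curvature signs", {
  g <- planar_grid_mesh(7, 7)
  h <- mean_curvature(g)
  interior <- !attr(h, "boundary")
  expect_true(any(interior))
  expect_lt(max(abs(h$values[interior])), 1e-6)

  # saddle z = (x^2 - y^2) / 4 on the same grid
  saddle <- g
  saddle$vertices[, 3] <-
    (saddle$vertices[, 1]^2 - saddle$vertices[, 2]^2) / 4
  hs <- mean_curvature(saddle)$values[interior]
  expect_true(any(hs > 1e-4) && any(hs < -1e-4))
})

test_that("inconsistent face orientation is rejected", {
  m <- make_icosphere(1)
  m$faces[1, ] <- m$faces[1, c(2, 1, 3)]   # flip one face
  expect_error(mean_curvature(m), "orientation")
})

test_that("annotation masks mark exactly the listed residues' vertices", {
  dir <- withr::local_tempdir()
  at <- rbind(pdb_atom_row("CA", "ALA", 1, 0, 0, 0, element = "C"),
              pdb_atom_row("CA", "GLY", 2, 4, 0, 0, element = "C"),
              pdb_atom_row("CA", "SER", 3, 8, 0, 0, element = "C"))
  s <- read_pdb(write_pdb_fixture(at, file.path(dir, "tri.pdb")))
  mesh <- trimesh3d(rbind(c(0, 1, 0), c(4, 1, 0), c(8, 1, 0)),
                    rbind(c(1, 2, 3)))

  empty <- annotation_mask(data.frame(chain = character(0),
                                      resno = integer(0)), s, mesh)
  expect_true(all(empty$values == 0))

  all_res <- annotation_mask(data.frame(chain = "A", resno = 1:3), s, mesh)
  expect_true(all(all_res$values == 1))

  one <- annotation_mask(data.frame(chain = "A", resno = 2), s, mesh)
  # brute-force nearest-atom assignment: only vertex 2 is closest to GLY 2
  nearest <- apply(mesh$vertices, 1, function(v)
    which.min(colSums((t(as.matrix(s$atoms[, c("x", "y", "z")])) - v)^2)))
  expect_equal(one$values, as.numeric(nearest == 2))

  expect_warning(annotation_mask(data.frame(chain = "A", resno = 9),
                                 s, mesh), "skipped")
})

test_that("feature fields are invariant to rigid motion of the pair", {
  dir <- withr::local_tempdir()
  s <- read_pdb(write_pdb_fixture(glycine_atoms(),
                                  file.path(dir, "gly.pdb")))
  mesh <- trimesh3d(rbind(c(0, 2, 0), c(2, 2, 0), c(1, 3, 1)),
                    rbind(c(1, 2, 3)))
  f0 <- coulomb_potential(s, mesh)
  # rotate both structure and mesh by 90 degrees about z and translate
  rot <- function(m) cbind(-m[, 2] + 1, m[, 1] - 2, m[, 3] + 3)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- rot(as.matrix(s$atoms[, c("x", "y", "z")]))
  mesh2 <- trimesh3d(rot(mesh$vertices), mesh$faces)
  f1 <- coulomb_potential(s2, mesh2)
  expect_equal(f1$values, f0$values, tolerance = 1e-9)
})
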