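# In-code fixtures shared across the test files.  Everything is generated at
# test time; nothing binary ships with the package.

# Minimal fixed-column PDB writer for hand-built atom tables.
write_pdb_fixture <- function(atoms, path, models = 1) {
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(atoms))) {
      a <- atoms[i, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, a$name, a$alt, a$resid, a$chain, a$resno,
        a$x + if (models > 1) (m - 1) * 100 else 0, a$y, a$z,
        a$occ, 0, a$element))
    }
    if (models > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_row <- function(name, resid, resno, x, y, z, chain = "A",
                         alt = "", occ = 1, element = substr(name, 1, 1)) {
  data.frame(name = name, alt = alt, resid = resid, resno = resno,
             chain = chain, x = x, y = y, z = z, occ = occ,
             element = element, stringsAsFactors = FALSE)
}

# Five-atom glycine backbone fragment.
glycine_atoms <- function() {
  rbind(pdb_atom_row("N", "GLY", 1, 0.0, 0.0, 0.0, element = "N"),
        pdb_atom_row("CA", "GLY", 1, 1.45, 0.0, 0.0, element = "C"),
        pdb_atom_row("C", "GLY", 1, 2.0, 1.4, 0.0, element = "C"),
        pdb_atom_row("O", "GLY", 1, 1.3, 2.4, 0.0, element = "O"),
        pdb_atom_row("OXT", "GLY", 1, 3.2, 1.5, 0.0, element = "O"))
}

# Hand-written MSMS .vert/.face pair for one triangle.
write_triangle_msms <- function(dir, face_index_bad = FALSE) {
  vert <- file.path(dir, "tri.vert")
  face <- file.path(dir, "tri.face")
  writeLines(c("# comment", "# comment",
               "3 1 1.00 1.40",
               "0.000 0.000 0.000 0.0 0.0 1.0 1 1 1",
               "1.000 0.000 0.000 0.0 0.0 1.0 1 2 1",
               "0.000 1.000 0.000 0.0 0.0 1.0 1 1 1"), vert)
  writeLines(c("# comment", "# comment", "1 1 1.00 1.40",
               if (face_index_bad) "1 2 4 1 1" else "1 2 3 1 1"), face)
  c(vert, face)
}

# Planar rectangular grid mesh (checkerboard diagonals), z = 0.
planar_grid_mesh <- function(nx = 6, ny = 6, dx = 1, dy = 1) {
  m <- make_cylinder_patch(radius = 1000, height = (ny - 1) * dy,
                           n_u = nx, n_v = ny,
                           angular_extent = (nx - 1) * dx / 1000,
                           graded = FALSE)
  uv <- attr(m, "uv")
  out <- trimesh3d(cbind(uv[, 1], uv[, 2], 0), m$faces)
  attr(out, "uv") <- uv
  out
}

# Independent set-based Jaccard similarity (oracle for tanimoto()).
jaccard_sets <- function(x, y) {
  a <- which(as.logical(x))
  b <- which(as.logical(y))
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# Independent all-pairs shortest paths (Floyd-Warshall) over an explicit
# weighted edge list; oracle for the Dijkstra-based geodesics.
floyd_warshall <- function(n, edges, weights) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    d[i, j] <- d[j, i] <- min(d[i, j], weights[e])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    dk <- d[i, k] + d[k, ]
    upd <- dk < d[i, ]
    d[i, upd] <- dk[upd]
  }
  d
}

# Procrustes residual after optimal orthogonal alignment (rotation and
# reflection, no scaling) of configuration a onto b.
procrustes_residual <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  s <- svd(crossprod(a, b))
  rot <- s$u %*% t(s$v)
  sqrt(sum((b - a %*% rot)^2) / nrow(a))
}
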