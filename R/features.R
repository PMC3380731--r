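#' Per-vertex scalar feature channel
#'
#' One surface channel: hydrophobicity (Kyte-Doolittle units), electrostatic
#' potential (charge units / Angstrom under the screened-Coulomb model, or
#' the imported grid's own units), signed mean curvature (1/Angstrom), or a
#' 0/1 annotation mask.  `clip_range` is the display normalization window
#' used when the channel is rasterized.
#'
#' @param values numeric vector, one finite value per vertex.
#' @param kind channel tag (`"hydrophobicity"`, `"potential"`,
#'   `"curvature"`, `"mask"`, ...).
#' @param clip_range length-2 numeric; defaults per kind (see Details).
#' @details Default clip ranges: hydrophobicity `[-4.5, 4.5]` (the full
#'   Kyte-Doolittle span); potential and curvature symmetric about zero at
#'   the 95th percentile of the absolute values; mask `[0, 1]`; otherwise
#'   the data range.
#' @return object of class `feature_field`.
#' @export
feature_field <- function(values, kind, clip_range = NULL) {
  values <- as.numeric(values)
  if (length(values) && !all(is.finite(values)))
    stop("feature values must be finite", call. = FALSE)
  if (is.null(clip_range)) {
    clip_range <- switch(kind,
      hydrophobicity = c(-4.5, 4.5),
      potential = ,
      curvature = {
        m <- stats::quantile(abs(values), 0.95, names = FALSE)
        if (m == 0) m <- 1
        c(-m, m)
      },
      mask = c(0, 1),
      range(values))
    if (clip_range[1] == clip_range[2]) clip_range <- clip_range + c(-1, 1)
  }
  structure(list(values = values, kind = kind,
                 clip_range = as.numeric(clip_range)),
            class = "feature_field")
}

#' @export
print.feature_field <- function(x, ...) {
  cat(sprintf("<feature_field> %s, %d vertices, range [%.3g, %.3g], clip [%.3g, %.3g]\n",
              x$kind, length(x$values), min(x$values), max(x$values),
              x$clip_range[1], x$clip_range[2]))
  invisible(x)
}

# Kyte-Doolittle hydropathy index, one value per standard residue.
kyte_doolittle_scale <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

# Index of the atom owning each vertex: the MSMS atom_index when present,
# otherwise a nearest-atom search with a cutoff (Angstrom).
nearest_atoms <- function(structure, mesh, cutoff = 5) {
  n <- n_vertices(mesh)
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  if (!is.null(mesh$atom_index)) {
    idx <- mesh$atom_index
    if (any(idx < 1 | idx > nrow(xyz)))
      stop("mesh atom_index outside the structure's atom range", call. = FALSE)
    return(idx)
  }
  idx <- integer(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - mesh$vertices[i, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > cutoff)
      stop("vertex ", i, " has no atom within ", cutoff, " Angstrom",
           call. = FALSE)
    idx[i] <- j
  }
  idx
}

#' Kyte-Doolittle hydrophobicity channel
#'
#' Each surface vertex inherits the Kyte-Doolittle hydropathy index of the
#' residue owning its nearest atom (the MSMS `atom_index` when the mesh
#' carries one, else a nearest-atom search).  Values span `[-4.5, 4.5]`
#' (Arg to Ile).
#'
#' @param structure a `pdb_structure` from [read_pdb()].
#' @param mesh a [trimesh3d] of that structure's surface.
#' @param cutoff nearest-atom search cutoff (Angstrom) when the mesh has no
#'   `atom_index`.
#' @return a [feature_field] of kind `"hydrophobicity"`.
#' @export
kd_hydrophobicity <- function(structure, mesh, cutoff = 5) {
  idx <- nearest_atoms(structure, mesh, cutoff)
  res <- toupper(structure$atoms$resid[idx])
  unknown <- setdiff(unique(res), names(kyte_doolittle_scale))
  if (length(unknown))
    stop("no Kyte-Doolittle value for residue(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  feature_field(unname(kyte_doolittle_scale[res]), "hydrophobicity")
}

#' Default formal charges for a structure
#'
#' Formal-charge assignment at neutral pH, split across chemically
#' equivalent atoms: Asp OD1/OD2 and Glu OE1/OE2 -0.5 each, Lys NZ +1,
#' Arg NH1/NH2 +0.5 each, His ND1/NE2 +0.05 each, the N-terminal N +1 and
#' the C-terminal OXT (or O when OXT is absent) -1.
#'
#' @param structure a `pdb_structure`.
#' @return data frame with columns `chain`, `resno`, `atom`, `charge`,
#'   `x`, `y`, `z` (only atoms with nonzero charge).
#' @export
default_charges <- function(structure) {
  at <- structure$atoms
  q <- numeric(nrow(at))
  res <- toupper(at$resid)
  q[res == "ASP" & at$atom %in% c("OD1", "OD2")] <- -0.5
  q[res == "GLU" & at$atom %in% c("OE1", "OE2")] <- -0.5
  q[res == "LYS" & at$atom == "NZ"] <- 1
  q[res == "ARG" & at$atom %in% c("NH1", "NH2")] <- 0.5
  q[res == "HIS" & at$atom %in% c("ND1", "NE2")] <- 0.05
  for (ch in unique(at$chain)) {
    rows <- which(at$chain == ch)
    first_res <- at$resno[rows[1]]
    q[rows[at$resno[rows] == first_res & at$atom[rows] == "N"]] <- 1
    last_res <- at$resno[rows[length(rows)]]
    lr <- rows[at$resno[rows] == last_res]
    if (any(at$atom[lr] == "OXT")) {
      q[lr[at$atom[lr] == "OXT"]] <- -1
    } else {
      q[lr[at$atom[lr] == "O"]] <- -1
    }
  }
  keep <- q != 0
  data.frame(chain = at$chain[keep], resno = at$resno[keep],
             atom = at$atom[keep], charge = q[keep],
             x = at$x[keep], y = at$y[keep], z = at$z[keep],
             stringsAsFactors = FALSE)
}

#' Screened-Coulomb electrostatic potential channel
#'
#' Coulombic approximation with a distance-dependent dielectric
#' `epsilon(d) = 4 d`:
#' \deqn{\phi(v) = \sum_i \frac{q_i}{\epsilon(d_i)\, d_i}
#'   = \sum_i \frac{q_i}{4 d_i^2}}{phi(v) = sum q_i / (4 d_i^2)}
#' summed over charged atoms, with distances floored at `min_dist` to guard
#' malformed inputs (surface vertices normally sit about a probe radius
#' from any atom).  A Poisson-Boltzmann potential solved externally can be
#' used instead via [load_potential_grid()] + [sample_potential()].
#'
#' @inheritParams kd_hydrophobicity
#' @param charge_table optional data frame with columns `x`, `y`, `z`,
#'   `charge` (e.g. an edited [default_charges()] table, or one read from a
#'   TSV); defaults to `default_charges(structure)`.
#' @param min_dist distance floor (Angstrom).
#' @return a [feature_field] of kind `"potential"` (charge units / Angstrom).
#' @export
coulomb_potential <- function(structure, mesh, charge_table = NULL,
                              min_dist = 1.0) {
  if (is.null(charge_table)) charge_table <- default_charges(structure)
  n <- n_vertices(mesh)
  if (nrow(charge_table) == 0)
    return(feature_field(numeric(n), "potential", clip_range = c(-1, 1)))
  cq <- as.matrix(charge_table[, c("x", "y", "z")])
  q <- charge_table$charge
  phi <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(cq) - mesh$vertices[i, ])^2))
    if (any(d == 0))
      stop("vertex ", i, " coincides with a charge", call. = FALSE)
    d <- pmax(d, min_dist)
    phi[i] <- sum(q / (4 * d^2))
  }
  feature_field(phi, "potential")
}

#' Import an externally solved potential grid (OpenDX)
#'
#' Reads the OpenDX scalar-grid format written by common Poisson-Boltzmann
#' solvers.  Values are stored with the z index varying fastest, per the
#' format.
#'
#' @param dx_path path to a `.dx` file.
#' @return object of class `dx_grid`: list with `origin`, `delta`, `counts`
#'   and the flat `values` vector.
#' @export
load_potential_grid <- function(dx_path) {
  lines <- readLines(dx_path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  gp <- grep("object.*gridpositions.*counts", lines, value = TRUE)
  if (length(gp) == 0) stop("malformed DX header: no gridpositions object",
                            call. = FALSE)
  counts <- as.integer(tail(strsplit(trimws(gp[1]), "[[:space:]]+")[[1]], 3))
  org <- grep("^origin", trimws(lines), value = TRUE)
  if (length(org) == 0) stop("malformed DX header: no origin", call. = FALSE)
  origin <- as.numeric(strsplit(trimws(org[1]), "[[:space:]]+")[[1]][2:4])
  dl <- grep("^delta", trimws(lines), value = TRUE)
  if (length(dl) < 3) stop("malformed DX header: need 3 delta lines",
                           call. = FALSE)
  deltas <- t(vapply(dl[1:3], function(s)
    as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]][2:4]), numeric(3)))
  delta <- diag(deltas)
  if (any(delta <= 0) || anyNA(counts) || anyNA(origin))
    stop("malformed DX header", call. = FALSE)
  data_start <- grep("data follows", lines)
  if (length(data_start) == 0)
    stop("malformed DX header: no data section", call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[(data_start[1] + 1):length(lines)]),
             "[[:space:]]+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < prod(counts))
    stop("DX data section has ", length(vals), " values, expected ",
         prod(counts), call. = FALSE)
  structure(list(origin = origin, delta = delta, counts = counts,
                 values = vals[seq_len(prod(counts))]),
            class = "dx_grid")
}

#' @rdname load_potential_grid
#' @param grid a `dx_grid`.
#' @param mesh a [trimesh3d].
#' @return `sample_potential()`: a [feature_field] of kind `"potential"`
#'   holding the trilinear interpolation of the grid at each vertex;
#'   vertices outside the grid take the nearest boundary value (one warning
#'   reports how many).
#' @export
sample_potential <- function(grid, mesh) {
  nxyz <- grid$counts
  # fractional grid coordinates, 0-based
  t3 <- sweep(sweep(mesh$vertices, 2, grid$origin), 2, grid$delta, "/")
  outside <- rowSums(t3 < 0 | t3 > rep(nxyz - 1, each = nrow(t3))) > 0
  if (any(outside))
    warning(sum(outside), " vertices outside the potential grid; ",
            "boundary values used", call. = FALSE)
  t3 <- pmin(pmax(t3, 0), rep(nxyz - 1, each = nrow(t3)))
  i0 <- pmin(floor(t3), rep(nxyz - 2, each = nrow(t3)))
  fr <- t3 - i0
  val_at <- function(ix, iy, iz)                      # 0-based indices
    grid$values[(ix * nxyz[2] + iy) * nxyz[3] + iz + 1]
  v <- numeric(nrow(t3))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    v <- v + w * val_at(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
  }
  feature_field(v, "potential")
}

#' Discrete mean curvature channel
#'
#' Mean curvature from the cotangent Laplace-Beltrami operator:
#' `H(v) = sign * |L v| / 2` per vertex area (Meyer's mixed Voronoi area),
#' with the sign positive where the mean-curvature vector opposes the
#' outward vertex normal (convex bumps) and negative in concavities, so a
#' unit sphere with outward-oriented faces scores +1 everywhere.  Boundary
#' vertices of open sections have no well-defined Laplacian and are assigned
#' the average of their interior neighbors (flagged in the attribute
#' `"boundary"`).
#'
#' @param mesh a [trimesh3d] with consistently oriented faces.
#' @return a [feature_field] of kind `"curvature"` (1/Angstrom).
#' @export
mean_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  # orientation check: each directed edge at most once
  dir_edges <- rbind(f[, 1:2, drop = FALSE], f[, 2:3, drop = FALSE],
                     f[, c(3, 1), drop = FALSE])
  if (anyDuplicated(dir_edges))
    stop("inconsistent face orientation: a directed edge occurs twice",
         call. = FALSE)
  undirected <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                      pmax(dir_edges[, 1], dir_edges[, 2]))
  boundary_edge <- !(undirected %in% undirected[duplicated(undirected)])
  boundary_vertex <- rep(FALSE, n)
  boundary_vertex[unique(as.vector(dir_edges[boundary_edge, ]))] <- TRUE

  cot3 <- function(a, b, c) {    # cotangent of the angle at a
    u <- v[b, ] - v[a, ]; w <- v[c, ] - v[a, ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    sum(u * w) / max(sqrt(sum(cr^2)), 1e-300)
  }
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  areas <- triangle_areas(v, f)
  varea <- numeric(n)
  fnorm <- matrix(0, nrow(f), 3)
  edge2 <- function(a, b) sum((v[a, ] - v[b, ])^2)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ca <- cot3(a, b, c); cb <- cot3(b, c, a); cc <- cot3(c, a, b)
    # mixed Voronoi area (Meyer et al.): true Voronoi part for non-obtuse
    # triangles, area/2 at the obtuse corner and area/4 elsewhere otherwise
    if (ca > 0 && cb > 0 && cc > 0) {
      varea[a] <- varea[a] + (edge2(a, b) * cc + edge2(a, c) * cb) / 8
      varea[b] <- varea[b] + (edge2(b, a) * cc + edge2(b, c) * ca) / 8
      varea[c] <- varea[c] + (edge2(c, a) * cb + edge2(c, b) * ca) / 8
    } else {
      obtuse <- c(ca, cb, cc) <= 0
      varea[c(a, b, c)] <- varea[c(a, b, c)] +
        areas[t] * ifelse(obtuse, 1 / 2, 1 / 4)
    }
    ii <- c(ii, b, c, c, a, a, b)
    jj <- c(jj, c, b, a, c, b, a)
    ww <- c(ww, ca, ca, cb, cb, cc, cc)
    u <- v[b, ] - v[a, ]; w2 <- v[c, ] - v[a, ]
    fnorm[t, ] <- c(u[2] * w2[3] - u[3] * w2[2], u[3] * w2[1] - u[1] * w2[3],
                    u[1] * w2[2] - u[2] * w2[1])
  }
  w_mat <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  lap <- as.matrix(w_mat %*% v) - Matrix::rowSums(w_mat) * v  # sum w_ij (v_j - v_i)
  lap <- lap / (2 * pmax(varea, 1e-300))
  # outward vertex normals (area-weighted face normals)
  vnorm <- matrix(0, n, 3)
  for (t in seq_len(nrow(f)))
    vnorm[f[t, ], ] <- vnorm[f[t, ], ] + rep(fnorm[t, ], each = 3)
  h <- sqrt(rowSums(lap^2)) / 2
  concave <- rowSums(lap * vnorm) > 0   # Laplacian points along outward normal
  h[concave] <- -h[concave]
  # boundary vertices: one-ring average over interior neighbors
  if (any(boundary_vertex)) {
    adj <- mesh_edges(mesh)
    for (b in which(boundary_vertex)) {
      nb <- c(adj[adj[, 1] == b, 2], adj[adj[, 2] == b, 1])
      nb <- nb[!boundary_vertex[nb]]
      h[b] <- if (length(nb)) mean(h[nb]) else 0
    }
  }
  out <- feature_field(h, "curvature")
  attr(out, "boundary") <- boundary_vertex
  out
}

#' Residue annotation mask channel
#'
#' Marks the surface patch belonging to a residue list (e.g. an active site
#' exported from a curated database): vertices whose nearest atom belongs to
#' a listed residue get 1, all others 0.  Listed residues absent from the
#' structure are skipped with a warning.
#'
#' @param residue_list data frame with columns `chain` and `resno`, or a
#'   path readable by [read_residue_list()].
#' @inheritParams kd_hydrophobicity
#' @return a [feature_field] of kind `"mask"`.
#' @export
annotation_mask <- function(residue_list, structure, mesh, cutoff = 5) {
  if (is.character(residue_list))
    residue_list <- read_residue_list(residue_list)
  at <- structure$atoms
  have <- paste(at$chain, at$resno)
  want <- paste(residue_list$chain, residue_list$resno)
  missing <- setdiff(want, have)
  if (length(missing))
    warning("residues not in structure, skipped: ",
            paste(missing, collapse = "; "), call. = FALSE)
  idx <- nearest_atoms(structure, mesh, cutoff)
  feature_field(as.numeric(have[idx] %in% want), "mask")
}
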