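#' Read an MSMS triangulated surface
#'
#' Parses the paired `.vert`/`.face` files written by MSMS.  Vertex records
#' carry six floats (position, then outward normal) followed by integer
#' fields whose layout varies across MSMS versions; the second trailing
#' integer is the 1-based index of the nearest atom (sphere) and is stored as
#' `atom_index`, extra columns being tolerated.  Face records carry three
#' 1-based vertex indices.  Leading `#` comment lines and the count header
#' line are skipped; if the header's counts disagree with the records
#' actually present, the records are trusted and a warning emitted.
#'
#' @param vert_path path to the `.vert` file.
#' @param face_path path to the `.face` file.
#' @return a [trimesh3d] with `normals` and (when present) `atom_index`.
#' @export
read_msms <- function(vert_path, face_path) {
  vrec <- msms_records(vert_path, min_fields = 6L)
  if (length(vrec) == 0) stop("no vertex records in ", vert_path,
                              call. = FALSE)
  vmat <- t(vapply(vrec, function(tok) as.numeric(tok[1:6]), numeric(6)))
  if (anyNA(vmat))
    stop("malformed vertex record in ", vert_path, call. = FALSE)
  atom_index <- vapply(vrec, function(tok) {
    trail <- suppressWarnings(as.integer(tok[-(1:6)]))
    trail <- trail[!is.na(trail)]
    if (length(trail) >= 2) trail[2] else if (length(trail) == 1) trail[1]
    else NA_integer_
  }, integer(1))
  if (all(is.na(atom_index))) atom_index <- NULL

  frec <- msms_records(face_path, min_fields = 3L, integer_records = TRUE)
  if (length(frec) == 0) stop("no face records in ", face_path, call. = FALSE)
  fmat <- t(vapply(frec, function(tok)
    suppressWarnings(as.integer(tok[1:3])), integer(3)))
  bad <- which(apply(fmat, 1, function(r)
    anyNA(r) || any(r < 1) || any(r > nrow(vmat))))
  if (length(bad))
    stop("face record ", bad[1], " of ", face_path,
         " references a vertex outside [1, ", nrow(vmat), "]", call. = FALSE)
  check_msms_header(vert_path, length(vrec), "vertex")
  check_msms_header(face_path, length(frec), "face")
  trimesh3d(vmat[, 1:3, drop = FALSE], fmat,
            atom_index = atom_index,
            normals = vmat[, 4:6, drop = FALSE])
}

# Tokenized data records of an MSMS file: '#' comments dropped, and the
# leading count-header line split off.  A line is the header when it is too
# short to be a record or (for the all-integer face records) when it carries
# decimal fields like the density/probe-radius columns.  The header token
# vector is attached as attribute "header".
msms_records <- function(path, min_fields, integer_records = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  header <- NULL
  if (length(toks) &&
        (length(toks[[1]]) < min_fields ||
           (integer_records && any(grepl("[.]", toks[[1]]))))) {
    header <- toks[[1]]
    toks <- toks[-1]
  }
  structure(toks, header = header)
}

check_msms_header <- function(path, n_records, what) {
  rec <- msms_records(path, min_fields = if (what == "vertex") 6L else 3L,
                      integer_records = what == "face")
  header <- attr(rec, "header")
  if (!is.null(header)) {
    declared <- suppressWarnings(as.integer(header[1]))
    if (!is.na(declared) && declared != n_records)
      warning(path, ": header declares ", declared, " ", what,
              " records but ", n_records, " found; trusting the records",
              call. = FALSE)
  }
  invisible(NULL)
}

#' Write a mesh as an MSMS `.vert`/`.face` pair
#'
#' Inverse of [read_msms()]: coordinates and normals at three decimals,
#' 1-based face indices.  Missing normals are written as zeros; missing atom
#' indices as zero.
#'
#' @param mesh a [trimesh3d].
#' @inheritParams read_msms
#' @return the two paths, invisibly.
#' @export
write_msms <- function(mesh, vert_path, face_path) {
  n <- n_vertices(mesh)
  nm <- if (is.null(mesh$normals)) matrix(0, n, 3) else mesh$normals
  ai <- if (is.null(mesh$atom_index)) rep(0L, n) else mesh$atom_index
  vlines <- c("# MSMS surface written by molcart",
              sprintf("%d %d %.2f %.2f", n, max(ai, 1L), 1.0, 1.4),
              sprintf("%9.3f %9.3f %9.3f %9.3f %9.3f %9.3f %7d %7d %2d",
                      mesh$vertices[, 1], mesh$vertices[, 2],
                      mesh$vertices[, 3], nm[, 1], nm[, 2], nm[, 3],
                      seq_len(n), ai, 1L))
  writeLines(vlines, vert_path)
  f <- mesh$faces
  flines <- c("# MSMS surface written by molcart",
              sprintf("%d %d %.2f %.2f", nrow(f), max(ai, 1L), 1.0, 1.4),
              sprintf("%7d %7d %7d %2d %7d", f[, 1], f[, 2], f[, 3], 1L,
                      seq_len(nrow(f))))
  writeLines(flines, face_path)
  invisible(c(vert_path, face_path))
}

#' Read a PDB structure
#'
#' Thin wrapper around [bio3d::read.pdb()] producing the flat atom table the
#' feature routines consume.  Only the first MODEL is used; for alternate
#' locations the highest-occupancy conformer is kept (ties to the
#' alphabetically first altloc).  HETATM records (waters, ligands) are
#' excluded by default since they would distort residue-based surface
#' properties.
#'
#' @param path path to a PDB file.
#' @param include_hetatm also keep HETATM records.
#' @return object of class `pdb_structure`: list with `atoms`, a data frame
#'   with columns `element`, `atom`, `resid`, `resno`, `chain`, `x`, `y`,
#'   `z`, `occupancy`, `type`.
#' @export
read_pdb <- function(path, include_hetatm = FALSE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  # altloc policy: keep the highest-occupancy conformer per atom site
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  at$o[is.na(at$o)] <- 1
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]
  atoms <- data.frame(element = at$elesy, atom = at$elety, resid = at$resid,
                      resno = at$resno, chain = at$chain,
                      x = at$x, y = at$y, z = at$z,
                      occupancy = at$o, type = at$type,
                      stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in ", path, call. = FALSE)
  structure(list(atoms = atoms, path = path), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %d atoms, %d residues\n", nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Write a mesh as ASCII PLY
#'
#' Exports vertices (optionally with 8-bit RGB colors) and the triangle
#' list, 0-based per the PLY convention.  Viewers interpolate the vertex
#' colors across each triangle, which is how textured surfaces are
#' displayed.
#'
#' @param mesh a [trimesh3d].
#' @param vertex_colors optional `n x 3` RGB matrix in 0..255; defaults to
#'   the mesh's own `colors` slot when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, vertex_colors = NULL, path) {
  if (is.null(vertex_colors)) vertex_colors <- mesh$colors
  n <- n_vertices(mesh)
  if (!is.null(vertex_colors))
    vertex_colors <- check_vertex_colors(vertex_colors, n)
  header <- c("ply", "format ascii 1.0",
              "comment written by molcart",
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              if (!is.null(vertex_colors))
                c("property uchar red", "property uchar green",
                  "property uchar blue"),
              sprintf("element face %d", n_faces(mesh)),
              "property list uchar int vertex_indices",
              "end_header")
  v <- mesh$vertices
  vlines <- if (is.null(vertex_colors)) {
    sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
  } else {
    sprintf("%.6f %.6f %.6f %d %d %d", v[, 1], v[, 2], v[, 3],
            vertex_colors[, 1], vertex_colors[, 2], vertex_colors[, 3])
  }
  f <- mesh$faces - 1L
  flines <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' Minimal reader for the files [write_ply()] produces (and other ASCII PLY
#' with leading x/y/z float properties): returns the mesh with colors when
#' red/green/blue uchar properties are present.
#'
#' @param path path to an ASCII PLY file.
#' @return a [trimesh3d].
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || lines[1] != "ply" ||
        !grepl("^format ascii", lines[2]))
    stop("not an ASCII PLY file: ", path, call. = FALSE)
  endh <- match("end_header", lines)
  header <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ",
                                                   header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header,
                                                 value = TRUE)))
  has_color <- any(grepl("^property uchar red", header))
  body <- lines[(endh + 1):length(lines)]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "[[:space:]]+")
  vmat <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  colors <- NULL
  if (has_color)
    colors <- t(vapply(vtok, function(t) as.integer(t[4:6]), integer(3)))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "[[:space:]]+")
  fmat <- t(vapply(ftok, function(t) as.integer(t[2:4]), integer(3))) + 1L
  trimesh3d(vmat, fmat, colors = colors)
}

#' Read a residue annotation list
#'
#' Plain-text active-site (or other) annotation: one `chain residue_number`
#' pair per line, `#` comments allowed.
#'
#' @param path path to the list file.
#' @return data frame with columns `chain` and `resno`.
#' @export
read_residue_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(chain = character(0), resno = integer(0)))
  toks <- strsplit(lines, "[[:space:]]+")
  data.frame(chain = vapply(toks, `[`, "", 1),
             resno = as.integer(vapply(toks, `[`, "", 2)),
             stringsAsFactors = FALSE)
}
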