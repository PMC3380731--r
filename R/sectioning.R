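#' Bisect a surface into six half-sections
#'
#' An enclosed surface cannot be flattened without collapse, so the workflow
#' cuts it once by each coordinate plane, producing six open half-sections
#' labeled `+x, -x, +y, -y, +z, -z`.  Each section is [cut_halfspace()] with
#' the given origin; opposing sections may share the boundary ring of
#' vertices lying exactly on the cutting plane, while faces straddling a
#' plane belong to neither of its two sections.
#'
#' @param mesh a [trimesh3d].
#' @param origin cutting-plane origin: the vertex centroid (default,
#'   translation invariant), the string `"coordinate"` for the raw coordinate
#'   origin `c(0,0,0)`, or any 3-D point.
#' @return named list of six [trimesh3d] sections.  An empty half-space
#'   yields a warning naming the label and an empty mesh for that slot.
#' @examples
#' secs <- bisect_by_planes(make_icosphere(1))
#' vapply(secs, n_faces, integer(1))
#' @export
bisect_by_planes <- function(mesh, origin = NULL) {
  if (identical(origin, "coordinate")) origin <- c(0, 0, 0)
  if (is.null(origin)) origin <- mesh_centroid(mesh)
  labels <- c("+x", "-x", "+y", "-y", "+z", "-z")
  out <- lapply(labels, function(lab) {
    sgn <- substr(lab, 1, 1)
    ax <- substr(lab, 2, 2)
    tryCatch(cut_halfspace(mesh, ax, sgn, origin = origin),
             error = function(e) {
               warning("section ", lab, " is empty", call. = FALSE)
               trimesh3d(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3))
             })
  })
  names(out) <- labels
  out
}
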