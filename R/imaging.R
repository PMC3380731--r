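#' Multi-channel raster of a surface map
#'
#' `surface_image()` wraps an `H x W x C` pixel array (8-bit values, 0..255)
#' with named channel semantics, a coverage mask (which pixels any splat
#' touched), and the affine transform from 2-D map coordinates to pixel
#' indices (`col = sx * x + ox`, `row = oy - sx * y`; one isotropic scale,
#' so aspect is preserved).
#'
#' @param pixels numeric `H x W x C` array in 0..255 (NA where uncovered).
#' @param channels character vector of C channel tags.
#' @param transform list with `scale`, `offset_col`, `offset_row`, or `NULL`
#'   for images with no map frame (plain imported PNGs).
#' @param coverage logical `H x W` matrix; defaults to non-NA pixels.
#' @return object of class `surface_image`.
#' @export
surface_image <- function(pixels, channels, transform = NULL,
                          coverage = NULL) {
  if (length(dim(pixels)) == 2) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3)
    stop("pixels must be an H x W x C array", call. = FALSE)
  if (length(channels) != dim(pixels)[3])
    stop("channel semantics (", length(channels),
         ") do not match the pixel array's ", dim(pixels)[3], " channels",
         call. = FALSE)
  if (is.null(coverage)) coverage <- !is.na(pixels[, , 1])
  structure(list(pixels = pixels, channels = channels,
                 transform = transform, coverage = coverage),
            class = "surface_image")
}

#' @export
print.surface_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<surface_image> %d x %d, channels: %s (%.0f%% covered)\n",
              d[1], d[2], paste(x$channels, collapse = ","),
              100 * mean(x$coverage)))
  invisible(x)
}

map_to_pixel <- function(image, xy) {
  tr <- image$transform
  if (is.null(tr)) stop("image has no map-coordinate transform", call. = FALSE)
  cbind(row = tr$offset_row - tr$scale * xy[, 2],
        col = tr$scale * xy[, 1] + tr$offset_col)
}

# Fit a square raster frame around an embedding: isotropic scale, 5% margin
# each side, map bbox centered.
fit_transform <- function(coords, resolution) {
  ext <- apply(coords, 2, range)
  span <- pmax(ext[2, ] - ext[1, ], 1e-12)
  if (nrow(coords) == 1) span <- c(1, 1)   # lone vertex: unit scale, centered
  if (max(span) < 1e-9) stop("zero-extent embedding", call. = FALSE)
  usable <- 0.9 * (resolution - 1)
  s <- usable / max(span)
  center <- colMeans(ext)
  mid <- (resolution + 1) / 2
  list(scale = s, offset_col = mid - s * center[1],
       offset_row = mid + s * center[2])
}

#' Rasterize an enriched 2-D map
#'
#' Fits the map's bounding box into a square raster (5% margin, aspect
#' preserved) and splats every vertex as a disc of `splat_radius` pixels;
#' where splats overlap, each pixel keeps the vertex whose map position is
#' nearest.  Each feature channel is normalized to 0..255 over its
#' `clip_range`, so the color assigned to a vertex does not depend on the
#' raster resolution.  A plain `n x C` matrix of 0..255 values (e.g. RGB
#' colors) may be passed instead of feature fields and is splatted without
#' normalization.
#'
#' @param emb an [embedding2d].
#' @param fields a [feature_field], a list of up to 3 of them, or an
#'   `n x C` numeric matrix of raw 0..255 channel values.
#' @param resolution raster side length in pixels (>= 16).
#' @param splat_radius splat disc radius in pixels.
#' @return a [surface_image]; the owning vertex of each pixel is attached
#'   as the integer matrix attribute `"owner"` (0 = empty).
#' @export
rasterize <- function(emb, fields, resolution = 256, splat_radius = 2) {
  stopifnot(inherits(emb, "embedding2d"))
  if (resolution < 16) stop("resolution must be >= 16", call. = FALSE)
  n <- nrow(emb$coords)
  if (inherits(fields, "feature_field")) fields <- list(fields)
  if (is.list(fields)) {
    if (length(fields) < 1 || length(fields) > 3)
      stop("between 1 and 3 feature fields", call. = FALSE)
    values <- vapply(fields, function(f) {
      stopifnot(inherits(f, "feature_field"))
      if (length(f$values) != n)
        stop("feature field not aligned with the embedding", call. = FALSE)
      cr <- f$clip_range
      v <- pmin(pmax(f$values, cr[1]), cr[2])
      round(255 * (v - cr[1]) / (cr[2] - cr[1]))
    }, numeric(n))
    channels <- vapply(fields, `[[`, "", "kind")
  } else {
    values <- as.matrix(fields)
    if (nrow(values) != n)
      stop("channel matrix not aligned with the embedding", call. = FALSE)
    if (anyNA(values) || any(values < 0) || any(values > 255))
      stop("raw channel values must lie in [0, 255]", call. = FALSE)
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  }
  values <- matrix(values, nrow = n)

  tr <- fit_transform(emb$coords, resolution)
  px <- map_to_pixel(surface_image(array(NA_real_,
                                         c(resolution, resolution, 1)),
                                   "tmp", tr), emb$coords)
  owner <- matrix(0L, resolution, resolution)
  bestd2 <- matrix(Inf, resolution, resolution)
  offs <- expand.grid(dr = -splat_radius:splat_radius,
                      dc = -splat_radius:splat_radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= splat_radius^2, , drop = FALSE]
  for (v in seq_len(n)) {
    r0 <- round(px[v, "row"]); c0 <- round(px[v, "col"])
    rr <- r0 + offs$dr; cc <- c0 + offs$dc
    ok <- rr >= 1 & rr <= resolution & cc >= 1 & cc <= resolution
    rr <- rr[ok]; cc <- cc[ok]
    d2 <- (rr - px[v, "row"])^2 + (cc - px[v, "col"])^2
    lin <- cbind(rr, cc)
    closer <- d2 < bestd2[lin]
    if (any(closer)) {
      lin <- lin[closer, , drop = FALSE]
      owner[lin] <- v
      bestd2[lin] <- d2[closer]
    }
  }
  pix <- array(NA_real_, c(resolution, resolution, ncol(values)))
  cov <- owner > 0L
  for (ch in seq_len(ncol(values))) {
    plane <- matrix(NA_real_, resolution, resolution)
    plane[cov] <- values[owner[cov], ch]
    pix[, , ch] <- plane
  }
  out <- surface_image(pix, channels, transform = tr, coverage = cov)
  attr(out, "owner") <- owner
  out
}

#' Read and write surface images as PNG
#'
#' Lossless 8-bit round trip via the png package.  Uncovered pixels are
#' written as zero with a zero alpha channel; on reading, an alpha channel
#' (when present) is converted back into the coverage mask.  Two-channel
#' images are padded with a zero third channel on writing.
#'
#' @param image a [surface_image].
#' @param path file path.
#' @return `write_png()` returns `path` invisibly; `read_png()` a
#'   [surface_image] (with no map transform).
#' @export
write_png <- function(image, path) {
  pix <- image$pixels
  d <- dim(pix)
  if (d[3] == 2) {
    pix <- array(c(pix, matrix(0, d[1], d[2])), c(d[1], d[2], 3))
    d <- dim(pix)
  }
  if (!d[3] %in% c(1, 3))
    stop("PNG export supports 1- or 3-channel images", call. = FALSE)
  pix[is.na(pix)] <- 0
  arr <- pix / 255
  if (!all(image$coverage)) {
    alpha <- ifelse(image$coverage, 1, 0)
    arr <- if (d[3] == 1) array(c(arr, arr, arr, alpha), c(d[1], d[2], 4))
           else array(c(arr, alpha), c(d[1], d[2], 4))
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  nc <- dim(arr)[3]
  coverage <- NULL
  if (nc %in% c(2, 4)) {           # strip alpha into the coverage mask
    coverage <- arr[, , nc] > 0
    arr <- arr[, , -nc, drop = FALSE]
    nc <- nc - 1L
  }
  pix <- round(arr * 255)
  channels <- switch(as.character(nc), "1" = "gray", "3" = c("R", "G", "B"),
                     paste0("ch", seq_len(nc)))
  if (is.null(coverage)) coverage <- matrix(TRUE, dim(pix)[1], dim(pix)[2])
  pix[array(!coverage, dim(pix))] <- NA
  surface_image(pix, channels, transform = NULL, coverage = coverage)
}

#' Rigid transform between two surface images
#'
#' @param rotation rotation angle in radians (counter-clockwise).
#' @param translation length-2 pixel translation `(row, col)`.
#' @param reflected whether a left-right reflection precedes the rotation.
#' @param score normalized cross-correlation at the optimum.
#' @return object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(rotation = 0, translation = c(0, 0),
                              reflected = FALSE, score = NA_real_) {
  structure(list(rotation = rotation, translation = translation,
                 reflected = reflected, score = score),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> rot %.1f deg, shift (%+.0f, %+.0f)%s, NCC %.3f\n",
              x$rotation * 180 / pi, x$translation[1], x$translation[2],
              if (x$reflected) ", reflected" else "", x$score))
  invisible(x)
}

gray_of <- function(image) {
  g <- apply(image$pixels, c(1, 2), mean)
  g[!image$coverage] <- 0
  list(g = g, m = image$coverage * 1)
}

# Rotate (and optionally reflect) a masked grayscale image about its center
# by nearest-neighbor inverse mapping, into a canvas large enough to hold
# any rotation.
rotate_masked <- function(g, m, theta, reflect = FALSE) {
  h <- nrow(g); w <- ncol(g)
  side <- ceiling(sqrt(h^2 + w^2))
  ctr_out <- (side + 1) / 2
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  rc <- expand.grid(r = seq_len(side), c = seq_len(side))
  dy <- rc$r - ctr_out; dx <- rc$c - ctr_out
  # inverse rotation back into source coordinates (image rows grow downward)
  cs <- cos(theta); sn <- sin(theta)
  sr <- cs * dy - sn * dx + ctr[1]
  sc <- sn * dy + cs * dx + ctr[2]
  if (reflect) sc <- w + 1 - sc
  ri <- round(sr); ci <- round(sc)
  ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  go <- matrix(0, side, side)
  mo <- matrix(0, side, side)
  idx_out <- cbind(rc$r[ok], rc$c[ok])
  idx_in <- cbind(ri[ok], ci[ok])
  go[idx_out] <- g[idx_in]
  mo[idx_out] <- m[idx_in]
  go[mo == 0] <- 0
  list(g = go, m = mo)
}

fft2 <- function(x) fft(x)
ifft2 <- function(x) Re(fft(x, inverse = TRUE)) / length(x)

# Masked normalized cross-correlation over all integer translations
# (Padfield-style: every sum computed via FFT correlations).  Returns the
# best shift (of B relative to A, in rows/cols) and its NCC, considering
# only shifts whose overlap is at least `min_overlap` of the larger mask.
masked_ncc_best_shift <- function(gA, mA, gB, mB, min_overlap = 0.25) {
  ph <- nrow(gA) + nrow(gB); pw <- ncol(gA) + ncol(gB)
  pad <- function(x) { o <- matrix(0, ph, pw)
    o[seq_len(nrow(x)), seq_len(ncol(x))] <- x; o }
  FA <- fft2(pad(gA * mA)); FMa <- fft2(pad(mA)); FA2 <- fft2(pad(gA^2 * mA))
  FB <- fft2(pad(gB * mB)); FMb <- fft2(pad(mB)); FB2 <- fft2(pad(gB^2 * mB))
  corr <- function(F1, F2) ifft2(F1 * Conj(F2))
  nn <- corr(FMa, FMb)
  sab <- corr(FA, FB)
  sa <- corr(FA, FMb)
  sb <- corr(FMa, FB)
  sa2 <- corr(FA2, FMb)
  sb2 <- corr(FMa, FB2)
  floor_n <- max(min_overlap * min(sum(mA), sum(mB)), 8)
  valid <- nn >= floor_n
  if (!any(valid)) return(NULL)
  num <- sab - sa * sb / pmax(nn, 1)
  va <- pmax(sa2 - sa^2 / pmax(nn, 1), 0)
  vb <- pmax(sb2 - sb^2 / pmax(nn, 1), 0)
  ncc <- num / sqrt(pmax(va * vb, 1e-12))
  ncc[!valid] <- -Inf
  best <- which.max(ncc)
  br <- (best - 1) %% ph; bc <- (best - 1) %/% ph
  if (br > ph / 2) br <- br - ph
  if (bc > pw / 2) bc <- bc - pw
  list(shift = c(br, bc), ncc = ncc[best])
}

#' Rigid registration of two surface images
#'
#' Exhaustive rotation search: for every angle on the grid (optionally also
#' reflected), B is resampled about its center and the best integer
#' translation found by masked cross-correlation; the pose maximizing the
#' normalized cross-correlation (NCC) over the overlapping covered pixels
#' wins.  Images are compared on their channel-averaged intensities.
#'
#' @param a,b [surface_image]s (B is registered onto A).
#' @param angle_step rotation grid spacing in degrees.
#' @param allow_reflection also search left-right reflected poses.
#' @param min_overlap smallest admissible overlap, as a fraction of the
#'   smaller image's coverage.
#' @return a [rigid_transform2d] mapping B into A's frame.
#' @export
register_rigid <- function(a, b, angle_step = 2, allow_reflection = FALSE,
                           min_overlap = 0.25) {
  ga <- gray_of(a); gb <- gray_of(b)
  for (im in list(ga, gb)) {
    vals <- im$g[im$m > 0]
    if (length(vals) == 0 || sd(vals) == 0)
      stop("NCC undefined: image has no intensity variance", call. = FALSE)
  }
  angles <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  best <- NULL
  for (refl in (if (allow_reflection) c(FALSE, TRUE) else FALSE)) {
    for (th in angles) {
      rb <- rotate_masked(gb$g, gb$m, th, reflect = refl)
      hit <- masked_ncc_best_shift(ga$g, ga$m, rb$g, rb$m, min_overlap)
      if (is.null(hit)) next
      if (is.null(best) || hit$ncc > best$score) {
        # shift is between padded top-left corners; express it as the offset
        # of B's center from A's center in A's frame
        center_off <- hit$shift +
          (c(nrow(rb$g), ncol(rb$g)) + 1) / 2 - (c(nrow(ga$g), ncol(ga$g)) + 1) / 2
        best <- rigid_transform2d(rotation = th, translation = center_off,
                                  reflected = refl, score = hit$ncc)
      }
    }
  }
  if (is.null(best))
    stop("no pose with sufficient overlap found", call. = FALSE)
  best
}

#' Superpose one surface image onto another
#'
#' Resamples B into A's frame under a rigid transform (nearest neighbor) and
#' blends the two 50/50 where both are covered; pixels covered by only one
#' image keep that image's value.  The overlap fraction (overlapping pixels
#' over the union of coverage) is attached as attribute
#' `"overlap_fraction"`, with a warning when it is zero.
#'
#' @inheritParams register_rigid
#' @param transform a [rigid_transform2d] (e.g. from [register_rigid()]).
#' @return a [surface_image] in A's frame.
#' @export
superpose <- function(a, b, transform) {
  da <- dim(a$pixels)
  nb <- dim(b$pixels)[3]
  if (nb != da[3]) stop("channel counts differ", call. = FALSE)
  ctr_a <- (da[1:2] + 1) / 2
  ctr_b <- (dim(b$pixels)[1:2] + 1) / 2
  rc <- expand.grid(r = seq_len(da[1]), c = seq_len(da[2]))
  d <- cbind(rc$r - ctr_a[1] - transform$translation[1],
             rc$c - ctr_a[2] - transform$translation[2])
  cs <- cos(transform$rotation); sn <- sin(transform$rotation)
  sr <- cs * d[, 1] - sn * d[, 2] + ctr_b[1]
  sc <- sn * d[, 1] + cs * d[, 2] + ctr_b[2]
  if (transform$reflected) sc <- dim(b$pixels)[2] + 1 - sc
  ri <- round(sr); ci <- round(sc)
  ok <- ri >= 1 & ri <= dim(b$pixels)[1] & ci >= 1 & ci <= dim(b$pixels)[2]
  b_cov <- matrix(FALSE, da[1], da[2])
  b_cov[cbind(rc$r[ok], rc$c[ok])] <- b$coverage[cbind(ri[ok], ci[ok])]
  pix <- a$pixels
  for (ch in seq_len(da[3])) {
    bch <- matrix(NA_real_, da[1], da[2])
    bch[cbind(rc$r[ok], rc$c[ok])] <- b$pixels[, , ch][cbind(ri[ok], ci[ok])]
    plane <- pix[, , ch]
    both <- a$coverage & b_cov & !is.na(bch)
    only_b <- !a$coverage & b_cov & !is.na(bch)
    plane[both] <- (plane[both] + bch[both]) / 2
    plane[only_b] <- bch[only_b]
    pix[, , ch] <- plane
  }
  cov <- a$coverage | b_cov
  overlap <- sum(a$coverage & b_cov) / max(sum(cov), 1)
  if (overlap == 0) warning("superposition has zero overlap", call. = FALSE)
  out <- surface_image(pix, a$channels, transform = a$transform,
                       coverage = cov)
  attr(out, "overlap_fraction") <- overlap
  out
}

#' Sample image colors at the map positions
#'
#' The texture-mapping forward step: every map point is assigned the pixel
#' value of the pixel it falls in.  Images carrying a map transform (e.g.
#' from [rasterize()]) are sampled in that frame; plain imported images are
#' first fitted so that the embedding's bounding box covers the full raster.
#'
#' @param emb an [embedding2d].
#' @param image a [surface_image].
#' @return numeric `n x C` matrix of channel values (0..255).
#' @export
texture_assign <- function(emb, image) {
  d <- dim(image$pixels)
  tr <- image$transform
  if (is.null(tr)) {
    # fit the embedding bbox onto the full image, preserving aspect
    tr <- fit_transform(emb$coords, min(d[1], d[2]))
    tr$offset_col <- tr$offset_col + (d[2] - min(d[1], d[2])) / 2
    tr$offset_row <- tr$offset_row + (d[1] - min(d[1], d[2])) / 2
    image$transform <- tr
  }
  px <- round(map_to_pixel(image, emb$coords))
  if (any(px[, "row"] < 1 | px[, "row"] > d[1] |
            px[, "col"] < 1 | px[, "col"] > d[2]))
    stop("map point falls outside the image", call. = FALSE)
  out <- matrix(NA_real_, nrow(px), d[3])
  for (ch in seq_len(d[3]))
    out[, ch] <- image$pixels[, , ch][px]
  colnames(out) <- image$channels
  out
}

#' Attach per-vertex colors to a mesh
#'
#' The texture-mapping return step: colors sampled in 2-D are carried back
#' onto the 3-D surface, vertex for vertex; export with [write_ply()] and
#' any PLY viewer will interpolate the colors across each triangle.
#'
#' @param mesh a [trimesh3d].
#' @param vertex_colors `n x 3` RGB matrix in 0..255 (1- or 2-channel input
#'   is expanded to gray / padded).
#' @return the colored [trimesh3d].
#' @export
colorize_mesh <- function(mesh, vertex_colors) {
  vertex_colors <- as.matrix(vertex_colors)
  if (ncol(vertex_colors) == 1)
    vertex_colors <- vertex_colors[, c(1, 1, 1)]
  if (ncol(vertex_colors) == 2)
    vertex_colors <- cbind(vertex_colors, 0)
  mesh$colors <- check_vertex_colors(round(vertex_colors), n_vertices(mesh))
  mesh
}
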