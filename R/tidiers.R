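#' Tidy a 2-D embedding
#'
#' @param x an [embedding2d].
#' @param ... unused.
#' @return a tibble with columns `vertex`, `x`, `y`.
#' @export
tidy.embedding2d <- function(x, ...) {
  tibble::tibble(vertex = seq_len(nrow(x$coords)),
                 x = x$coords[, 1], y = x$coords[, 2])
}

#' Tidy a score report
#'
#' @param x a `score_report` from [score_map()].
#' @param ... unused.
#' @return a one-row tibble with the report fields.
#' @export
tidy.score_report <- function(x, ...) {
  tibble::tibble(method = x$method, area_score = x$area_score,
                 neighbor_score = x$neighbor_score, k = x$k,
                 n_vertices = x$n_vertices, n_faces = x$n_faces)
}

#' Tidy a feature field
#'
#' @param x a [feature_field].
#' @param ... unused.
#' @return a tibble with columns `vertex` and `value`.
#' @export
tidy.feature_field <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$values), value = x$values)
}

#' Plot a 2-D embedding
#'
#' Scatter plot of the map, optionally colored by a feature channel.
#'
#' @param object an [embedding2d].
#' @param field optional [feature_field] aligned with the embedding.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.embedding2d <- function(object, field = NULL, ...) {
  df <- tidy(object)
  if (!is.null(field)) {
    df$value <- field$values
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          color = .data$value)) +
      ggplot2::scale_color_gradient2(low = "blue", mid = "white",
                                     high = "red",
                                     limits = field$clip_range,
                                     oob = scales_squish,
                                     name = field$kind)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  }
  p + ggplot2::geom_point(size = 1) + ggplot2::coord_equal() +
    ggplot2::labs(title = object$method) + ggplot2::theme_minimal()
}

# minimal out-of-bounds squisher so scales is not a hard dependency
scales_squish <- function(x, range = c(0, 1)) pmin(pmax(x, range[1]), range[2])

#' Plot a surface image
#'
#' Raster display of up to three channels mapped to RGB.
#'
#' @param object a [surface_image].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.surface_image <- function(object, ...) {
  d <- dim(object$pixels)
  px <- object$pixels
  px[is.na(px)] <- 255
  rgb3 <- switch(as.character(d[3]),
                 "1" = px[, , c(1, 1, 1)],
                 "2" = array(c(px, matrix(255, d[1], d[2])),
                             c(d[1], d[2], 3)),
                 px[, , 1:3])
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(rgb3[, , 1][cbind(df$row, df$col)],
                            rgb3[, , 2][cbind(df$row, df$col)],
                            rgb3[, , 3][cbind(df$row, df$col)],
                            maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::coord_equal() + ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
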