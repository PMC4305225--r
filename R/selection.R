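# Polygon-based cluster selection on the 2-D embedding, visual-attribute
# mapping, and scatter-plot export — the headless counterpart of drawing
# a polygon on the plot and exporting the enclosed sequences.

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd rule; the polygon is implicitly closed
#' and may self-intersect. Points lying exactly on an edge (or vertex)
#' count as inside, so a boundary drawn through a point captures it.
#'
#' @param points numeric n x 2 matrix (or length-2 vector) of x/y
#'   coordinates.
#' @param polygon numeric m x 2 matrix of vertices, m >= 3.
#' @return logical vector of length n.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' pointInPolygon(c(0.5, 0.5), sq)  # TRUE
#' pointInPolygon(c(1.5, 0.5), sq)  # FALSE
#' @export
pointInPolygon <- function(points, polygon) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  polygon <- as.matrix(polygon)
  m <- nrow(polygon)
  if (m < 3L) stop("polygon needs at least 3 vertices")
  if (any(!is.finite(polygon))) stop("polygon vertices must be finite")

  px <- points[, 1]
  py <- points[, 2]
  inside <- rep(FALSE, nrow(points))
  onEdge <- rep(FALSE, nrow(points))
  j <- m
  for (i in seq_len(m)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    # collinear and within the segment's bounding box -> on the edge
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) & px <= pmax(xi, xj) &
              py >= pmin(yi, yj) & py <= pmax(yi, yj)
    onEdge <- onEdge | (cross == 0 & within)
    # even-odd ray cast: horizontal ray towards +x
    crosses <- ((yi > py) != (yj > py)) &
               (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Select the sequences inside a polygon
#'
#' @param embedding an [EmbeddingResult] (or a data.frame with columns
#'   `id`, `x`, `y` as read by [readEmbedding()]).
#' @param polygon numeric m x 2 vertex matrix.
#' @return character vector of the ids inside the polygon, in embedding
#'   row order; an empty selection is returned (with a warning).
#' @export
selectCluster <- function(embedding, polygon) {
  if (is(embedding, "EmbeddingResult")) {
    co <- embeddingCoords(embedding)
    ids <- rownames(co)
  } else {
    stopifnot(all(c("id", "x", "y") %in% colnames(embedding)))
    co <- cbind(embedding$x, embedding$y)
    ids <- embedding$id
  }
  hit <- pointInPolygon(co, polygon)
  if (!any(hit)) warning("polygon selects no points")
  ids[hit]
}

#' Map annotations to per-point visual attributes
#'
#' Point size encodes `ln(length)` and opacity encodes `ln(coverage + 1)`
#' (the +1 guards assemblies that report zero coverage), both min-max
#' scaled into fixed display ranges; `label` maps to a categorical
#' palette and marker-gene carriers are drawn as stars. When all values
#' of a channel coincide (degenerate min-max), the channel falls back to
#' its minimum; a missing channel falls back to a constant.
#'
#' @param annotations a data.frame/`DataFrame` with any of `coverage`,
#'   `label`, `isMarker` (e.g. from [readAnnotations()]), or `NULL`.
#' @param lengths integer sequence lengths (>= 1), one per point.
#' @param sizeRange,opacityRange display ranges, defaults `[2, 12]` and
#'   `[0.2, 1]`.
#' @return data.frame with columns `size`, `opacity`, `color`, `shape`
#'   (`"circle"` or `"star"`).
#' @export
computeVisualAttributes <- function(annotations, lengths,
                                    sizeRange = c(2, 12),
                                    opacityRange = c(0.2, 1)) {
  stopifnot(all(lengths >= 1))
  n <- length(lengths)
  ann <- if (is.null(annotations)) data.frame() else as.data.frame(annotations)

  rescale <- function(v, range) {
    span <- max(v) - min(v)
    if (span == 0) return(rep(range[1], length(v)))
    range[1] + (range[2] - range[1]) * (v - min(v)) / span
  }

  size <- rescale(log(lengths), sizeRange)
  opacity <- if ("coverage" %in% colnames(ann)) {
    rescale(log(ann$coverage + 1), opacityRange)
  } else rep(opacityRange[2], n)
  color <- if ("label" %in% colnames(ann)) {
    as.character(ann$label)
  } else rep("unlabelled", n)
  shape <- if ("isMarker" %in% colnames(ann)) {
    ifelse(ann$isMarker, "star", "circle")
  } else rep("circle", n)

  data.frame(size = size, opacity = opacity, color = color, shape = shape,
             stringsAsFactors = FALSE)
}

#' Scatter plot of an embedding with the standard visual encodings
#'
#' Size ~ ln(length), opacity ~ ln(coverage + 1), color ~ label, star
#' shape for marker-gene carriers; optional polygons are overdrawn.
#'
#' @param embedding an [EmbeddingResult].
#' @param lengths sequence lengths aligned to the embedding (required for
#'   the size channel; constant size if `NULL`).
#' @param annotations optional annotation table aligned to the embedding.
#' @param polygons optional named list of vertex matrices to overlay.
#' @param file optional output path (`.png`/`.pdf`); when given, the plot
#'   is saved and the path returned invisibly.
#' @param width,height device size in inches.
#' @return the ggplot object (invisibly if written to `file`).
#' @importFrom ggplot2 .data
#' @export
plotEmbedding <- function(embedding, lengths = NULL, annotations = NULL,
                          polygons = NULL, file = NULL,
                          width = 7, height = 6) {
  co <- embeddingCoords(embedding)
  n <- nrow(co)
  if (is.null(lengths)) lengths <- rep(1000L, n)
  va <- computeVisualAttributes(annotations, lengths)
  df <- data.frame(x = co[, 1], y = co[, 2], va)

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$color,
                                     shape = .data$shape),
                        size = df$size / 3, alpha = df$opacity) +
    ggplot2::scale_shape_manual(values = c(circle = 16, star = 8)) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  colour = "label", shape = "") +
    ggplot2::theme_minimal()
  if (length(unique(df$color)) == 1L)
    p <- p + ggplot2::guides(colour = "none")
  if (all(df$shape == "circle"))
    p <- p + ggplot2::guides(shape = "none")
  if (!is.null(polygons)) {
    for (nm in names(polygons)) {
      poly <- as.data.frame(polygons[[nm]])
      colnames(poly) <- c("x", "y")
      p <- p + ggplot2::geom_polygon(data = poly, fill = NA,
                                     colour = "red", linewidth = 0.4)
    }
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
    return(invisible(file))
  }
  p
}
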