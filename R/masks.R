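#' ROI polygon
#'
#' Ordered vertex list in 0-based pixel coordinates (x = column, rightward;
#' y = row, downward; pixel centers at integers). The polygon must be simple
#' (non-self-intersecting) with at least three vertices and nonzero area.
#'
#' @param vertices numeric matrix or data.frame with columns x, y (or a
#'   2-column matrix), one row per vertex.
#' @param label region label, e.g. `"tumor"` or `"parenchyma"`.
#' @param check_simple verify non-self-intersection (O(E^2); disable for
#'   very large polygons).
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, label = "tumor", check_simple = TRUE) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) stop("'vertices' must have two columns (x, y)")
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  a <- polygon_area(v)
  if (abs(a) < .Machine$double.eps)
    stop("degenerate polygon (zero area)")
  if (check_simple && !is_simple_polygon(v))
    stop("polygon is self-intersecting")
  structure(list(vertices = v, label = label), class = "roi_polygon")
}

#' Read an ROI polygon from JSON
#'
#' Expects `{"label": ..., "vertices": [[x, y], ...]}`.
#'
#' @param path JSON file path.
#' @return An [roi_polygon()].
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_polygon(j$vertices, label = if (is.null(j$label)) "tumor" else j$label)
}

#' @rdname read_roi_json
#' @param polygon an [roi_polygon()] to write.
#' @export
write_roi_json <- function(polygon, path) {
  jsonlite::write_json(
    list(label = polygon$label, vertices = unname(polygon$vertices)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  sum(v[j, 1L] * v[, 2L] - v[, 1L] * v[j, 2L]) / 2
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ## adjacent edges share a vertex; skip them
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(seg[i, 1:2], seg[i, 3:4],
                             seg[j, 1:2], seg[j, 3:4])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Region mask
#'
#' Boolean pixel grid with a label; the rasterized form of an ROI.
#'
#' @param mask logical matrix.
#' @param label region label.
#' @return An object of class `region_mask` with elements `mask`, `label`,
#'   `count`.
#' @export
region_mask <- function(mask, label = "region") {
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  mask <- mask & !is.na(mask)
  structure(list(mask = mask, label = label, count = sum(mask)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> '", x$label, "': ", x$count, " of ",
      length(x$mask), " pixels\n", sep = "")
  invisible(x)
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its center (integer 0-based coordinates)
#' lies inside the polygon under the even-odd rule. Boundary ties are
#' resolved by the half-open ray-casting convention: an edge counts a
#' crossing when the ray at the pixel center passes its half-open vertical
#' span `[min(y), max(y))`, so centers exactly on a horizontal edge at the
#' polygon's top belong to the mask and those at the bottom do not.
#'
#' @param polygon an [roi_polygon()].
#' @param grid_shape `c(ny, nx)`.
#' @return A [region_mask()] with the polygon's label.
#' @export
rasterize_polygon <- function(polygon, grid_shape) {
  stopifnot(inherits(polygon, "roi_polygon"))
  v <- polygon$vertices
  ny <- grid_shape[1L]; nx <- grid_shape[2L]
  if (any(v[, 1L] < -0.5 | v[, 1L] > nx - 0.5 |
            v[, 2L] < -0.5 | v[, 2L] > ny - 0.5))
    stop("polygon vertices fall outside the grid bounds")
  xc <- rep(0:(nx - 1L), each = ny)
  yc <- rep(0:(ny - 1L), nx)
  inside <- point_in_polygon(xc, yc, v)
  region_mask(matrix(inside, ny, nx), polygon$label)
}

## even-odd ray casting, vectorized over query points
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Construct a parenchymal ring around a tumor mask
#'
#' Dilates the tumor mask with a diamond (4-connected, L1-ball) structuring
#' element of radius `round(width_mm / pixel_spacing)` pixels and subtracts
#' the tumor, yielding an annular band of surrounding tissue clipped to the
#' grid and disjoint from the tumor.
#'
#' @param tumor a [region_mask()].
#' @param width_mm ring width in mm.
#' @param pixel_spacing pixel edge length in mm.
#' @return A [region_mask()] labelled `"parenchyma"`.
#' @export
make_parenchyma_ring <- function(tumor, width_mm, pixel_spacing = 1) {
  stopifnot(inherits(tumor, "region_mask"))
  if (width_mm <= 0) stop("'width_mm' must be positive")
  r <- round(width_mm / pixel_spacing)
  if (r < 1) stop("ring width rounds to 0 pixels at this pixel spacing")
  m <- tumor$mask * 1L
  dil <- EBImage::dilate(m, EBImage::makeBrush(2L * r + 1L, "diamond"))
  region_mask(dil > 0 & !tumor$mask, "parenchyma")
}

#' Export a region mask
#'
#' `write_mask_png()` writes a 0/255 grayscale PNG; `mask_to_rle()` returns
#' a run-length encoding in column-major order as a data.frame suitable for
#' CSV export.
#'
#' @param mask a [region_mask()].
#' @param path output file path.
#' @return The path (png) or a data.frame with columns `start`, `length`
#'   (1-based column-major pixel offsets of TRUE runs).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask$mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
mask_to_rle <- function(mask) {
  r <- rle(as.vector(mask$mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}
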