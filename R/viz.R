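#' Bilinearly interpolate the velocity field
#'
#' Storage-frame interpolation at sub-pixel 0-based positions. Positions
#' whose 4-pixel neighborhood leaves the grid or touches an invalid pixel
#' return `NA`.
#'
#' @param field a [transport_field()].
#' @param x,y 0-based storage coordinates (x = column, y = row).
#' @return A list of vectors `ux`, `uy`.
#' @export
interp_velocity <- function(field, x, y) {
  d <- dim(field)
  ok <- x >= 0 & x <= d[2L] - 1L & y >= 0 & y <= d[1L] - 1L
  j0 <- pmax(pmin(floor(x), d[2L] - 2L), 0)
  i0 <- pmax(pmin(floor(y), d[1L] - 2L), 0)
  fx <- x - j0; fy <- y - i0
  bil <- function(m) {
    v00 <- m[cbind(i0 + 1L, j0 + 1L)]; v01 <- m[cbind(i0 + 1L, j0 + 2L)]
    v10 <- m[cbind(i0 + 2L, j0 + 1L)]; v11 <- m[cbind(i0 + 2L, j0 + 2L)]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
  }
  ux <- bil(field$velocity_x); uy <- bil(field$velocity_y)
  ux[!ok] <- NA_real_; uy[!ok] <- NA_real_
  list(ux = ux, uy = uy)
}

#' Integrate streamlines through the velocity field
#'
#' Classical 4th-order Runge-Kutta integration of the unit tangent field
#' `dx/ds = u(x)/|u(x)|` (arc-length parameterization, so streamlines trace
#' direction structure independent of speed) with bilinear interpolation of
#' the velocity components. A streamline ends when it leaves the valid
#' field (`left_mask`), the local speed falls below `min_speed`
#' (`low_speed`), or `max_steps` is reached.
#'
#' @param field a [transport_field()].
#' @param seed_points numeric matrix (n x 2) of 0-based `(x, y)` seeds.
#' @param step arc-length step in pixels.
#' @param max_steps maximum number of steps per streamline.
#' @param min_speed termination speed threshold.
#' @return A list of `streamline` objects: `points` (m x 2 matrix of x, y)
#'   and `reason` (`"left_mask"`, `"low_speed"`, `"max_steps"`).
#' @export
compute_streamlines <- function(field, seed_points, step = 0.5,
                                max_steps = 1000, min_speed = 1e-12) {
  stopifnot(inherits(field, "transport_field"))
  if (step <= 0) stop("'step' must be positive")
  seed_points <- matrix(as.numeric(seed_points), ncol = 2L)
  d <- dim(field)
  if (any(seed_points[, 1L] < 0 | seed_points[, 1L] > d[2L] - 1L |
            seed_points[, 2L] < 0 | seed_points[, 2L] > d[1L] - 1L))
    stop("seed point outside the grid")
  dirfun <- function(p) {
    v <- interp_velocity(field, p[1L], p[2L])
    if (!is.finite(v$ux) || !is.finite(v$uy)) return(NULL)
    sp <- sqrt(v$ux^2 + v$uy^2)
    if (sp < min_speed) return(NA)
    c(v$ux, v$uy) / sp
  }
  lapply(seq_len(nrow(seed_points)), function(s) {
    p <- seed_points[s, ]
    pts <- matrix(p, 1L, 2L)
    reason <- "max_steps"
    for (it in seq_len(max_steps)) {
      k1 <- dirfun(p)
      if (is.null(k1)) { reason <- "left_mask"; break }
      if (anyNA(k1)) { reason <- "low_speed"; break }
      k2 <- dirfun(p + step / 2 * k1)
      k3 <- if (!is.null(k2) && !anyNA(k2)) dirfun(p + step / 2 * k2)
      k4 <- if (!is.null(k3) && !anyNA(k3)) dirfun(p + step * k3)
      if (is.null(k2) || is.null(k3) || is.null(k4)) {
        reason <- "left_mask"; break
      }
      if (anyNA(k2) || anyNA(k3) || anyNA(k4)) {
        reason <- "low_speed"; break
      }
      p2 <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (p2[1L] < 0 || p2[1L] > d[2L] - 1L ||
            p2[2L] < 0 || p2[2L] > d[1L] - 1L) {
        reason <- "left_mask"; break
      }
      p <- p2
      pts <- rbind(pts, p)
    }
    structure(list(points = unname(pts), reason = reason),
              class = "streamline")
  })
}

#' Regular streamline seed grid inside a mask
#'
#' @param mask a [region_mask()].
#' @param spacing seed spacing in pixels.
#' @return An n x 2 matrix of 0-based `(x, y)` seed points.
#' @export
streamline_seeds <- function(mask, spacing = 4) {
  idx <- which(mask$mask, arr.ind = TRUE)
  keep <- (idx[, 1L] - 1L) %% spacing == 0 & (idx[, 2L] - 1L) %% spacing == 0
  cbind(x = idx[keep, 2L] - 1, y = idx[keep, 1L] - 1)
}

#' Direction-magnitude rose histogram
#'
#' Wind-rose style polar histogram of flow direction, stratified by speed.
#' Directions use the anatomical frame (one y-flip from storage):
#' `atan2(-uy, ux)` in degrees, so 0 deg points right (toward increasing
#' x) and 90 deg points up (toward decreasing row, anterior on an axial
#' image). Direction bins partition [0, 360) uniformly; each valid masked
#' pixel falls in exactly one direction x magnitude cell, except truly
#' static pixels (`|u| = 0`), which are counted separately rather than
#' assigned an arbitrary direction. Counts (plus the static count) always
#' sum to the number of valid masked pixels.
#'
#' @param field a [transport_field()].
#' @param mask optional [region_mask()].
#' @param n_dir_bins number of direction bins (>= 4).
#' @param mag_edges increasing magnitude bin edges; defaults to quintile
#'   edges of the nonzero speeds. Values outside the edge range land in
#'   the first/last bin.
#' @param weight `"count"` (pixels, default) or `"magnitude"`
#'   (speed-weighted).
#' @return A list of class `rose_histogram`: `counts` (n_dir x n_mag),
#'   `dir_edges` (degrees), `mag_edges`, `static`, `total`, `weight`.
#' @export
rose_histogram <- function(field, mask = NULL, n_dir_bins = 16,
                           mag_edges = NULL,
                           weight = c("count", "magnitude")) {
  stopifnot(inherits(field, "transport_field"))
  weight <- match.arg(weight)
  if (n_dir_bins < 4L) stop("'n_dir_bins' must be at least 4")
  sel <- field$valid_mask
  if (!is.null(mask)) sel <- sel & mask$mask
  ux <- field$velocity_x[sel]; uy <- field$velocity_y[sel]
  sp <- sqrt(ux^2 + uy^2)
  static <- sp == 0
  total <- length(sp)
  ang <- (atan2(-uy[!static], ux[!static]) * 180 / pi) %% 360
  spn <- sp[!static]
  if (is.null(mag_edges)) {
    mag_edges <- if (length(spn))
      unique(quantile(spn, seq(0, 1, length.out = 6))) else c(0, 1)
    if (length(mag_edges) < 2L)
      mag_edges <- c(mag_edges, mag_edges + 1)
  }
  if (any(diff(mag_edges) <= 0)) stop("'mag_edges' must be increasing")
  n_mag <- length(mag_edges) - 1L
  dbin <- pmin(floor(ang / (360 / n_dir_bins)) + 1L, n_dir_bins)
  mbin <- pmin(pmax(findInterval(spn, mag_edges,
                                 rightmost.closed = TRUE), 1L), n_mag)
  counts <- matrix(0, n_dir_bins, n_mag)
  w <- if (weight == "count") rep(1, length(ang)) else spn
  for (i in seq_along(ang))
    counts[dbin[i], mbin[i]] <- counts[dbin[i], mbin[i]] + w[i]
  structure(
    list(counts = counts,
         dir_edges = seq(0, 360, length.out = n_dir_bins + 1L),
         mag_edges = mag_edges,
         static = if (weight == "count") sum(static) else 0,
         total = total, weight = weight),
    class = "rose_histogram")
}

#' @export
print.rose_histogram <- function(x, ...) {
  cat("<rose_histogram> ", nrow(x$counts), " direction bins x ",
      ncol(x$counts), " magnitude bins; ", x$total, " pixels (",
      x$static, " static)\n", sep = "")
  invisible(x)
}

#' Export a rose histogram as a tidy table
#'
#' @param rose a [rose_histogram()].
#' @return `data.frame` with `dir_lo`, `dir_hi`, `mag_lo`, `mag_hi`,
#'   `count` (one row per cell, plus one `static` row when nonzero).
#' @export
rose_to_table <- function(rose) {
  nd <- nrow(rose$counts); nm <- ncol(rose$counts)
  df <- data.frame(
    dir_lo = rep(rose$dir_edges[seq_len(nd)], nm),
    dir_hi = rep(rose$dir_edges[-1L], nm),
    mag_lo = rep(rose$mag_edges[seq_len(nm)], each = nd),
    mag_hi = rep(rose$mag_edges[-1L], each = nd),
    count = as.vector(rose$counts))
  if (rose$static > 0)
    df <- rbind(df, data.frame(dir_lo = NA, dir_hi = NA, mag_lo = 0,
                               mag_hi = 0, count = rose$static))
  df
}

## ---- deterministic raster rendering -------------------------------------
## Figures are drawn into numeric RGB arrays and written with png::writePNG,
## which is byte-deterministic for fixed input - run manifests hash
## identically across repeat runs.

viridis_ramp <- local({
  anchors <- c("#440154", "#414487", "#2A788E", "#22A884", "#7AD151",
               "#FDE725")
  ramp <- colorRamp(anchors)
  function(v) ramp(pmin(pmax(v, 0), 1)) / 255
})

normalize01 <- function(m, lim = range(m, finite = TRUE)) {
  if (!is.finite(lim[1L]) || diff(lim) == 0)
    return(matrix(0, nrow(m), ncol(m)))
  pmin(pmax((m - lim[1L]) / diff(lim), 0), 1)
}

#' Render a parameter heat map over an anatomical background
#'
#' Writes a PNG in which valid masked pixels are colored by `map` value
#' and all other pixels show the grayscale background; invalid pixels are
#' never colored. The color limits and palette are recorded in a JSON
#' sidecar. Rendering is raster-based and byte-deterministic.
#'
#' @param map numeric matrix (e.g. speed or D).
#' @param mask optional [region_mask()] restricting the overlay.
#' @param background optional background matrix (same shape); defaults to
#'   a flat dark field.
#' @param out_path output PNG path.
#' @param zlim color limits; default the finite range of the masked map.
#' @param upscale integer pixel replication factor for the output raster.
#' @return Invisibly, a list with `path` and `zlim`.
#' @export
render_heatmap <- function(map, mask = NULL, background = NULL, out_path,
                           zlim = NULL, upscale = 4L) {
  sel <- is.finite(map)
  if (!is.null(mask)) sel <- sel & mask$mask
  if (is.null(zlim))
    zlim <- if (any(sel)) range(map[sel]) else c(0, 1)
  if (is.null(background)) background <- matrix(0.15, nrow(map), ncol(map))
  if (!identical(dim(background), dim(map)))
    stop("'background' must match the map shape")
  bg <- normalize01(background)
  rgb <- array(rep(bg, 3L), c(dim(map), 3L))
  if (any(sel)) {
    cols <- viridis_ramp(normalize01(map, zlim)[sel])
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(upscale_raster(rgb, upscale), out_path)
  jsonlite::write_json(
    list(zlim = zlim, palette = "viridis", upscale = upscale),
    paste0(out_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(list(path = out_path, zlim = zlim))
}

upscale_raster <- function(rgb, f) {
  f <- as.integer(f)
  if (f <= 1L) return(rgb)
  d <- dim(rgb)
  rgb[rep(seq_len(d[1L]), each = f), rep(seq_len(d[2L]), each = f), ,
      drop = FALSE]
}

#' Quiver arrow segments
#'
#' Computes arrow geometry for a decimated quiver plot: one unit-length
#' arrow per kept valid pixel, centered on the pixel and pointing along the
#' local flow (storage frame; rendering is what flips y). Speeds are
#' attached for coloring.
#'
#' @param field a [transport_field()].
#' @param decimate keep every `decimate`-th pixel per axis.
#' @param arrow_len arrow length in pixels.
#' @return `data.frame` with `x0, y0, x1, y1, speed` (0-based storage
#'   coordinates).
#' @export
quiver_segments <- function(field, decimate = 2L, arrow_len = 1.6) {
  idx <- which(field$valid_mask, arr.ind = TRUE)
  keep <- (idx[, 1L] - 1L) %% decimate == 0 &
    (idx[, 2L] - 1L) %% decimate == 0
  idx <- idx[keep, , drop = FALSE]
  ux <- field$velocity_x[idx]; uy <- field$velocity_y[idx]
  sp <- sqrt(ux^2 + uy^2)
  nz <- sp > 0
  idx <- idx[nz, , drop = FALSE]
  dx <- ux[nz] / sp[nz] * arrow_len / 2
  dy <- uy[nz] / sp[nz] * arrow_len / 2
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  data.frame(x0 = x - dx, y0 = y - dy, x1 = x + dx, y1 = y + dy,
             speed = sp[nz])
}

#' Render a quiver + streamline overlay
#'
#' Draws speed-colored arrows (see [quiver_segments()]) and green
#' streamlines over the grayscale background and writes a PNG
#' (byte-deterministic raster rendering). Arrowheads make the flow
#' direction unambiguous; because PNG rows run top-down while the storage
#' frame has y down, flow toward decreasing row index appears as "up" on
#' the figure with no extra flip.
#'
#' @param field a [transport_field()].
#' @param background optional background matrix.
#' @param streamlines list of streamlines from [compute_streamlines()]
#'   (may be empty for a quiver-only figure).
#' @param out_path output PNG path.
#' @param decimate quiver decimation factor per axis.
#' @param upscale raster upscale factor (sub-pixel drawing resolution).
#' @return Invisibly, a list with `path` and `n_arrows`.
#' @export
render_quiver_streamlines <- function(field, background = NULL,
                                      streamlines = list(), out_path,
                                      decimate = 2L, upscale = 6L) {
  d <- dim(field)
  if (is.null(background)) background <- matrix(0.15, d[1L], d[2L])
  bg <- normalize01(background)
  rgb <- array(rep(bg, 3L), c(d, 3L))
  rgb <- upscale_raster(rgb, upscale)
  seg <- quiver_segments(field, decimate = decimate)
  if (nrow(seg)) {
    spn <- normalize01(matrix(seg$speed), range(seg$speed))
    cols <- viridis_ramp(as.vector(spn))
    for (i in seq_len(nrow(seg))) {
      rgb <- draw_segment(rgb, seg$x0[i], seg$y0[i], seg$x1[i], seg$y1[i],
                          cols[i, ], upscale)
      ## arrowhead: two short barbs at +-150 degrees from the shaft
      th <- atan2(seg$y1[i] - seg$y0[i], seg$x1[i] - seg$x0[i])
      for (s in c(-1, 1)) {
        a <- th + s * 5 * pi / 6
        rgb <- draw_segment(rgb, seg$x1[i], seg$y1[i],
                            seg$x1[i] + 0.6 * cos(a),
                            seg$y1[i] + 0.6 * sin(a), cols[i, ], upscale)
      }
    }
  }
  green <- c(0, 0.9, 0.2)
  for (sl in streamlines) {
    p <- sl$points
    if (nrow(p) > 1L)
      for (i in seq_len(nrow(p) - 1L))
        rgb <- draw_segment(rgb, p[i, 1L], p[i, 2L], p[i + 1L, 1L],
                            p[i + 1L, 2L], green, upscale)
  }
  png::writePNG(rgb, out_path)
  invisible(list(path = out_path, n_arrows = nrow(seg)))
}

## draw a line segment into an upscaled RGB raster; coordinates are
## 0-based storage-pixel units
draw_segment <- function(rgb, x0, y0, x1, y1, col, upscale) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0)) * upscale * 2))
  xs <- round((seq(x0, x1, length.out = n) + 0.5) * upscale + 0.5)
  ys <- round((seq(y0, y1, length.out = n) + 0.5) * upscale + 0.5)
  d <- dim(rgb)
  ok <- xs >= 1 & xs <= d[2L] & ys >= 1 & ys <= d[1L]
  if (any(ok)) {
    for (ch in 1:3)
      rgb[cbind(ys[ok], xs[ok], ch)] <- col[ch]
  }
  rgb
}
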