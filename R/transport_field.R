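#' Per-pixel transport field
#'
#' Holds an isotropic diffusion coefficient map and the two velocity
#' components on a pixel grid, together with a validity mask. Invalid pixels
#' carry `NA` (a true sentinel, never a silent zero) and are excluded from
#' every summary. Transport parameters are treated as constant over the
#' analysis time window: one field per image stack.
#'
#' @param diffusion_map,velocity_x,velocity_y numeric matrices of equal
#'   shape. `diffusion_map` must be nonnegative wherever valid. The storage
#'   frame has x = column (right) and y = row (down).
#' @param valid_mask logical matrix marking pixels with usable estimates;
#'   defaults to pixels where all three maps are finite.
#' @param pixel_spacing pixel edge length in mm.
#' @param units `"px_frame"` (pixels and frame intervals) or `"physical"`
#'   (mm and seconds); see [to_physical_units()].
#' @param frame_interval_s reference frame interval in seconds (used for
#'   unit conversion).
#' @return An object of class `transport_field`.
#' @export
transport_field <- function(diffusion_map, velocity_x, velocity_y,
                            valid_mask = NULL, pixel_spacing = 1,
                            units = c("px_frame", "physical"),
                            frame_interval_s = NA_real_) {
  units <- match.arg(units)
  dims <- dim(diffusion_map)
  if (!identical(dims, dim(velocity_x)) || !identical(dims, dim(velocity_y)))
    stop("all maps must share one grid shape")
  if (is.null(valid_mask))
    valid_mask <- is.finite(diffusion_map) & is.finite(velocity_x) &
      is.finite(velocity_y)
  if (!identical(dims, dim(valid_mask)))
    stop("'valid_mask' must match the map shape")
  if (any(diffusion_map[valid_mask] < 0, na.rm = TRUE))
    stop("diffusion_map must be nonnegative at valid pixels")
  diffusion_map[!valid_mask] <- NA_real_
  velocity_x[!valid_mask] <- NA_real_
  velocity_y[!valid_mask] <- NA_real_
  structure(
    list(diffusion_map = diffusion_map, velocity_x = velocity_x,
         velocity_y = velocity_y, valid_mask = valid_mask,
         pixel_spacing = pixel_spacing, units = units,
         frame_interval_s = frame_interval_s),
    class = "transport_field")
}

#' @export
dim.transport_field <- function(x) dim(x$diffusion_map)

#' @export
print.transport_field <- function(x, ...) {
  d <- dim(x)
  cat("<", class(x)[1L], "> ", d[1L], "x", d[2L], " pixels, ",
      sum(x$valid_mask), " valid (", x$units, " units)\n", sep = "")
  if (sum(x$valid_mask) > 0) {
    sp <- velocity_magnitude(x)
    cat(sprintf("  D: median %.4g   |u|: median %.4g\n",
                stats::median(x$diffusion_map[x$valid_mask]),
                stats::median(sp[x$valid_mask])))
  }
  invisible(x)
}

#' Velocity magnitude map
#'
#' `sqrt(ux^2 + uy^2)` per pixel; `NA` at invalid pixels.
#'
#' @param field a [transport_field()].
#' @return A numeric matrix of speeds.
#' @export
velocity_magnitude <- function(field) {
  stopifnot(inherits(field, "transport_field"))
  sqrt(field$velocity_x^2 + field$velocity_y^2)
}

#' Convert a transport field between pixel-frame and physical units
#'
#' Estimation is done in pixel-frame units (D in px^2/frame, u in px/frame).
#' `to_physical_units()` rescales D by `spacing^2 / interval` to mm^2/s and
#' u by `spacing / interval` to mm/s; `to_pixel_units()` inverts it. The
#' conversion is metadata-driven and exact. With non-uniform frame intervals
#' a single conversion factor is ill-defined: the mean interval is used only
#' when `average_rule = TRUE`, otherwise conversion errors out.
#'
#' @param field a [transport_field()].
#' @param pixel_spacing_mm pixel edge length in mm.
#' @param frame_interval_s frame interval in seconds.
#' @param average_rule allow the mean-interval rule for non-uniform timing.
#' @return The rescaled `transport_field`.
#' @export
to_physical_units <- function(field, pixel_spacing_mm = field$pixel_spacing,
                              frame_interval_s = field$frame_interval_s,
                              average_rule = FALSE) {
  stopifnot(inherits(field, "transport_field"))
  if (field$units == "physical") return(field)
  check_interval(field, frame_interval_s, average_rule)
  out <- field
  out$diffusion_map <- field$diffusion_map *
    pixel_spacing_mm^2 / frame_interval_s
  out$velocity_x <- field$velocity_x * pixel_spacing_mm / frame_interval_s
  out$velocity_y <- field$velocity_y * pixel_spacing_mm / frame_interval_s
  out$units <- "physical"
  out
}

#' @rdname to_physical_units
#' @export
to_pixel_units <- function(field, pixel_spacing_mm = field$pixel_spacing,
                           frame_interval_s = field$frame_interval_s,
                           average_rule = FALSE) {
  stopifnot(inherits(field, "transport_field"))
  if (field$units == "px_frame") return(field)
  check_interval(field, frame_interval_s, average_rule)
  out <- field
  out$diffusion_map <- field$diffusion_map *
    frame_interval_s / pixel_spacing_mm^2
  out$velocity_x <- field$velocity_x * frame_interval_s / pixel_spacing_mm
  out$velocity_y <- field$velocity_y * frame_interval_s / pixel_spacing_mm
  out$units <- "px_frame"
  out
}

check_interval <- function(field, frame_interval_s, average_rule) {
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("'frame_interval_s' must be a positive number")
  cv <- attr(field, "interval_cv")
  if (!is.null(cv) && is.finite(cv) && cv > 1e-6 && !average_rule)
    stop("frame intervals are non-uniform (cv = ", signif(cv, 3),
         "); pass average_rule = TRUE to use the mean interval")
  invisible(TRUE)
}
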