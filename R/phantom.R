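#' Phantom specification
#'
#' Describes a synthetic slice with known ground-truth transport so that
#' every downstream stage can be validated by parameter recovery. Three
#' geometries are supported:
#' \describe{
#'   \item{`uniform`}{constant `D` and `u` everywhere.}
#'   \item{`gaussian_blob`}{`D` and the speed scaled by a smooth Gaussian
#'     envelope centered on the blob (spatially varying but smooth).}
#'   \item{`tumor_ring`}{a disk ("tumor") with one `(D, |u|)` regime and a
#'     surrounding annulus ("parenchyma") with another; the velocity points
#'     radially outward from the disk center, emulating bulk outflow from a
#'     pressurized tumor core. Outside the annulus the field is static.}
#' }
#'
#' @param kind phantom geometry, see above.
#' @param shape `c(ny, nx)` grid shape, at least 16 x 16.
#' @param D diffusion coefficient; for `tumor_ring` the inside value.
#' @param u velocity `c(ux, uy)` for `uniform`/`gaussian_blob`.
#' @param D_out,ring_speed_in,ring_speed_out `tumor_ring` parameters:
#'   annulus diffusion, inner and outer speeds.
#' @param ring_center disk center `c(x, y)` (0-based pixels); defaults to
#'   the grid center, which for even grids falls between pixels so no pixel
#'   sits at radius zero.
#' @param ring_radius,ring_width disk radius and annulus width in pixels.
#' @param blob_center,blob_sigma,blob_amplitude initial-condition blob
#'   parameters ([gaussian_blob()]).
#' @param pixel_spacing pixel edge length in mm.
#' @param source_rate,source_on,source_off optional enhancement source
#'   (see [simulate_stack()]); `source_rate = 0` disables it.
#' @param noise_sigma acquisition noise standard deviation.
#' @param seed integer seed used when the phantom is simulated.
#' @return An object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(kind = c("uniform", "gaussian_blob", "tumor_ring"),
                         shape = c(64, 64), D = 0.2, u = c(0.4, -0.2),
                         D_out = NULL, ring_speed_in = 0.05,
                         ring_speed_out = 0.15,
                         ring_center = (rev(shape) - 1) / 2,
                         ring_radius = min(shape) / 5,
                         ring_width = min(shape) / 8,
                         blob_center = (rev(shape) - 1) / 2, blob_sigma = 4,
                         blob_amplitude = 1, pixel_spacing = 1,
                         source_rate = 0, source_on = 0, source_off = Inf,
                         noise_sigma = 0, seed = 1L) {
  kind <- if (is.character(kind) && length(kind) >= 1L)
    match.arg(kind) else stop("unknown phantom kind")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L))
    stop("'shape' must be at least 16 x 16")
  if (any(D < 0) || (!is.null(D_out) && D_out < 0))
    stop("diffusion coefficients must be nonnegative")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(
    list(kind = kind, shape = shape, D = D, u = u,
         D_out = if (is.null(D_out)) D else D_out,
         ring_speed_in = ring_speed_in, ring_speed_out = ring_speed_out,
         ring_center = ring_center, ring_radius = ring_radius,
         ring_width = ring_width, blob_center = blob_center,
         blob_sigma = blob_sigma, blob_amplitude = blob_amplitude,
         pixel_spacing = pixel_spacing, source_rate = source_rate,
         source_on = source_on, source_off = source_off,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Build a phantom transport field and initial condition
#'
#' Deterministically constructs the ground-truth [transport_field()] and the
#' initial concentration described by a [phantom_spec()]. For the
#' `tumor_ring` kind, the tumor disk and parenchymal annulus masks are
#' attached so recovery tests can compare region summaries against truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `field` (transport_field), `initial`
#'   (matrix), `spec`, and for `tumor_ring` also `tumor_mask` and
#'   `ring_mask` ([region_mask()] objects).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.character(spec$kind) ||
        !spec$kind %in% c("uniform", "gaussian_blob", "tumor_ring"))
    stop("unknown phantom kind: ", spec$kind)
  ny <- spec$shape[1L]; nx <- spec$shape[2L]
  x <- matrix(rep(0:(nx - 1L), each = ny), ny)
  y <- matrix(rep(0:(ny - 1L), nx), ny)
  out <- switch(
    spec$kind,
    uniform = list(
      D = matrix(spec$D, ny, nx),
      ux = matrix(spec$u[1L], ny, nx),
      uy = matrix(spec$u[2L], ny, nx)),
    gaussian_blob = {
      env <- exp(-((x - spec$blob_center[1L])^2 +
                     (y - spec$blob_center[2L])^2) /
                   (2 * (2 * spec$blob_sigma)^2))
      list(D = spec$D * env, ux = spec$u[1L] * env, uy = spec$u[2L] * env)
    },
    tumor_ring = {
      dx <- x - spec$ring_center[1L]; dy <- y - spec$ring_center[2L]
      r <- sqrt(dx^2 + dy^2)
      inside <- r <= spec$ring_radius
      ring <- r > spec$ring_radius &
        r <= spec$ring_radius + spec$ring_width
      speed <- matrix(0, ny, nx)
      speed[inside] <- spec$ring_speed_in
      speed[ring] <- spec$ring_speed_out
      rr <- pmax(r, .Machine$double.eps)
      list(D = ifelse(inside, spec$D, ifelse(ring, spec$D_out, 0)),
           ux = speed * dx / rr, uy = speed * dy / rr,
           inside = inside, ring = ring)
    },
    stop("unknown phantom kind: ", spec$kind))
  field <- transport_field(out$D, out$ux, out$uy,
                           pixel_spacing = spec$pixel_spacing)
  initial <- gaussian_blob(spec$shape, spec$blob_center, spec$blob_sigma,
                           spec$blob_amplitude)
  res <- list(field = field, initial = initial, spec = spec)
  if (spec$kind == "tumor_ring") {
    res$tumor_mask <- region_mask(out$inside, "tumor")
    res$ring_mask <- region_mask(out$ring, "parenchyma")
  }
  res
}

#' Simulate a phantom end to end
#'
#' Convenience wrapper: [make_phantom()] then [simulate_stack()] with the
#' spec's source, noise and seed.
#'
#' @param spec a [phantom_spec()].
#' @param frame_times acquisition times in seconds.
#' @param pre_contrast_count leading pre-contrast frames.
#' @param ... passed to [simulate_stack()].
#' @return A list `(stack, field, initial, spec, ...)` as from
#'   [make_phantom()] plus the simulated `conc_stack`.
#' @export
simulate_phantom <- function(spec, frame_times = 0:5,
                             pre_contrast_count = 1, ...) {
  ph <- make_phantom(spec)
  src <- if (any(spec$source_rate != 0))
    list(rate = spec$source_rate, t_on = spec$source_on,
         t_off = spec$source_off)
  ph$stack <- simulate_stack(ph$field, ph$initial, frame_times,
                             pre_contrast_count = pre_contrast_count,
                             source = src, noise_sigma = spec$noise_sigma,
                             seed = spec$seed, ...)
  ph
}
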