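#' Concentration image stack
#'
#' Container for a dynamic contrast-enhanced image time series on a single
#' 2D slice: one matrix per timepoint, with acquisition times, pixel spacing
#' and the number of leading pre-contrast frames. Frame intensities are
#' treated as proportional to local contrast-agent concentration.
#'
#' @param frames numeric array `ny x nx x nt` (row = y, col = x) or a list of
#'   equally-shaped matrices. Values must be finite.
#' @param frame_times numeric vector of acquisition times in seconds,
#'   strictly increasing, one per frame.
#' @param pixel_spacing in-plane pixel edge length in mm (isotropic).
#' @param pre_contrast_count number of leading frames acquired before
#'   contrast arrival.
#' @param noise_sd optional known acquisition noise standard deviation (same
#'   intensity units as `frames`); estimated by [subtract_background()] when
#'   not supplied.
#' @return An object of class `conc_stack`: a list with elements `frames`,
#'   `frame_times`, `pixel_spacing`, `pre_contrast_count`, `noise_sd`.
#' @seealso [subtract_background()], [select_spanning_frames()],
#'   [estimate_transport()]
#' @export
conc_stack <- function(frames, frame_times, pixel_spacing = 1,
                       pre_contrast_count = 0, noise_sd = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share one grid shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be an ny x nx x nt array or a list of matrices")
  storage.mode(frames) <- "double"
  if (!all(is.finite(frames)))
    stop("frames contain non-finite values")
  nt <- dim(frames)[3L]
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != nt)
    stop("'frame_times' must have one entry per frame (got ",
         length(frame_times), " for ", nt, " frames)")
  if (any(diff(frame_times) <= 0))
    stop("'frame_times' must be strictly increasing")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      !is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop("'pixel_spacing' must be a single positive number (mm)")
  pre_contrast_count <- as.integer(pre_contrast_count)
  if (pre_contrast_count < 0L || pre_contrast_count > nt)
    stop("'pre_contrast_count' must be between 0 and the number of frames")
  structure(
    list(frames = frames, frame_times = frame_times,
         pixel_spacing = pixel_spacing,
         pre_contrast_count = pre_contrast_count,
         noise_sd = noise_sd),
    class = "conc_stack")
}

#' @export
print.conc_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<conc_stack> ", d[1L], "x", d[2L], " pixels, ", d[3L], " frames (",
      x$pre_contrast_count, " pre-contrast)\n", sep = "")
  cat("  times [s]: ", paste(signif(x$frame_times, 4), collapse = ", "),
      "\n  pixel spacing: ", x$pixel_spacing, " mm\n", sep = "")
  if (!is.null(x$noise_sd))
    cat("  noise sd estimate: ", signif(x$noise_sd, 4), "\n", sep = "")
  invisible(x)
}

#' @export
dim.conc_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3L]

#' Select frames spanning the imaging session
#'
#' DCE acquisitions often record hundreds of dynamic frames over a few
#' minutes; transport estimation needs only a handful that span the session.
#' Returns the first pre-contrast frame plus `n_select - 1` post-contrast
#' frame indices evenly spanning the post-contrast range, always including
#' the final frame. Fractional positions are rounded with the half-up rule
#' (`floor(x + 0.5)`), so e.g. 5 available frames with one pre-contrast frame
#' and `n_select = 4` give indices `c(1, 2, 4, 5)`.
#'
#' @param n_available total number of frames on disk.
#' @param n_select number of frames to keep (>= 4).
#' @param pre_contrast_count number of leading pre-contrast frames (>= 1).
#' @return Integer vector of 1-based frame indices, strictly increasing.
#' @export
select_spanning_frames <- function(n_available, n_select = 4,
                                   pre_contrast_count = 1) {
  n_available <- as.integer(n_available)
  n_select <- as.integer(n_select)
  pre_contrast_count <- as.integer(pre_contrast_count)
  if (n_select < 4L) stop("'n_select' must be at least 4")
  if (pre_contrast_count < 1L)
    stop("at least one pre-contrast frame is required")
  if (n_select > n_available)
    stop("cannot select ", n_select, " frames from ", n_available)
  n_post <- n_available - pre_contrast_count
  if (n_post < n_select - 1L)
    stop("only ", n_post, " post-contrast frames available, need ",
         n_select - 1L)
  post <- as.integer(floor(
    seq(pre_contrast_count + 1L, n_available, length.out = n_select - 1L)
    + 0.5))
  c(1L, post)
}

#' Subtract the pre-contrast background
#'
#' Subtracts the pixel-wise mean of all pre-contrast frames from every
#' post-contrast frame, clamping negative values to zero (a concentration
#' cannot be negative). The returned stack contains the post-contrast frames
#' only, with `pre_contrast_count = 0`. The acquisition noise standard
#' deviation is estimated from the pre-contrast frames and carried along for
#' the noise-corrected inverse solver: with two or more pre frames from the
#' pooled residual around their mean, with a single pre frame from the
#' robust spread of its 5-point Laplacian (`mad/sqrt(20)`), which is blind
#' to any flat or slowly-varying baseline.
#'
#' The background estimate is lightly smoothed (3 x 3 box, replicated
#' edges) before subtraction: the baseline it captures is spatially smooth,
#' while smoothing suppresses most of the pre-frame acquisition noise that
#' would otherwise be injected into every subtracted frame (the small
#' remainder is tracked and handled by the estimator's noise correction).
#' Set `smooth_background = FALSE` for the raw subtraction.
#'
#' @param stack a [conc_stack()] with `pre_contrast_count >= 1`.
#' @param clamp clamp negative differences to zero (default `TRUE`).
#' @param smooth_background smooth the background estimate before
#'   subtracting (default `TRUE`).
#' @return A background-subtracted `conc_stack` of the post-contrast frames.
#' @export
subtract_background <- function(stack, clamp = TRUE,
                                smooth_background = TRUE) {
  stopifnot(inherits(stack, "conc_stack"))
  npre <- stack$pre_contrast_count
  if (npre < 1L)
    stop("no pre-contrast frame: background subtraction needs at least one")
  nt <- n_frames(stack)
  npost <- nt - npre
  if (npost < 3L)
    stop("at least three post-contrast frames are required (got ", npost, ")")
  pre <- stack$frames[, , seq_len(npre), drop = FALSE]
  bg <- apply(pre, c(1L, 2L), mean)
  if (smooth_background) bg <- box3_smooth(bg)
  post_idx <- (npre + 1L):nt
  out <- stack$frames[, , post_idx, drop = FALSE]
  for (k in seq_len(npost)) {
    f <- out[, , k] - bg
    if (clamp) f[f < 0] <- 0
    out[, , k] <- f
  }
  noise_sd <- stack$noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- if (npre >= 2L) {
      sqrt(sum((pre - as.vector(bg))^2) / (length(bg) * (npre - 1L)))
    } else {
      lap <- stencil_laplacian(pre[, , 1L])
      interior <- lap[2:(nrow(lap) - 1L), 2:(ncol(lap) - 1L)]
      stats::mad(interior, center = stats::median(interior)) / sqrt(20)
    }
  }
  res <- conc_stack(out, stack$frame_times[post_idx],
                    pixel_spacing = stack$pixel_spacing,
                    pre_contrast_count = 0L, noise_sd = noise_sd)
  ## the subtracted background injects shared noise into every frame; the
  ## inverse solver's noise correction needs its variance ratio and whether
  ## it was smoothed (the stencil kernels see smoothed noise differently)
  res$bg_noise_var <- 1 / npre          # Var(mean pre) in units of sigma^2
  res$bg_smoothed <- smooth_background
  res
}

## 3x3 box smoothing with replicated edges
box3_smooth <- function(m) {
  p <- pad_replicate(m)
  n1 <- nrow(m); n2 <- ncol(m)
  acc <- matrix(0, n1, n2)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[di + seq_len(n1), dj + seq_len(n2)]
  acc / 9
}

## central/Laplacian stencils in pixel units; edges filled by replicating
## the boundary value (zero-flux ghost cells), so results there are one-sided
stencil_laplacian <- function(f) {
  p <- pad_replicate(f)
  n1 <- nrow(f); n2 <- ncol(f)
  p[2:(n1 + 1L), 3:(n2 + 2L)] + p[2:(n1 + 1L), 1:n2] +
    p[3:(n1 + 2L), 2:(n2 + 1L)] + p[1:n1, 2:(n2 + 1L)] - 4 * f
}

stencil_gx <- function(f) {
  p <- pad_replicate(f)
  n1 <- nrow(f); n2 <- ncol(f)
  (p[2:(n1 + 1L), 3:(n2 + 2L)] - p[2:(n1 + 1L), 1:n2]) / 2
}

stencil_gy <- function(f) {
  p <- pad_replicate(f)
  n1 <- nrow(f); n2 <- ncol(f)
  (p[3:(n1 + 2L), 2:(n2 + 1L)] - p[1:n1, 2:(n2 + 1L)]) / 2
}

pad_replicate <- function(f) {
  f2 <- rbind(f[1L, , drop = FALSE], f, f[nrow(f), , drop = FALSE])
  cbind(f2[, 1L, drop = FALSE], f2, f2[, ncol(f2), drop = FALSE])
}
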