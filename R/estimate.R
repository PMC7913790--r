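#' Options for the pixel-wise transport inverse problem
#'
#' @param advection_form `"gradient"` (default): the advective term
#'   `div(phi u)` is expanded as `u . grad(phi) + phi div(u)` and the
#'   locally non-computable `phi div(u)` term is dropped (a locally
#'   divergence-free assumption), giving an independent linear system per
#'   pixel. `"conservative_joint"` (a coupled whole-ROI solve with a
#'   divergence penalty) is a recognized extension point and currently
#'   errors.
#' @param min_coef_norm_factor a row (frame interval) is usable only when
#'   the norm of its stencil coefficient vector exceeds this factor times
#'   the stack's maximum intensity; pixels with fewer than 3 usable rows
#'   are flagged `degenerate`, so flat background never yields flow
#'   "measurements".
#' @param condition_ceiling pixels whose design matrix condition number
#'   (computed from the raw, uncorrected normal matrix) exceeds the
#'   ceiling are flagged `ill_conditioned`.
#' @param nonneg_policy what to do with a negative recovered diffusion
#'   coefficient: `"clip"` to zero and flag (keeps spatial coverage),
#'   or `"reject"` (mark the pixel invalid).
#' @param boundary `"exclude"` marks the 1-pixel image border invalid;
#'   `"mirror"` uses replicated-edge (zero-flux ghost) stencils there.
#' @param noise_correction subtract the closed-form noise moments of the
#'   finite-difference stencils from the normal equations (corrected-score
#'   least squares). With independent pixel noise of variance `s^2`, the
#'   stencil noise inflates `A'A` by `s^2 * diag(20, 1/2, 1/2)` per row
#'   (plus a small exactly-known term for the shared subtracted-background
#'   noise), and the shared frame noise between the response and the
#'   Laplacian regressor adds `4 s^2` per row to the first element of
#'   `A'b`; subtracting both removes the leading errors-in-variables bias.
#'   With `s = 0` the correction is inert, so noiseless recovery is
#'   unaffected.
#' @param noise_sd noise standard deviation used by the correction; `NULL`
#'   takes the stack's estimate (see [subtract_background()]) and falls
#'   back to a robust stencil estimate from the first frame.
#' @return An object of class `estimation_options`.
#' @export
estimation_options <- function(advection_form = c("gradient",
                                                  "conservative_joint"),
                               min_coef_norm_factor = 1e-9,
                               condition_ceiling = 1e6,
                               nonneg_policy = c("clip", "reject"),
                               boundary = c("exclude", "mirror"),
                               noise_correction = TRUE,
                               noise_sd = NULL) {
  advection_form <- match.arg(advection_form)
  if (advection_form == "conservative_joint")
    stop("the conservative-joint (coupled, divergence-penalized) solver ",
         "is an extension point and is not implemented; use the default ",
         "per-pixel gradient form")
  if (min_coef_norm_factor <= 0) stop("'min_coef_norm_factor' must be > 0")
  if (condition_ceiling <= 1) stop("'condition_ceiling' must be > 1")
  structure(
    list(advection_form = advection_form,
         min_coef_norm_factor = min_coef_norm_factor,
         condition_ceiling = condition_ceiling,
         nonneg_policy = match.arg(nonneg_policy),
         boundary = match.arg(boundary),
         noise_correction = isTRUE(noise_correction),
         noise_sd = noise_sd),
    class = "estimation_options")
}

resolve_noise_sd <- function(stack, options) {
  if (!options$noise_correction) return(0)
  if (!is.null(options$noise_sd)) return(options$noise_sd)
  if (!is.null(stack$noise_sd)) return(stack$noise_sd)
  lap <- stencil_laplacian(stack$frames[, , 1L])
  interior <- lap[2:(nrow(lap) - 1L), 2:(ncol(lap) - 1L)]
  stats::mad(interior, center = stats::median(interior)) / sqrt(20)
}

## per-interval stencil fields and responses, shared by both solvers;
## returns K-length lists plus the per-row frame-unit interval
interval_terms <- function(stack) {
  nt <- n_frames(stack)
  K <- nt - 1L
  dts <- diff(stack$frame_times)
  dt_ref <- mean(dts)
  dtau <- dts / dt_ref
  L <- Gx <- Gy <- R <- vector("list", K)
  for (k in seq_len(K)) {
    f <- stack$frames[, , k]
    L[[k]] <- stencil_laplacian(f)
    Gx[[k]] <- stencil_gx(f)
    Gy[[k]] <- stencil_gy(f)
    R[[k]] <- (stack$frames[, , k + 1L] - f) / dtau[k]
  }
  list(L = L, Gx = Gx, Gy = Gy, R = R, K = K, dtau = dtau,
       dt_ref = dt_ref, dt_cv = stats::sd(dts) / dt_ref)
}

#' Assemble the per-pixel linear system
#'
#' Builds the discretized diffusion-advection system for one pixel: one row
#' per consecutive frame interval encoding
#' `(phi[k+1] - phi[k]) / dtau[k] = D * L(phi[k]) - ux * Gx(phi[k]) - uy *
#' Gy(phi[k])` in pixel-frame units, with the 5-point Laplacian and central
#' first differences evaluated on the earlier frame (forward-time,
#' central-space). The unknown vector is `(D, ux, uy)`.
#'
#' @param stack a background-subtracted [conc_stack()] with at least 4
#'   frames.
#' @param pixel `c(row, col)`, 1-based.
#' @param options an [estimation_options()].
#' @return A list of class `pixel_system`: `A` (K x 3 design matrix), `b`
#'   (response), `row_usable` (stencil-norm screen), `condition` (design
#'   condition number), `status` (`"ok"`, `"degenerate"`,
#'   `"ill_conditioned"`), and `solution` (named vector, `NA` unless
#'   status is `"ok"`).
#' @export
assemble_pixel_system <- function(stack, pixel,
                                  options = estimation_options()) {
  stopifnot(inherits(stack, "conc_stack"))
  if (stack$pre_contrast_count != 0L)
    stop("stack must be background-subtracted first (see ",
         "subtract_background)")
  if (n_frames(stack) < 4L)
    stop("need at least 4 frames (3 intervals) to determine (D, ux, uy)")
  d <- dim(stack$frames)
  i <- pixel[1L]; j <- pixel[2L]
  if (i < 1L || j < 1L || i > d[1L] || j > d[2L])
    stop("pixel out of bounds")
  if (options$boundary == "exclude" &&
        (i == 1L || j == 1L || i == d[1L] || j == d[2L]))
    stop("pixel lies on the image border (boundary policy 'exclude')")
  tt <- interval_terms(stack)
  A <- cbind(D = vapply(tt$L, `[`, 0, i, j),
             ux = -vapply(tt$Gx, `[`, 0, i, j),
             uy = -vapply(tt$Gy, `[`, 0, i, j))
  b <- vapply(tt$R, `[`, 0, i, j)
  thr <- options$min_coef_norm_factor * max(abs(stack$frames))
  row_usable <- sqrt(rowSums(A^2)) > thr
  sd_n <- resolve_noise_sd(stack, options)
  sys <- solve_corrected(A[row_usable, , drop = FALSE], b[row_usable],
                         tt$dtau[row_usable], sd_n,
                         options$condition_ceiling,
                         stencil_noise_moments(stack))
  structure(list(A = A, b = b, row_usable = row_usable,
                 condition = sys$condition, status = sys$status,
                 solution = sys$solution, pixel = pixel),
            class = "pixel_system")
}

## Per-row noise second moments of the stencil regressors, in units of
## sigma^2. Each subtracted frame carries its own acquisition noise
## (Laplacian energy 20, gradient energy 1/2) plus the shared subtracted
## background of variance sigma^2/n_pre, whose stencil energy depends on
## whether the background was box-smoothed: the 3x3 box nearly annihilates
## the Laplacian (kernel energy 0.39507 instead of 20) and most of the
## gradient (0.037037 instead of 0.5).
stencil_noise_moments <- function(stack) {
  mL <- 20; mG <- 0.5
  if (!is.null(stack$bg_noise_var)) {
    v0 <- stack$bg_noise_var
    if (isTRUE(stack$bg_smoothed)) {
      mL <- mL + v0 * 0.39506172839506
      mG <- mG + v0 * 0.037037037037037
    } else {
      mL <- mL + v0 * 20
      mG <- mG + v0 * 0.5
    }
  }
  c(L = mL, G = mG)
}

## corrected-score normal-equation solve for one pixel (reference path)
solve_corrected <- function(A, b, dtau, noise_sd, ceiling,
                            moments = c(L = 20, G = 0.5)) {
  if (nrow(A) < 3L)
    return(list(status = "degenerate", condition = NA_real_,
                solution = c(D = NA_real_, ux = NA_real_, uy = NA_real_)))
  ## conditioning is judged on the raw design: it measures how informative
  ## the data are; the noise correction is applied only to the solve
  ev <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) > 0) sqrt(max(ev) / min(ev)) else Inf
  if (!is.finite(cond) || cond > ceiling)
    return(list(status = "ill_conditioned", condition = cond,
                solution = c(D = NA_real_, ux = NA_real_, uy = NA_real_)))
  M <- crossprod(A) - noise_sd^2 * nrow(A) *
    diag(unname(c(moments["L"], moments["G"], moments["G"])))
  v <- crossprod(A, b) - c(4 * noise_sd^2 * sum(1 / dtau), 0, 0)
  ## exactly-determined noiseless systems: direct solve of A x = b avoids
  ## squaring the condition number through the normal equations
  x <- tryCatch({
    if (nrow(A) == 3L && noise_sd == 0) drop(solve(A, b))
    else drop(solve(M, v))
  }, error = function(e) rep(NA_real_, 3L))
  if (!all(is.finite(x)))
    return(list(status = "ill_conditioned", condition = cond,
                solution = c(D = NA_real_, ux = NA_real_, uy = NA_real_)))
  list(status = "ok", condition = cond,
       solution = c(D = x[1L], ux = x[2L], uy = x[3L]))
}

#' Estimate the transport field from a concentration stack
#'
#' The fitting function at the core of the package: inverts the
#' diffusion-advection equation pixel by pixel on a background-subtracted
#' DCE stack, returning the isotropic diffusion coefficient map and the
#' interstitial velocity vector field in pixel-frame units. Each pixel's
#' system (see [assemble_pixel_system()]) is solved by corrected-score
#' least squares (ordinary least squares when `noise_correction` is off or
#' the noise estimate is zero); exactly-determined 3-interval systems
#' reduce to a direct solve. Pixels that are degenerate (flat),
#' ill-conditioned, on an excluded border or outside the mask are invalid
#' (`NA`), never silent zeros. A negative recovered D is clipped to zero
#' and flagged under the default policy.
#'
#' @param stack a background-subtracted [conc_stack()] (>= 4 frames).
#' @param mask optional [region_mask()] restricting estimation.
#' @param options an [estimation_options()].
#' @return An object of class `c("transport_fit", "transport_field")`: a
#'   [transport_field()] plus `status` (integer matrix, see
#'   `iffmap:::.iff_status_codes`), `condition`, `clipped` (logical
#'   matrix), `residual_rms`, `n_rows_used`, `noise_sd_used`, `options`.
#'   Methods: `print`, `summary`, `coef`, `residuals`, `plot`, `simulate`.
#' @examples
#' ph <- simulate_phantom(phantom_spec("uniform", shape = c(32, 32),
#'                                     D = 0.1, u = c(0.2, -0.1)),
#'                        frame_times = 0:4, micro_dt = 1)
#' fit <- estimate_transport(subtract_background(ph$stack))
#' summary(fit)
#' @export
estimate_transport <- function(stack, mask = NULL,
                               options = estimation_options()) {
  stopifnot(inherits(stack, "conc_stack"))
  if (stack$pre_contrast_count != 0L)
    stop("stack must be background-subtracted first (see ",
         "subtract_background)")
  nt <- n_frames(stack)
  if (nt < 4L)
    stop("need at least 4 frames (3 intervals) to determine (D, ux, uy)")
  d <- dim(stack$frames)[1:2]
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "region_mask"))
    if (!identical(dim(mask$mask), d))
      stop("mask shape does not match the stack")
    if (mask$count == 0L) stop("empty mask")
    inmask <- mask$mask
  } else inmask <- matrix(TRUE, d[1L], d[2L])

  tt <- interval_terms(stack)
  K <- tt$K
  thr <- options$min_coef_norm_factor * max(abs(stack$frames))
  sd_n <- resolve_noise_sd(stack, options)

  ## accumulate weighted normal equations across intervals, vectorized
  M11 <- M12 <- M13 <- M22 <- M23 <- M33 <- matrix(0, d[1L], d[2L])
  b1 <- b2 <- b3 <- matrix(0, d[1L], d[2L])
  n_used <- matrix(0, d[1L], d[2L])
  inv_dtau_sum <- matrix(0, d[1L], d[2L])
  for (k in seq_len(K)) {
    a1 <- tt$L[[k]]; a2 <- -tt$Gx[[k]]; a3 <- -tt$Gy[[k]]
    r <- tt$R[[k]]
    w <- (sqrt(a1^2 + a2^2 + a3^2) > thr) * 1
    M11 <- M11 + w * a1 * a1; M12 <- M12 + w * a1 * a2
    M13 <- M13 + w * a1 * a3; M22 <- M22 + w * a2 * a2
    M23 <- M23 + w * a2 * a3; M33 <- M33 + w * a3 * a3
    b1 <- b1 + w * a1 * r; b2 <- b2 + w * a2 * r; b3 <- b3 + w * a3 * r
    n_used <- n_used + w
    inv_dtau_sum <- inv_dtau_sum + w / tt$dtau[k]
  }
  ## conditioning from the raw design (data informativeness); the noise
  ## correction below only adjusts the solve
  ev <- sym3_eigenvalues(M11, M12, M13, M22, M23, M33)
  if (sd_n > 0) {
    mom <- stencil_noise_moments(stack)
    M11 <- M11 - sd_n^2 * mom[["L"]] * n_used
    M22 <- M22 - sd_n^2 * mom[["G"]] * n_used
    M33 <- M33 - sd_n^2 * mom[["G"]] * n_used
    b1 <- b1 - 4 * sd_n^2 * inv_dtau_sum
  }
  condition <- sqrt(ev$max / pmax(ev$min, 0))  # Inf where min <= 0
  status <- matrix(.iff_status_codes[["ok"]], d[1L], d[2L])
  status[n_used < 3] <- .iff_status_codes[["degenerate"]]
  bad_cond <- n_used >= 3 &
    (!is.finite(condition) | condition > options$condition_ceiling |
       ev$min <= 0)
  status[bad_cond] <- .iff_status_codes[["ill_conditioned"]]
  if (options$boundary == "exclude") {
    border <- matrix(FALSE, d[1L], d[2L])
    border[c(1L, d[1L]), ] <- TRUE; border[, c(1L, d[2L])] <- TRUE
    status[border] <- .iff_status_codes[["border"]]
  }
  status[!inmask] <- .iff_status_codes[["outside_mask"]]

  sol <- sym3_solve(M11, M12, M13, M22, M23, M33, b1, b2, b3)
  if (sd_n == 0 && K == 3L) {
    ## exactly-determined minimal stacks: direct Cramer solve of the 3x3
    ## design itself (condition cond(A), not cond(A)^2), where all rows
    ## passed the degeneracy screen
    full <- n_used == 3
    a11 <- tt$L[[1L]]; a12 <- -tt$Gx[[1L]]; a13 <- -tt$Gy[[1L]]
    a21 <- tt$L[[2L]]; a22 <- -tt$Gx[[2L]]; a23 <- -tt$Gy[[2L]]
    a31 <- tt$L[[3L]]; a32 <- -tt$Gx[[3L]]; a33 <- -tt$Gy[[3L]]
    r1 <- tt$R[[1L]]; r2 <- tt$R[[2L]]; r3 <- tt$R[[3L]]
    det3 <- function(c1, c2, c3, d1, d2, d3, e1, e2, e3)
      c1 * (d2 * e3 - d3 * e2) - c2 * (d1 * e3 - d3 * e1) +
      c3 * (d1 * e2 - d2 * e1)
    dA <- det3(a11, a12, a13, a21, a22, a23, a31, a32, a33)
    x1 <- det3(r1, a12, a13, r2, a22, a23, r3, a32, a33) / dA
    x2 <- det3(a11, r1, a13, a21, r2, a23, a31, r3, a33) / dA
    x3 <- det3(a11, a12, r1, a21, a22, r2, a31, a32, r3) / dA
    use <- full & is.finite(x1) & is.finite(x2) & is.finite(x3)
    sol$x1[use] <- x1[use]; sol$x2[use] <- x2[use]; sol$x3[use] <- x3[use]
  }
  ok <- status == .iff_status_codes[["ok"]]
  bad_solve <- ok & !(is.finite(sol$x1) & is.finite(sol$x2) &
                        is.finite(sol$x3))
  status[bad_solve] <- .iff_status_codes[["ill_conditioned"]]
  ok <- ok & !bad_solve
  Dm <- ifelse(ok, sol$x1, NA_real_)
  Ux <- ifelse(ok, sol$x2, NA_real_)
  Uy <- ifelse(ok, sol$x3, NA_real_)
  clipped <- matrix(FALSE, d[1L], d[2L])
  neg <- ok & Dm < 0
  if (options$nonneg_policy == "clip") {
    clipped[neg] <- TRUE
    Dm[neg] <- 0
  } else {
    Dm[neg] <- NA_real_; Ux[neg] <- NA_real_; Uy[neg] <- NA_real_
    status[neg] <- .iff_status_codes[["ill_conditioned"]]
    ok <- ok & !neg
  }

  ## per-pixel RMS residual of the (uncorrected) rows at the solution
  rss <- matrix(0, d[1L], d[2L])
  for (k in seq_len(K)) {
    res <- tt$R[[k]] - (Dm * tt$L[[k]] - Ux * tt$Gx[[k]] - Uy * tt$Gy[[k]])
    rss <- rss + res^2
  }
  residual_rms <- ifelse(ok, sqrt(rss / K), NA_real_)

  fit <- transport_field(Dm, Ux, Uy, valid_mask = ok,
                         pixel_spacing = stack$pixel_spacing,
                         units = "px_frame",
                         frame_interval_s = tt$dt_ref)
  attr(fit, "interval_cv") <- tt$dt_cv
  fit$status <- status
  fit$condition <- condition
  fit$clipped <- clipped
  fit$residual_rms <- residual_rms
  fit$n_rows_used <- n_used
  fit$noise_sd_used <- sd_n
  fit$options <- options
  class(fit) <- c("transport_fit", class(fit))
  fit
}

#' @export
summary.transport_fit <- function(object, ...) {
  codes <- .iff_status_codes
  tab <- vapply(codes, function(cd) sum(object$status == cd), 0L)
  sp <- velocity_magnitude(object)
  v <- object$valid_mask
  qs <- function(x) if (any(v)) quantile(x[v], c(0.25, 0.5, 0.75)) else
    rep(NA_real_, 3L)
  out <- list(status_counts = tab, n_clipped = sum(object$clipped),
              D_quartiles = qs(object$diffusion_map),
              speed_quartiles = qs(sp), units = object$units,
              noise_sd_used = object$noise_sd_used,
              degenerate_fraction = unname(tab["degenerate"]) /
                length(object$status))
  class(out) <- "summary.transport_fit"
  out
}

#' @export
print.summary.transport_fit <- function(x, ...) {
  cat("Pixel-wise diffusion-advection fit (", x$units, " units)\n",
      sep = "")
  cat("  pixel status: ",
      paste(names(x$status_counts), x$status_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  clipped negative D: ", x$n_clipped, "\n", sep = "")
  cat(sprintf("  D quartiles:     %.4g / %.4g / %.4g\n",
              x$D_quartiles[1L], x$D_quartiles[2L], x$D_quartiles[3L]))
  cat(sprintf("  speed quartiles: %.4g / %.4g / %.4g\n",
              x$speed_quartiles[1L], x$speed_quartiles[2L],
              x$speed_quartiles[3L]))
  cat("  noise sd used by correction: ", signif(x$noise_sd_used, 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.transport_fit <- function(object, ...) {
  idx <- which(object$valid_mask, arr.ind = TRUE)
  data.frame(row = idx[, 1L], col = idx[, 2L],
             x = idx[, 2L] - 1L, y = idx[, 1L] - 1L,
             D = object$diffusion_map[idx],
             ux = object$velocity_x[idx],
             uy = object$velocity_y[idx])
}

#' @export
residuals.transport_fit <- function(object, ...) object$residual_rms

#' @export
plot.transport_fit <- function(x, what = c("speed", "D"), ...) {
  what <- match.arg(what)
  m <- if (what == "speed") velocity_magnitude(x) else x$diffusion_map
  ## flip rows so anatomical "up" (row 1) is at the top of the plot
  graphics::image(t(m[nrow(m):1, ]), asp = nrow(m) / ncol(m), axes = FALSE,
                  main = if (what == "speed") "|u|" else "D", ...)
  invisible(x)
}

#' @export
simulate.transport_fit <- function(object, nsim = 1, seed = NULL,
                                   initial, frame_times,
                                   noise_sigma = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- object
  ## invalid pixels carry no estimate; simulate them as static tissue
  for (nm in c("diffusion_map", "velocity_x", "velocity_y"))
    f[[nm]][!f$valid_mask] <- 0
  f$valid_mask[] <- TRUE
  out <- lapply(seq_len(nsim), function(i)
    simulate_stack(f, initial, frame_times, pre_contrast_count = 0,
                   noise_sigma = noise_sigma, advection = "gradient", ...))
  if (nsim == 1L) out[[1L]] else out
}

## closed-form eigenvalues of symmetric 3x3 matrices, vectorized over
## pixels (trigonometric method); returns min and max
sym3_eigenvalues <- function(a11, a12, a13, a22, a23, a33) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  list(min = pmin(e1, e3, 3 * q - e1 - e3),
       max = pmax(e1, e3, 3 * q - e1 - e3))
}

## adjugate solve of symmetric 3x3 systems, vectorized over pixels
sym3_solve <- function(m11, m12, m13, m22, m23, m33, b1, b2, b3) {
  c11 <- m22 * m33 - m23^2
  c12 <- m13 * m23 - m12 * m33
  c13 <- m12 * m23 - m13 * m22
  c22 <- m11 * m33 - m13^2
  c23 <- m12 * m13 - m11 * m23
  c33 <- m11 * m22 - m12^2
  det <- m11 * c11 + m12 * c12 + m13 * c13
  list(x1 = (c11 * b1 + c12 * b2 + c13 * b3) / det,
       x2 = (c12 * b1 + c22 * b2 + c23 * b3) / det,
       x3 = (c13 * b1 + c23 * b2 + c33 * b3) / det)
}
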