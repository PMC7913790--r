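test_that("pixel systems encode the hand-evaluated stencil", {
  ## frame 1 is flat except a (1, 2, 1) bump across the center row
  f1 <- matrix(1, 5, 5); f1[3, 2:4] <- c(1, 2, 1); f1[3, 3] <- 2
  f1[2, 3] <- 1; f1[4, 3] <- 1
  fr <- array(1, c(5, 5, 4)); fr[, , 1] <- f1
  st <- conc_stack(fr, 0:3, pre_contrast_count = 0)
  ps <- assemble_pixel_system(st, c(3, 3))
  ## L = 1 + 1 + 1 + 1 - 4*2 = -4; Gx = (1 - 1)/2 = 0; Gy = 0
  expect_equal(unname(ps$A[1, ]), c(-4, 0, 0))
  expect_equal(ps$b[1], 1 - 2)  # frame difference at the center
  ## flat frames give all-zero rows -> degenerate status
  flat <- conc_stack(array(3, c(5, 5, 4)), 0:3, pre_contrast_count = 0)
  psf <- assemble_pixel_system(flat, c(3, 3))
  expect_identical(psf$status, "degenerate")
  expect_true(all(psf$A == 0) && all(psf$b == 0))
})

test_that("pixel-system preconditions are enforced", {
  st <- conc_stack(array(1, c(5, 5, 4)), 0:3, pre_contrast_count = 1)
  expect_error(assemble_pixel_system(st, c(3, 3)), "background-subtract")
  st0 <- conc_stack(array(1, c(5, 5, 3)), 0:2, pre_contrast_count = 0)
  expect_error(assemble_pixel_system(st0, c(3, 3)), "at least 4 frames")
  st4 <- conc_stack(array(1, c(5, 5, 4)), 0:3, pre_contrast_count = 0)
  expect_error(assemble_pixel_system(st4, c(1, 3)), "border")
  expect_error(assemble_pixel_system(st4, c(9, 3)), "out of bounds")
})

test_that("matched-discretization stacks are recovered exactly", {
  for (adv in c("conservative", "gradient")) {
    ph <- matched_uniform_stack(shape = c(48, 48), advection = adv)
    fit <- estimate_transport(subtract_background(ph$stack))
    ok <- fit$valid_mask
    expect_gt(sum(ok), 500)
    expect_lt(max(abs(fit$diffusion_map[ok] - 0.2)) / 0.2, 1e-6)
    expect_lt(max(abs(fit$velocity_x[ok] - 0.4)) / 0.4, 1e-6)
    expect_lt(max(abs(fit$velocity_y[ok] + 0.2)) / 0.2, 1e-6)
  }
})

test_that("pure diffusion yields vanishing recovered velocity", {
  ph <- matched_uniform_stack(shape = c(48, 48), u = c(0, 0))
  fit <- estimate_transport(subtract_background(ph$stack))
  ok <- fit$valid_mask
  sp <- velocity_magnitude(fit)
  expect_lt(median(sp[ok]), 1e-6)
  expect_lt(max(abs(fit$diffusion_map[ok] - 0.2)) / 0.2, 1e-6)
})

test_that("the vectorized solver matches the per-pixel reference path", {
  ph <- matched_uniform_stack(shape = c(24, 24), noise_sigma = 0.01,
                              seed = 13)
  sub <- subtract_background(ph$stack)
  fit <- estimate_transport(sub)
  set.seed(2)
  ## well-conditioned pixels: the two code paths agree to float accuracy
  idx <- which(fit$valid_mask & fit$condition < 1e4 & !fit$clipped,
               arr.ind = TRUE)
  for (r in sample(nrow(idx), 12)) {
    px <- idx[r, ]
    ps <- assemble_pixel_system(sub, px)
    expect_identical(ps$status, "ok")
    expect_equal(unname(ps$solution),
                 c(fit$diffusion_map[px[1], px[2]],
                   fit$velocity_x[px[1], px[2]],
                   fit$velocity_y[px[1], px[2]]), tolerance = 1e-6)
  }
})

test_that("flat regions are flagged degenerate, not zero-velocity", {
  ## blob confined to one corner; the far corner stays flat
  spec <- phantom_spec("uniform", shape = c(32, 32), D = 0.1,
                       u = c(0.2, 0), blob_center = c(8, 8),
                       blob_sigma = 2.5)
  ph <- simulate_phantom(spec, frame_times = 0:4, pre_contrast_count = 1,
                         micro_dt = 1)
  fit <- estimate_transport(subtract_background(ph$stack))
  far <- fit$status[24:31, 24:31]
  expect_true(all(far == 1L))  # degenerate
  expect_true(all(is.na(fit$velocity_x[24:31, 24:31])))
})

test_that("negative D handling follows the configured policy", {
  ## build frames that satisfy the inverse stencil exactly with D < 0
  ## (mild anti-diffusion plus drift, stable over three steps)
  lap <- function(f) iffmap:::stencil_laplacian(f)
  gx <- function(f) iffmap:::stencil_gx(f)
  phi <- gaussian_blob(c(24, 24), sigma = 4)
  fr <- array(0, c(24, 24, 4)); fr[, , 1] <- phi
  for (k in 2:4) {
    phi <- phi + (-0.05) * lap(phi) - 0.1 * gx(phi)
    fr[, , k] <- phi
  }
  st <- conc_stack(fr, 0:3, pre_contrast_count = 0)
  fit_clip <- estimate_transport(st)
  expect_gt(sum(fit_clip$clipped), 0)
  expect_true(all(fit_clip$diffusion_map[fit_clip$valid_mask] >= 0))
  fit_rej <- estimate_transport(
    st, options = estimation_options(nonneg_policy = "reject"))
  expect_identical(sum(fit_rej$clipped), 0L)
  expect_lt(sum(fit_rej$valid_mask), sum(fit_clip$valid_mask))
})

test_that("noise bias stays within the frozen Monte-Carlo bounds", {
  ## corrected-score estimator at 1% noise; bounds fixed before the build
  meds <- t(vapply(1:25, function(s) {
    ph <- matched_uniform_stack(noise_sigma = 0.01, seed = s)
    sub <- subtract_background(ph$stack)
    fit <- estimate_transport(sub, signal_mask(sub))
    ok <- fit$valid_mask
    c(D = median(fit$diffusion_map[ok]),
      ux = median(fit$velocity_x[ok]),
      uy = median(fit$velocity_y[ok]))
  }, c(D = 0, ux = 0, uy = 0)))
  expect_lt(abs(median(meds[, "D"]) - 0.2) / 0.2, 0.10)
  mag <- sqrt(median(meds[, "ux"])^2 + median(meds[, "uy"])^2)
  expect_lt(abs(mag - sqrt(0.2)) / sqrt(0.2), 0.10)
})

test_that("estimation error grows monotonically with the noise level", {
  err_one <- function(sigma, seed) {
    ph <- matched_uniform_stack(shape = c(48, 48), noise_sigma = sigma,
                                seed = seed)
    sub <- subtract_background(ph$stack)
    fit <- estimate_transport(sub, signal_mask(sub))
    ok <- fit$valid_mask
    median(sqrt((fit$diffusion_map[ok] - 0.2)^2 +
                  (fit$velocity_x[ok] - 0.4)^2 +
                  (fit$velocity_y[ok] + 0.2)^2)) / sqrt(0.24)
  }
  med <- vapply(c(0, 0.005, 0.01, 0.02, 0.05), function(s)
    median(vapply(1:9, function(k) err_one(s, k), 0)), 0)
  expect_true(all(diff(med) > 0))
})

test_that("mismatched (fine) forward discretization stays within 15%", {
  ## CFL-like numbers: D*dt/h^2 = 0.08 < 0.1, |u|*dt/h = 0.15 < 0.2
  spec <- phantom_spec("uniform", shape = c(64, 64), D = 0.08,
                       u = c(0.15, 0))
  ph <- simulate_phantom(spec, frame_times = 0:4, pre_contrast_count = 1)
  fit <- estimate_transport(subtract_background(ph$stack))
  ok <- fit$valid_mask
  expect_lt(abs(median(fit$diffusion_map[ok]) - 0.08) / 0.08, 0.15)
  expect_lt(abs(median(fit$velocity_x[ok]) - 0.15) / 0.15, 0.15)
})

test_that("unit conversion is exact, invertible and commutes with speed", {
  ph <- matched_uniform_stack(shape = c(24, 24))
  fit <- estimate_transport(subtract_background(ph$stack))
  phys <- to_physical_units(fit, pixel_spacing_mm = 0.5,
                            frame_interval_s = 10)
  ok <- fit$valid_mask
  expect_equal(phys$diffusion_map[ok], fit$diffusion_map[ok] * 0.025)
  expect_equal(phys$velocity_x[ok], fit$velocity_x[ok] * 0.05)
  back <- to_pixel_units(phys, pixel_spacing_mm = 0.5,
                         frame_interval_s = 10)
  expect_equal(back$diffusion_map[ok], fit$diffusion_map[ok],
               tolerance = 1e-12)
  ## |u| commutes with the rescale
  expect_equal(velocity_magnitude(phys)[ok],
               velocity_magnitude(fit)[ok] * 0.05, tolerance = 1e-12)
  ## simple arithmetic: 2 px/frame at 0.5 mm / 10 s = 0.1 mm/s
  f <- uniform_field(c(16, 16), D = 1, ux = 2)
  f$frame_interval_s <- 10
  p <- to_physical_units(f, pixel_spacing_mm = 0.5, frame_interval_s = 10)
  expect_equal(p$velocity_x[1, 1], 0.1)
  expect_equal(to_physical_units(uniform_field(c(16, 16), D = 1),
                                 pixel_spacing_mm = 1,
                                 frame_interval_s = 1)$diffusion_map[1, 1],
               1)
})

test_that("velocity magnitude is rotation-equivariant and NA-propagating", {
  expect_equal(velocity_magnitude(uniform_field(c(16, 16), ux = 3,
                                                uy = 4))[1, 1], 5)
  expect_equal(velocity_magnitude(uniform_field(c(16, 16)))[1, 1], 0)
  set.seed(17)
  ux <- matrix(rnorm(64), 8); uy <- matrix(rnorm(64), 8)
  f <- transport_field(matrix(0.1, 8, 8), ux, uy)
  ## rotate the grid and the vector components together
  fr <- transport_field(matrix(0.1, 8, 8), rot90ccw(uy), -rot90ccw(ux))
  expect_equal(velocity_magnitude(fr), rot90ccw(velocity_magnitude(f)))
  f2 <- transport_field(matrix(0.1, 8, 8), ux, uy,
                        valid_mask = matrix(c(TRUE, FALSE), 8, 8))
  expect_true(all(is.na(velocity_magnitude(f2)[!f2$valid_mask])))
})

test_that("fit accessors expose coherent diagnostics", {
  ph <- matched_uniform_stack(shape = c(24, 24), noise_sigma = 0.005,
                              seed = 4)
  fit <- estimate_transport(subtract_background(ph$stack))
  cf <- coef(fit)
  expect_identical(nrow(cf), sum(fit$valid_mask))
  expect_true(all(is.finite(cf$D)))
  rr <- residuals(fit)
  expect_identical(dim(rr), dim(fit))
  expect_true(all(is.finite(rr[fit$valid_mask])))
  s <- summary(fit)
  expect_identical(unname(s$status_counts[["ok"]]) , sum(fit$valid_mask))
  ## simulate() from the fit reproduces a stack of the right shape
  st <- simulate(fit, initial = ph$initial, frame_times = 0:3)
  expect_s3_class(st, "conc_stack")
  expect_identical(dim(st)[3], 4L)
})
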