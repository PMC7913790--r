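## shared fixtures, built in code at test time

## matched-discretization uniform stack: 1 pre + 4 post, micro-step = frame
## interval, so the inverse stencil reproduces the forward step exactly
matched_uniform_stack <- function(shape = c(64, 64), D = 0.2,
                                  u = c(0.4, -0.2), noise_sigma = 0,
                                  seed = 1L, advection = "conservative") {
  spec <- phantom_spec("uniform", shape = shape, D = D, u = u,
                       noise_sigma = noise_sigma, seed = seed)
  simulate_phantom(spec, frame_times = 0:4, pre_contrast_count = 1,
                   micro_dt = 1, advection = advection)
}

## mask of meaningful enhancement (mirrors the pipeline's fallback ROI)
signal_mask <- function(sub, frac = 0.2) {
  mf <- apply(sub$frames, c(1L, 2L), mean)
  region_mask(mf > frac * max(mf), "tumor")
}

## 90-degree counterclockwise rotation (anatomical frame) of a matrix
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

## uniform-field transport_field helper
uniform_field <- function(shape, D = 0, ux = 0, uy = 0, spacing = 1) {
  transport_field(matrix(D, shape[1L], shape[2L]),
                  matrix(ux, shape[1L], shape[2L]),
                  matrix(uy, shape[1L], shape[2L]),
                  pixel_spacing = spacing)
}

## moment-fitted isotropic variance of a nonnegative field
moment_variance <- function(m) {
  x <- col(m) - 1; y <- row(m) - 1; s <- sum(m)
  mx <- sum(x * m) / s; my <- sum(y * m) / s
  (sum((x - mx)^2 * m) / s + sum((y - my)^2 * m) / s) / 2
}
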