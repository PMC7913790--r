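test_that("streamlines in a uniform field advance in straight steps", {
  f <- uniform_field(c(16, 16), ux = 1)
  sl <- compute_streamlines(f, cbind(2, 2), step = 0.5, max_steps = 10)[[1]]
  expect_identical(nrow(sl$points), 11L)
  expect_equal(sl$points[, 1], 2 + 0.5 * (0:10))
  expect_equal(sl$points[, 2], rep(2, 11))
  expect_identical(sl$reason, "max_steps")
})

test_that("zero fields terminate immediately with low_speed", {
  f <- uniform_field(c(16, 16))
  sl <- compute_streamlines(f, cbind(5, 5), step = 0.5)[[1]]
  expect_identical(nrow(sl$points), 1L)
  expect_identical(sl$reason, "low_speed")
  expect_error(compute_streamlines(f, cbind(30, 5)), "outside the grid")
  expect_error(compute_streamlines(f, cbind(5, 5), step = 0), "positive")
})

test_that("rigid-rotation streamlines hold their radius over a revolution", {
  n <- 64; ctr <- (n - 1) / 2
  x <- matrix(rep(0:(n - 1), each = n), n); y <- matrix(rep(0:(n - 1), n), n)
  f <- transport_field(matrix(0.1, n, n), -(y - ctr), x - ctr)
  radius <- 10
  step <- 0.01 * radius
  n_steps <- ceiling(2 * pi * radius / step)
  sl <- compute_streamlines(f, cbind(ctr + radius, ctr), step = step,
                            max_steps = n_steps)[[1]]
  r <- sqrt((sl$points[, 1] - ctr)^2 + (sl$points[, 2] - ctr)^2)
  expect_lt(max(abs(r / radius - 1)), 0.001)
})

test_that("streamline tangents align with the interpolated field", {
  set.seed(6)
  n <- 32
  ## smooth random field: low-order trig surface
  x <- matrix(rep(0:(n - 1), each = n), n) / n
  y <- matrix(rep(0:(n - 1), n), n) / n
  f <- transport_field(matrix(0.1, n, n),
                       0.5 + 0.3 * sin(2 * pi * x) * cos(pi * y),
                       0.4 + 0.3 * cos(2 * pi * y))
  sl <- compute_streamlines(f, cbind(10, 10), step = 0.1,
                            max_steps = 100)[[1]]
  p <- sl$points
  for (i in seq_len(nrow(p) - 1)) {
    d <- p[i + 1, ] - p[i, ]
    mid <- interp_velocity(f, p[i, 1], p[i, 2])
    ang <- acos(min(1, sum(d * c(mid$ux, mid$uy)) /
                      sqrt(sum(d^2) * (mid$ux^2 + mid$uy^2))))
    expect_lt(ang * 180 / pi, 1)
  }
})

test_that("rose histograms conserve pixel counts and bin by hand", {
  ## 4 pixels at 10, 100, 190, 280 degrees -> four distinct bins of 8
  ang <- c(10, 100, 190, 280) * pi / 180
  ux <- matrix(0, 16, 16); uy <- matrix(0, 16, 16)
  ux[1, 1:4] <- cos(ang); uy[1, 1:4] <- -sin(ang)  # storage y-flip
  f <- transport_field(matrix(0.1, 16, 16), ux, uy)
  rh <- rose_histogram(f, n_dir_bins = 8, mag_edges = c(0, 2))
  nz <- which(rh$counts[, 1] > 0)
  expect_identical(nz, c(1L, 3L, 5L, 7L))
  expect_true(all(rh$counts[nz, 1] == 1))
  ## static pixels counted separately; totals conserved
  expect_identical(rh$static, 16L * 16L - 4L)
  expect_equal(sum(rh$counts) + rh$static, rh$total)
})

test_that("uniform rightward flow lands entirely in the 0-degree bin", {
  f <- uniform_field(c(12, 12), ux = 1)
  rh <- rose_histogram(f, n_dir_bins = 16)
  expect_identical(sum(rh$counts), 144)
  expect_identical(sum(rh$counts[1, ]), 144)  # bin containing 0 degrees
})

test_that("rotating the field by 90 degrees shifts rose counts by n/4", {
  set.seed(23)
  n <- 24
  f <- transport_field(matrix(0.1, n, n), matrix(rnorm(n * n), n),
                       matrix(rnorm(n * n), n))
  edges <- c(0, 1, 2, 50)
  r0 <- rose_histogram(f, n_dir_bins = 16, mag_edges = edges)
  ## +90 degrees anatomically: (ux, uy) -> (uy, -ux), grid rotated with it
  fr <- transport_field(matrix(0.1, n, n), rot90ccw(f$velocity_y),
                        -rot90ccw(f$velocity_x))
  r1 <- rose_histogram(fr, n_dir_bins = 16, mag_edges = edges)
  expect_equal(r1$counts, r0$counts[c(13:16, 1:12), ])
  expect_equal(sum(r1$counts) + r1$static, r0$total)
})

test_that("rose conservation holds on random fields with invalid pixels", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 20
    vm <- matrix(runif(n * n) > 0.3, n, n)
    f <- transport_field(matrix(0.1, n, n), matrix(rnorm(n * n), n),
                         matrix(rnorm(n * n), n), valid_mask = vm)
    mk <- region_mask(matrix(runif(n * n) > 0.5, n, n), "roi")
    rh <- rose_histogram(f, mk)
    expect_equal(sum(rh$counts) + rh$static, sum(vm & mk$mask))
    tab <- rose_to_table(rh)
    expect_equal(sum(tab$count), rh$total)
  }
})

test_that("magnitude weighting replaces counts by summed speeds", {
  f <- uniform_field(c(8, 8), ux = 2)
  rh <- rose_histogram(f, n_dir_bins = 8, mag_edges = c(0, 5),
                       weight = "magnitude")
  expect_equal(sum(rh$counts), 2 * 64)
})

test_that("heat map rendering is byte-deterministic with recorded scale", {
  set.seed(2)
  m <- matrix(runif(144), 12, 12)
  m[1, 1] <- NA  # invalid pixel -> background only
  bg <- matrix(runif(144), 12, 12)
  p1 <- file.path(tempdir(), "h1.png"); p2 <- file.path(tempdir(), "h2.png")
  r1 <- render_heatmap(m, background = bg, out_path = p1)
  r2 <- render_heatmap(m, background = bg, out_path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  side <- jsonlite::read_json(paste0(p1, ".json"), simplifyVector = TRUE)
  expect_equal(side$zlim, range(m, na.rm = TRUE))
  ## hot pixel drives the auto scale
  m2 <- matrix(1, 6, 6); m2[3, 3] <- 7
  r3 <- render_heatmap(m2, out_path = file.path(tempdir(), "h3.png"))
  expect_equal(r3$zlim[2], 7)
})

test_that("quiver arrows follow the flow and decimation halves their count", {
  f <- uniform_field(c(16, 16), ux = 1)
  seg <- quiver_segments(f, decimate = 1L)
  expect_true(all(seg$x1 > seg$x0))
  expect_true(all(seg$y1 == seg$y0))
  seg2 <- quiver_segments(f, decimate = 2L)
  expect_equal(nrow(seg2), nrow(seg) / 4, tolerance = 0.01)
  ## upward anatomical flow = decreasing row index
  fu <- uniform_field(c(16, 16), uy = -1)
  segu <- quiver_segments(fu)
  expect_true(all(segu$y1 < segu$y0))
  ## rendering works with and without streamlines
  p <- file.path(tempdir(), "q.png")
  out <- render_quiver_streamlines(f, out_path = p)
  expect_true(file.exists(p))
  expect_gt(out$n_arrows, 0)
  sl <- compute_streamlines(f, cbind(2, 8), step = 0.5, max_steps = 20)
  p2 <- file.path(tempdir(), "qs.png")
  render_quiver_streamlines(f, streamlines = sl, out_path = p2)
  expect_true(file.exists(p2))
})
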