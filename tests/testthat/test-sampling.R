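# Bilinear sampling, RoI align, uncertainty scoring and point selection.

test_that("bilinear sampling reproduces node values, constants and bilinear forms", {
  set.seed(1)
  H <- 7; W <- 9
  xs <- seq_len(W) - 0.5; ys <- seq_len(H) - 0.5

  # exact at node centers
  vals <- matrix(stats::rnorm(H * W), H, W)
  g <- grid_feature(vals, 1)
  got <- bilinear_sample(g, point_set(rep(xs, each = H), rep(ys, W)))
  expect_equal(as.vector(got), as.vector(vals), tolerance = 1e-14)

  # constant preservation
  gc <- grid_feature(matrix(7, 5, 5), 2)
  expect_equal(bilinear_sample(gc, point_set(c(1.3, 7.7), c(2.1, 9.9)))[, 1], c(7, 7))

  # exact on a + b x + c y + d x y at arbitrary interior points
  a <- 0.4; b <- 1.7; cc <- -0.9; d <- 0.21
  f <- outer(ys, xs, function(y, x) a + b * x + cc * y + d * x * y)
  gf <- grid_feature(f, 1)
  px <- stats::runif(300, 0.5, W - 0.5); py <- stats::runif(300, 0.5, H - 0.5)
  got <- bilinear_sample(gf, point_set(px, py))[, 1]
  want <- a + b * px + cc * py + d * px * py
  expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-12)

  # closed-form spot check: f = 2x + 3y on a unit-stride grid at (0.5, 0.5)
  framp <- outer(ys, xs, function(y, x) 2 * x + 3 * y)
  expect_equal(bilinear_sample(grid_feature(framp, 1), point_set(0.5, 0.5))[1, 1], 2.5)

  # grids below 2x2 are rejected
  expect_error(grid_feature(matrix(1, 1, 5), 1), "2x2")
})

test_that("interpolation weights are convex at every query, including clamped ones", {
  set.seed(2)
  for (rep in 1:50) {
    H <- sample(2:12, 1); W <- sample(2:12, 1); s <- sample(c(1, 2, 4), 1)
    x <- stats::runif(20, -s, (W + 1) * s)   # deliberately includes out-of-range
    y <- stats::runif(20, -s, (H + 1) * s)
    bw <- pointcell:::bilinear_weights(c(H, W), s, x, y)
    wsum <- bw$w00 + bw$w01 + bw$w10 + bw$w11
    expect_true(all(wsum - 1 < 1e-12 & 1 - wsum < 1e-12))
    for (wn in c("w00", "w01", "w10", "w11"))
      expect_true(all(bw[[wn]] >= 0 & bw[[wn]] <= 1))
  }
})

test_that("roi_align is a mean of sub-grid bilinear samples with the expected identities", {
  # constant map -> constant output
  g <- grid_feature(array(3.5, c(8, 8, 2)), 4)
  out <- roi_align(g, pc_box(2, 2, 27, 21), out_size = 7, sampling_ratio = 2)
  expect_equal(dim(out), c(7, 7, 2))
  expect_true(all(abs(out - 3.5) < 1e-12))

  # grid-aligned box with out_size = box span and ratio 1 recovers node values
  vals <- matrix(stats::rnorm(100), 10, 10)
  gu <- grid_feature(vals, 1)
  crop <- roi_align(gu, pc_box(2, 3, 7, 8), out_size = 5, sampling_ratio = 1)
  expect_equal(crop[, , 1], vals[4:8, 3:7], tolerance = 1e-12)

  # linear ramp: output equals the ramp at output-cell sample centers
  xs <- seq_len(12) - 0.5; ys <- seq_len(12) - 0.5
  ramp <- outer(ys, xs, function(y, x) 2 * x + 3 * y)
  b <- pc_box(1.5, 2, 7.5, 8)
  out <- roi_align(grid_feature(ramp, 1), b, out_size = 3, sampling_ratio = 2)
  u <- (seq_len(3) - 0.5) / 3
  want <- outer(2 + u * 6, 1.5 + u * 6, function(y, x) 2 * x + 3 * y)
  expect_equal(out[, , 1], want, tolerance = 1e-12)

  # invariance to translating map content and box by an integer stride count
  set.seed(3)
  base <- matrix(stats::rnorm(16 * 16), 16, 16)
  shifted <- matrix(0, 16, 16); shifted[3:16, 2:16] <- base[1:14, 1:15]
  b0 <- pc_box(4, 6, 24, 22)
  b1 <- pc_box(4 + 2, 6 + 4, 24 + 2, 22 + 4)   # shift by (1, 2) grid cells * stride 2
  o0 <- roi_align(grid_feature(base, 2), b0, 4, 2)
  o1 <- roi_align(grid_feature(shifted, 2), b1, 4, 2)
  expect_equal(o0, o1, tolerance = 1e-12)

  expect_error(pc_box(5, 5, 5, 9), "positive area")
})

test_that("uncertainty is maximal at 0.5, minimal at saturation, symmetric", {
  expect_equal(uncertainty(0.5), 0)
  expect_equal(uncertainty(c(0, 1)), c(-0.5, -0.5))
  expect_equal(uncertainty(0.4), uncertainty(0.6))
  p <- matrix(c(0.1, 0.5, 0.9, 0.3), 2)
  expect_equal(dim(uncertainty(p)), dim(p))
  expect_error(uncertainty(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("topk point selection picks the most uncertain cells deterministically", {
  # the documented 1x4 example: 0.5 then 0.4 win
  prob <- matrix(c(0.1, 0.4, 0.5, 0.9), 1)
  sel <- select_points(prob, 2, "topk")
  expect_equal(sel$x, c((3 - 0.5) / 4, (2 - 0.5) / 4))
  expect_equal(sel$y, c(0.5, 0.5))

  # uniform 0.5, n = all -> every point, row-major order
  prob <- matrix(0.5, 3, 3)
  sel <- select_points(prob, 9, "topk")
  expect_equal(nrow(sel), 9)
  expect_equal(sel$x[1:3], c(0.5, 1.5, 2.5) / 3)  # first row scanned first
  expect_equal(sel$y[1:3], rep(0.5 / 3, 3))

  expect_error(select_points(prob, 10, "topk"), "exceeds")
})

test_that("oversample_random selection is seeded-deterministic and returns n points", {
  p <- matrix(stats::runif(64), 8, 8)
  set.seed(9); s1 <- select_points(p, 12, "oversample_random")
  set.seed(9); s2 <- select_points(p, 12, "oversample_random")
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 12)
  expect_true(all(s1$x >= 0 & s1$x <= 1 & s1$y >= 0 & s1$y <= 1))
})

test_that("topk selection agrees with a brute-force full sort on random grids", {
  set.seed(4)
  for (rep in 1:60) {
    H <- sample(2:16, 1); W <- sample(2:16, 1)
    # quantized probabilities so ties actually occur
    prob <- matrix(sample(seq(0, 1, by = 0.1), H * W, replace = TRUE), H, W)
    n <- sample(seq_len(H * W), 1)
    sel <- select_points(prob, n, "topk")
    # oracle: full sort of (|p - 0.5| ascending, row-major index)
    u <- as.vector(t(abs(prob - 0.5)))
    ord <- order(u, seq_along(u))[seq_len(n)]
    oi <- (ord - 1) %/% W + 1; oj <- (ord - 1) %% W + 1
    expect_equal(sel$x, (oj - 0.5) / W)
    expect_equal(sel$y, (oi - 0.5) / H)
  }
})
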