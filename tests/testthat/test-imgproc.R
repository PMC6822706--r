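test_that("inversion complements intensities and is an involution", {
  expect_equal(invert_image(matrix(0, 3, 3)), matrix(1, 3, 3))
  expect_equal(invert_image(matrix(0.3, 1, 1))[1, 1], 0.7)
  set.seed(11)
  x <- matrix(runif(64), 8, 8)
  expect_equal(invert_image(invert_image(x)), x)
  expect_error(invert_image(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("background subtraction matches an explicit Gaussian convolution", {
  # uniform image: any radius gives zeros
  expect_equal(gaussian_background_subtract(matrix(0.42, 20, 20), 5),
               matrix(0, 20, 20))
  # radius 0: image minus itself
  x <- matrix(runif(100, 0, 1), 10, 10)
  expect_equal(gaussian_background_subtract(x, 0), matrix(0, 10, 10))
  expect_error(gaussian_background_subtract(x, -1), ">= 0")

  # single bright pixel: oracle is a separable sampled-Gaussian kernel
  # (support 3 sigma) applied by direct convolution
  sigma <- 1
  img <- matrix(0, 15, 15); img[8, 8] <- 1
  out <- gaussian_background_subtract(img, sigma)
  hw <- ceiling(3 * sigma)
  g <- dnorm(-hw:hw, sd = sigma); g <- g / sum(g)
  K <- outer(g, g)
  expect_equal(out[8, 8], 1 - K[hw + 1, hw + 1], tolerance = 1e-6)
  # off-peak pixels had value 0, so subtraction clips them to 0
  expect_equal(out[8, 9], 0)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("hysteresis matches its stated examples", {
  row <- matrix(c(0.9, 0.5, 0.2, 0.5, 0.9), 1)
  expect_equal(hysteresis_binarize(row, 0.8, 0.4)[1, ],
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # weak pixels without a strong seed stay background
  expect_equal(hysteresis_binarize(matrix(c(0, 0.5, 0.5), 1), 0.8, 0.4),
               matrix(FALSE, 1, 3))
  # b1 = b2 degenerates to a plain threshold
  set.seed(21)
  x <- matrix(runif(400), 20, 20)
  expect_equal(hysteresis_binarize(x, 0.5, 0.5), x > 0.5)
  expect_error(hysteresis_binarize(x, 0.3, 0.6), "b2 <= b1")
})

test_that("hysteresis equals the BFS flood-fill oracle exhaustively on small grids", {
  b1 <- 0.8; b2 <- 0.4
  for (g in all_three_level_grids(2, 3))
    expect_equal(hysteresis_binarize(g, b1, b2), hysteresis_oracle(g, b1, b2))
  # randomized larger grids
  set.seed(31)
  lv <- c(0.1, 0.6, 0.95)
  for (i in 1:300) {
    g <- matrix(sample(lv, 16, replace = TRUE), 4, 4)
    expect_equal(hysteresis_binarize(g, b1, b2), hysteresis_oracle(g, b1, b2))
  }
})

test_that("hysteresis is monotone in both thresholds", {
  set.seed(41)
  for (i in 1:20) {
    x <- matrix(runif(256), 16, 16)
    hi <- hysteresis_binarize(x, 0.8, 0.5)
    expect_true(all(hi <= hysteresis_binarize(x, 0.7, 0.5)))  # lower b1
    expect_true(all(hi <= hysteresis_binarize(x, 0.8, 0.3)))  # lower b2
  }
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[cbind(1:4, 1:4)] <- TRUE  # diagonal chain
  m[5, 1] <- TRUE             # separate pixel
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(length(unique(lab[cbind(1:4, 1:4)])), 1)
})

test_that("3x3 dilation follows its definition and lattice properties", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  d <- dilate_3x3(m)
  expect_equal(sum(d), 9)
  expect_true(all(d[2:4, 2:4]))
  expect_equal(dilate_3x3(matrix(FALSE, 4, 4)), matrix(FALSE, 4, 4))
  # one-pixel gap on a row is closed
  g <- matrix(FALSE, 3, 7); g[2, 2] <- TRUE; g[2, 4] <- TRUE
  expect_equal(max(label_components(dilate_3x3(g))), 1)
  # extensive and increasing
  set.seed(51)
  for (i in 1:10) {
    a <- matrix(runif(144) < 0.2, 12, 12)
    b <- a | (matrix(runif(144) < 0.1, 12, 12))
    expect_true(all(a <= dilate_3x3(a)))
    expect_true(all(dilate_3x3(a) <= dilate_3x3(b)))
  }
})

test_that("thinning produces single-pixel-wide topology-preserving skeletons", {
  # filled 3x11 rectangle reduces to one path with two endpoints
  m <- matrix(FALSE, 9, 17); m[4:6, 4:14] <- TRUE
  sk <- thin_skeleton(m)
  g <- skeleton_to_graph(sk)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sum(g$nodes$degree == 1), 2)
  # empty image and already-thin line are fixed points
  expect_equal(thin_skeleton(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
  ln <- matrix(FALSE, 5, 12); ln[3, 2:11] <- TRUE
  expect_equal(thin_skeleton(ln), ln)
  # connected-component count is preserved on random hole-free blobs
  set.seed(61)
  for (i in 1:8) {
    bw <- matrix(FALSE, 64, 64)
    for (k in 1:5) {
      cr <- sample(10:54, 1); cc <- sample(10:54, 1)
      bw <- bw | draw_disk(64, 64, cr, cc, sample(3:7, 1))
    }
    expect_equal(max(label_components(thin_skeleton(bw))),
                 max(label_components(bw)))
  }
})

test_that("skeleton cleaning removes small components and prunes short branches", {
  # 5-pixel component below the size cutoff disappears
  m <- matrix(FALSE, 10, 10); m[5, 3:7] <- TRUE
  expect_equal(sum(clean_skeleton(m, 10)), 0)
  # min_hyphae = 0 is the identity
  expect_equal(clean_skeleton(m, 0), m)
  # Y with arms 20, 20, 3: short arm pruned, long arms merge into one path
  y <- matrix(FALSE, 48, 48)
  y <- draw_segment(y, 24, 24, 4, 24)    # 20 up
  y <- draw_segment(y, 24, 24, 44, 24)   # 20 down
  y <- draw_segment(y, 24, 24, 24, 27)   # 3 right
  cl <- clean_skeleton(y, 5)
  g <- skeleton_to_graph(cl)
  expect_equal(sum(g$nodes$degree == 1), 2)
  expect_equal(nrow(g$edges), 1)
  expect_false(any(cl[24, 26:27]))
  # never grows, and is idempotent
  set.seed(71)
  for (i in 1:6) {
    bw <- matrix(FALSE, 48, 48)
    for (k in 1:4)
      bw <- draw_segment(bw, sample(5:43, 1), sample(5:43, 1),
                         sample(5:43, 1), sample(5:43, 1))
    sk <- thin_skeleton(bw)
    cl1 <- clean_skeleton(sk, 8)
    expect_lte(sum(cl1), sum(sk))
    expect_equal(clean_skeleton(cl1, 8), cl1)
  }
})

test_that("mask subtraction is set difference", {
  img <- matrix(TRUE, 4, 4)
  expect_equal(sum(subtract_mask(img, matrix(TRUE, 4, 4))), 0)
  expect_equal(subtract_mask(img, matrix(FALSE, 4, 4)), img)
  ring <- matrix(FALSE, 6, 6)
  ring[c(1, 6), ] <- TRUE; ring[, c(1, 6)] <- TRUE
  full <- matrix(TRUE, 6, 6)
  out <- subtract_mask(full, ring)
  expect_true(all(out[2:5, 2:5]))
  expect_equal(sum(out), 16)
  expect_error(subtract_mask(img, matrix(FALSE, 3, 3)), "shape")
})
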