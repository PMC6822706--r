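test_that("straight and diagonal lines map to exact two-node graphs", {
  sk <- matrix(FALSE, 5, 12); sk[3, 2:11] <- TRUE  # 10 px horizontal
  g <- skeleton_to_graph(sk)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$length_px, 9)
  m <- graph_metrics(g)
  expect_equal(m$total_length, 9)
  expect_equal(m$n_tips, 2)
  expect_equal(m$hull_area, 0)  # collinear nodes

  dg <- matrix(FALSE, 14, 14); dg[cbind(2:11, 2:11)] <- TRUE
  gd <- skeleton_to_graph(dg)
  expect_equal(gd$edges$length_px, 9 * sqrt(2))
})

test_that("a Y skeleton yields three tips, one junction and three edges", {
  y <- draw_y_skeleton(arms = c(10, 10, 10))  # three 11-px arms incl. center
  g <- skeleton_to_graph(y)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(sum(g$nodes$degree == 1), 3)
  expect_equal(sum(g$nodes$degree == 3), 1)
  expect_equal(nrow(g$edges), 3)
})

test_that("closed loops and isolated pixels are represented correctly", {
  ring <- matrix(FALSE, 12, 12)
  ring[3, 3:9] <- TRUE; ring[9, 3:9] <- TRUE
  ring[3:9, 3] <- TRUE; ring[3:9, 9] <- TRUE
  g <- skeleton_to_graph(ring)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$from, g$edges$to)      # self-loop
  expect_equal(g$nodes$degree, 2)             # self-loop counts twice
  expect_equal(graph_metrics(g)$n_tips, 0)

  dot <- matrix(FALSE, 5, 5); dot[3, 3] <- TRUE
  gd <- skeleton_to_graph(dot)
  expect_equal(nrow(gd$nodes), 1)
  expect_equal(gd$nodes$degree, 0)
  expect_equal(graph_metrics(gd)$n_tips, 0)   # isolated nodes are not tips

  ge <- skeleton_to_graph(matrix(FALSE, 6, 6))
  expect_equal(nrow(ge$nodes), 0)
  me <- graph_metrics(ge)
  expect_equal(me$total_length, 0)
  expect_equal(me$hull_area, 0)
})

test_that("edge paths jointly cover the skeleton exactly once", {
  for (sk in list(draw_y_skeleton(arms = c(12, 9, 15)),
                  { m <- matrix(FALSE, 30, 30)
                    m <- draw_segment(m, 5, 5, 5, 25)
                    m <- draw_segment(m, 15, 3, 28, 16); m })) {
    g <- skeleton_to_graph(sk)
    covered <- unique(do.call(rbind, g$paths))
    expect_equal(nrow(covered), sum(sk))
    expect_true(all(sk[covered]))
  }
})

test_that("adding a disjoint n-pixel segment adds length n-1 and two tips", {
  sk <- draw_y_skeleton(arms = c(10, 10, 10))
  m0 <- graph_metrics(skeleton_to_graph(sk))
  sk2 <- sk; sk2[40, 10:21] <- TRUE  # disjoint 12-px horizontal segment
  m1 <- graph_metrics(skeleton_to_graph(sk2))
  expect_equal(m1$total_length - m0$total_length, 11)
  expect_equal(m1$n_tips - m0$n_tips, 2)
})

test_that("hull area matches the gift-wrapping oracle and the triangle example", {
  tri <- fungalfeatures:::new_mycelial_graph(
    nodes = data.frame(id = 1:3, row = c(0, 0, 3), col = c(0, 4, 0),
                       degree = c(1, 1, 1)),
    edges = data.frame(from = integer(0), to = integer(0),
                       length_px = numeric(0)),
    paths = list(), dim = c(10, 10))
  expect_equal(graph_metrics(tri)$hull_area, 6)

  set.seed(81)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    nodes <- data.frame(id = seq_len(n), row = runif(n, 0, 40),
                        col = runif(n, 0, 40), degree = rep(1, n))
    g <- fungalfeatures:::new_mycelial_graph(
      nodes, data.frame(from = integer(0), to = integer(0),
                        length_px = numeric(0)), list(), c(50, 50))
    expect_equal(graph_metrics(g)$hull_area,
                 hull_area_oracle(nodes$col, nodes$row), tolerance = 1e-9)
    # invariant under node permutation
    perm <- sample(n)
    gp <- fungalfeatures:::new_mycelial_graph(
      nodes[perm, ], g$edges, list(), c(50, 50))
    expect_equal(graph_metrics(gp)$hull_area, graph_metrics(g)$hull_area)
  }
})

test_that("planted trees satisfy the forest relation and drive exact recovery", {
  sc <- generate_mycelium_scene(n_branches = 12, size = c(512, 512),
                                seed = 5)
  pg <- sc$planted_graph
  # forest: edges = nodes - components (planted trees are connected)
  expect_equal(nrow(pg$edges), nrow(pg$nodes) - 1)
  a <- analyze_mycelium_image(sc$image, preset_params("mycelium"))
  expect_equal(a$metrics$n_tips, sum(pg$nodes$degree == 1))
  expect_equal(a$metrics$total_length, sum(pg$edges$length_px),
               tolerance = 0.1)
})

test_that("blank images give empty graphs and zero metrics", {
  a <- analyze_mycelium_image(matrix(0.05, 128, 128),
                              preset_params("mycelium"))
  expect_equal(nrow(a$graph$nodes), 0)
  expect_equal(a$metrics$total_length, 0)
  expect_equal(a$metrics$n_tips, 0)
  expect_equal(a$metrics$hull_area, 0)
})

test_that("an illumination gradient does not change the recovered tip count", {
  flat <- generate_mycelium_scene(n_branches = 12, size = c(512, 512),
                                  gradient_amplitude = 0, seed = 6)
  grad <- generate_mycelium_scene(n_branches = 12, size = c(512, 512),
                                  gradient_amplitude = 0.12, seed = 6)
  p <- preset_params("mycelium")
  expect_equal(analyze_mycelium_image(grad$image, p)$metrics$n_tips,
               analyze_mycelium_image(flat$image, p)$metrics$n_tips)
})

test_that("time series analysis is deterministic, ordered and monotone", {
  p <- preset_params("mycelium")
  sc <- generate_mycelium_scene(n_branches = 8, size = c(384, 384), seed = 7)
  same <- analyze_time_series(list(sc$image, sc$image, sc$image), p)
  expect_equal(nrow(same), 3)
  expect_equal(same$timepoint, 1:3)
  expect_equal(same$total_length, rep(same$total_length[1], 3))
  expect_equal(same$n_tips, rep(same$n_tips[1], 3))

  expect_equal(nrow(analyze_time_series(list(), p)), 0)
  expect_error(analyze_time_series(list(matrix(0, 4, 4), matrix(0, 5, 5)), p),
               "shape")

  frames <- generate_growth_series(n_frames = 3, growth_per_frame = 4,
                                   seed = 8, size = c(512, 512))
  ts <- analyze_time_series(lapply(frames, `[[`, "image"), p)
  expect_true(all(diff(ts$total_length) >= 0))
})

test_that("mask subtraction removes edge artifacts from the analysis", {
  sc <- generate_mycelium_scene(n_branches = 8, size = c(384, 384), seed = 9)
  img <- sc$image
  img[, 1:12] <- 0.9  # bright well edge
  mask <- matrix(FALSE, 384, 384); mask[, 1:20] <- TRUE
  p <- preset_params("mycelium")
  with_mask <- analyze_mycelium_image(img, p, mask)
  expect_false(any(with_mask$skeleton[, 1:20]))
  expect_error(analyze_mycelium_image(img, p, matrix(FALSE, 10, 10)),
               "shape")
})
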