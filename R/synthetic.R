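# Synthetic micrograph generator with exact planted ground truth.
#
# Every generator is deterministic under its seed, restores the caller's
# random-number state, and returns a `planted_scene`: the rendered image,
# the ground-truth foreground mask, a descriptor table of the planted
# objects and (for mycelium scenes) the exact generative tree as a
# `mycelial_graph`. The planted descriptors are the recovery oracle for the
# quantification pipelines.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

new_planted_scene <- function(image, truth_mask, objects, seed,
                              planted_graph = NULL) {
  structure(list(image = image, truth_mask = truth_mask, objects = objects,
                 planted_graph = planted_graph, seed = seed),
            class = "planted_scene")
}

#' @export
print.planted_scene <- function(x, ...) {
  cat("Planted scene", paste(dim(x$image), collapse = "x"), "(seed",
      x$seed, "):", nrow(x$objects), "objects\n")
  invisible(x)
}

# Pixel set of a rotated filled ellipse; semi-axes a >= b, orientation
# theta (radians, major axis measured from the column direction).
rasterize_ellipse <- function(nr, nc, cr, ccol, a, b, theta) {
  half <- ceiling(a) + 1L
  rs <- max(1L, floor(cr - half)):min(nr, ceiling(cr + half))
  cs <- max(1L, floor(ccol - half)):min(nc, ceiling(ccol + half))
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - ccol)
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  cbind(rs[w[, 1]], cs[w[, 2]])
}

# Pixel set of a capsule (thick line segment): all pixels within
# `half_width` of the segment of half-length `half_len` through the center
# at angle `theta`. Constant width keeps thin bars connected when
# rasterized, unlike the vanishing tips of a very flat ellipse.
rasterize_capsule <- function(nr, nc, cr, ccol, half_len, half_width,
                              theta) {
  half <- ceiling(half_len + half_width) + 1L
  rs <- max(1L, floor(cr - half)):min(nr, ceiling(cr + half))
  cs <- max(1L, floor(ccol - half)):min(nc, ceiling(ccol + half))
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - ccol)
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  du <- pmax(abs(u) - half_len, 0)
  inside <- du^2 + v^2 <= half_width^2
  w <- which(inside, arr.ind = TRUE)
  cbind(rs[w[, 1]], cs[w[, 2]])
}

# Deduplicate consecutive identical pixels of a rounded polyline.
dedupe_path <- function(px) {
  if (nrow(px) < 2) return(px)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px[keep, , drop = FALSE]
}

step_rule_length <- function(px) {
  if (nrow(px) < 2) return(0)
  d <- diff(px)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

any_in_window <- function(mask, r, c, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  rs <- max(1L, r - radius):min(nr, r + radius)
  cs <- max(1L, c - radius):min(nc, c + radius)
  any(mask[rs, cs])
}

#' Generate a spore scene with planted ground truth
#'
#' Plants non-overlapping ellipses ("spores") with sampled axes and
#' orientation, plus optional distractors that a calibrated pipeline must
#' reject: thin high-elongation bars emulating hyphal fragments and 1–3
#' pixel dots emulating dust. Placement uses rejection sampling with a
#' clearance margin so planted objects never touch, making the planted
#' count an exact oracle for [count_spores()].
#'
#' Intensities follow the requested polarity — `dark_on_bright` renders
#' spores at ~0.25 on a ~0.9 brightfield background, `bright_on_dark`
#' renders them at ~0.8 on ~0.1 (the fluorescence convention used by
#' [measure_spores()]) — with additive Gaussian noise, clipped to `[0, 1]`.
#'
#' @param n_spores Number of spores to plant.
#' @param axis_range Range of the full major-axis length, pixels.
#' @param elongation_range Range of planted elongation (`1 - minor/major`).
#' @param polarity `"dark_on_bright"` (brightfield) or `"bright_on_dark"`
#'   (stained fluorescence).
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param n_distractors Number of distractor objects (split between bars
#'   and dust dots).
#' @param size Image shape `c(rows, cols)`.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   scene exactly.
#' @return A `planted_scene`; `objects` holds one row per planted object
#'   with its type, center, axes and orientation.
#' @export
generate_spore_scene <- function(n_spores = 100, axis_range = c(10, 18),
                                 elongation_range = c(0, 0.4),
                                 polarity = c("dark_on_bright",
                                              "bright_on_dark"),
                                 noise_sigma = 0.05, n_distractors = 10,
                                 size = c(1024, 1024), seed = 1) {
  polarity <- match.arg(polarity)
  stopifnot(n_spores >= 0, noise_sigma >= 0, all(size >= 32))
  if (n_spores * pi * (axis_range[2] / 2)^2 > 0.3 * prod(size))
    stop("infeasible packing: requested spore area exceeds 30% of the image")
  with_seed(seed, {
    nr <- size[1]; nc <- size[2]
    occ <- matrix(FALSE, nr, nc)
    objects <- list()
    # candidate pixels are accepted only if no existing object lies within
    # a 3-pixel (Chebyshev) clearance of them, so planted objects never
    # touch and segmentations cannot merge them
    is_clear <- function(px, gap = 3L) {
      r0 <- max(1L, min(px[, 1]) - gap); r1 <- min(nr, max(px[, 1]) + gap)
      c0 <- max(1L, min(px[, 2]) - gap); c1 <- min(nc, max(px[, 2]) + gap)
      sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      sub[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
      subd <- EBImage::dilate(sub * 1,
                              EBImage::makeBrush(2 * gap + 1, "box")) > 0
      !any(occ[r0:r1, c0:c1] & subd)
    }
    place <- function(type, a, b, theta, shape = "ellipse", tries = 200) {
      margin <- ceiling(a) + 4
      for (t in seq_len(tries)) {
        cr <- runif(1, margin, nr - margin)
        ccol <- runif(1, margin, nc - margin)
        px <- if (shape == "ellipse")
          rasterize_ellipse(nr, nc, cr, ccol, a, b, theta)
        else rasterize_capsule(nr, nc, cr, ccol, a, b, theta)
        if (nrow(px) == 0L)  # sub-pixel object: keep its center pixel
          px <- matrix(as.integer(round(c(cr, ccol))), 1L)
        if (!is_clear(px)) next
        occ[cbind(px[, 1], px[, 2])] <<- TRUE
        objects[[length(objects) + 1L]] <<- data.frame(
          type = type, row = cr, col = ccol, major = 2 * a, minor = 2 * b,
          theta = theta)
        return(px)
      }
      stop("could not place object after ", tries, " tries; ",
           "reduce object count or density")
    }
    spore_px <- list()
    for (i in seq_len(n_spores)) {
      L <- runif(1, axis_range[1], axis_range[2])
      e <- runif(1, elongation_range[1], elongation_range[2])
      a <- L / 2; b <- a * (1 - e)
      spore_px[[i]] <- place("spore", a, b, runif(1, 0, pi))
    }
    distractor_px <- list()
    n_bars <- ceiling(n_distractors / 2)
    for (i in seq_len(n_distractors)) {
      if (i <= n_bars) {  # thin bar: hyphal-fragment mimic, capsule shape
        len <- runif(1, 40, 80)
        distractor_px[[i]] <- place("hypha_fragment", len / 2, 1.5,
                                    runif(1, 0, pi), shape = "capsule")
      } else {            # dust dot, below any sensible min_area
        distractor_px[[i]] <- place("dust", runif(1, 0.6, 1.0), 0.6,
                                    runif(1, 0, pi))
      }
    }
    bg <- if (polarity == "dark_on_bright") 0.9 else 0.1
    obj_base <- if (polarity == "dark_on_bright") 0.25 else 0.8
    img <- matrix(bg, nr, nc)
    paint <- function(px) {
      v <- obj_base + runif(1, -0.05, 0.05)
      img[cbind(px[, 1], px[, 2])] <<- v
    }
    for (px in spore_px) paint(px)
    for (px in distractor_px) paint(px)
    truth <- occ
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
    img[img < 0] <- 0; img[img > 1] <- 1
    obj_df <- if (length(objects)) do.call(rbind, objects) else
      data.frame(type = character(0), row = numeric(0), col = numeric(0),
                 major = numeric(0), minor = numeric(0), theta = numeric(0))
    new_planted_scene(img, truth, obj_df, seed)
  })
}

# Random branching tree grown from a root point. Each branch is a smooth
# unit-step polyline; completed branches spawn two children at diverging
# angles (FIFO, so growth is breadth-first and balanced). A branch stops
# early at the image margin or when its head comes within `avoid` pixels
# (Chebyshev) of previously drawn centerline, so planted tips stay
# separated from foreign branches. Collision checking is suspended within
# 20 px of the branch origin, where proximity to the parent is expected.
grow_tree <- function(n_branches, branch_length_range, size,
                      margin = 10, step_sd = 0.05,
                      branch_angle = c(0.5, 0.9), min_branch = 30,
                      avoid = 7) {
  nr <- size[1]; nc <- size[2]
  centerline <- matrix(FALSE, nr, nc)
  node_r <- stats::runif(1, 0.35 * nr, 0.65 * nr)
  node_c <- stats::runif(1, 0.35 * nc, 0.65 * nc)
  e_from <- integer(0); e_to <- integer(0); e_len <- numeric(0)
  e_paths <- list()
  queue_node <- 1L
  queue_angle <- stats::runif(1, 0, 2 * pi)
  n_drawn <- 0L
  grow_one <- function(start, angle) {
    pos <- c(node_r[start], node_c[start])
    origin <- pos
    L <- round(stats::runif(1, branch_length_range[1],
                            branch_length_range[2]))
    pts <- matrix(NA_real_, L + 1L, 2L)
    pts[1, ] <- pos
    n_ok <- 0L
    for (i in seq_len(L)) {
      angle <- angle + stats::rnorm(1, 0, step_sd)
      cand <- pos + c(sin(angle), cos(angle))
      rc <- round(cand)
      if (rc[1] < margin || rc[1] > nr - margin ||
          rc[2] < margin || rc[2] > nc - margin) break
      if (max(abs(cand - origin)) > 20 &&
          any_in_window(centerline, rc[1], rc[2], avoid)) break
      pos <- cand
      pts[i + 1L, ] <- pos
      n_ok <- i
    }
    if (n_ok < min_branch) return(NULL)
    list(pts = pts[seq_len(n_ok + 1L), , drop = FALSE], angle = angle)
  }
  while (length(queue_node) && n_drawn < n_branches) {
    start <- queue_node[1]; ang0 <- queue_angle[1]
    queue_node <- queue_node[-1]; queue_angle <- queue_angle[-1]
    br <- NULL
    ang <- ang0
    for (try in 1:4) {
      br <- grow_one(start, ang)
      if (!is.null(br)) break
      ang <- ang0 + stats::rnorm(1, 0, 0.4)
    }
    if (is.null(br)) next
    px <- dedupe_path(round(br$pts))
    centerline[cbind(px[, 1], px[, 2])] <- TRUE
    node_r <- c(node_r, br$pts[nrow(br$pts), 1])
    node_c <- c(node_c, br$pts[nrow(br$pts), 2])
    end_id <- length(node_r)
    k <- length(e_from) + 1L
    e_from[k] <- start; e_to[k] <- end_id
    e_len[k] <- step_rule_length(px)
    e_paths[[k]] <- px
    n_drawn <- n_drawn + 1L
    spread1 <- stats::runif(1, branch_angle[1], branch_angle[2])
    spread2 <- stats::runif(1, branch_angle[1], branch_angle[2])
    queue_node <- c(queue_node, end_id, end_id)
    queue_angle <- c(queue_angle, br$angle + spread1, br$angle - spread2)
  }
  deg <- tabulate(c(e_from, e_to), nbins = length(node_r))
  nodes <- data.frame(id = seq_along(node_r), row = node_r, col = node_c,
                      degree = deg)
  edges <- data.frame(from = e_from, to = e_to, length_px = e_len)
  new_mycelial_graph(nodes, edges, e_paths, c(nr, nc))
}

# Shared renderer for mycelium scenes: rasterizes the first `upto` branch
# paths, dilates to the drawn width, and composes intensity field,
# illumination gradient and noise. The truth mask is exactly the dilated
# centerline.
render_mycelium <- function(tree, upto, branch_width, gradient_amplitude,
                            noise_sigma, size, optics) {
  nr <- size[1]; nc <- size[2]
  centerline <- matrix(FALSE, nr, nc)
  for (k in seq_len(upto)) {
    px <- tree$paths[[k]]
    centerline[cbind(px[, 1], px[, 2])] <- TRUE
  }
  mask <- EBImage::dilate(centerline * 1,
                          EBImage::makeBrush(branch_width, "disc")) > 0
  rn <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
  cn <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  field <- 0.78 + 0.12 * sin(rn * nr / 57 + optics$ph1) *
                         cos(cn * nc / 71 + optics$ph2)
  img <- matrix(0.05, nr, nc)
  img[mask] <- field[mask]
  if (gradient_amplitude > 0) {
    proj <- cos(optics$gth) * cn + sin(optics$gth) * rn
    img <- img + gradient_amplitude *
      (0.5 + 0.5 * sin(1.5 * pi * proj + optics$gph))
  }
  if (noise_sigma > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, truth = mask)
}

subset_tree <- function(tree, upto) {
  edges <- tree$edges[seq_len(upto), , drop = FALSE]
  deg <- tabulate(c(edges$from, edges$to), nbins = nrow(tree$nodes))
  nodes <- tree$nodes
  nodes$degree <- deg
  used <- deg > 0
  new_mycelial_graph(nodes[used, , drop = FALSE], edges,
                     tree$paths[seq_len(upto)], tree$dim)
}

#' Generate a mycelium scene from a planted random tree
#'
#' Grows a random branching tree of smooth unit-step polylines from a root
#' point (the generative model for a young colony), rasterizes its
#' centerlines, dilates them to `branch_width`, and renders a fluorescence-
#' convention image: bright hyphae with slight intensity variation on a
#' dark background, plus a low-frequency illumination gradient and additive
#' Gaussian noise. Branches avoid running into each other, so planted tips
#' remain distinct structures.
#'
#' The exact generative tree is returned as `planted_graph` (a
#' `mycelial_graph`), so tip counts and total centerline length are known
#' without any image processing — the recovery oracle for
#' [analyze_mycelium_image()]. The truth mask (dilated centerline) is the
#' ground truth for segmentation-accuracy evaluation.
#'
#' @param n_branches Number of branch segments to grow.
#' @param branch_length_range Range of branch lengths, pixels.
#' @param branch_width Drawn hyphal width, odd number of pixels.
#' @param gradient_amplitude Peak amplitude of the illumination gradient.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param size Image shape `c(rows, cols)`.
#' @param seed Integer seed.
#' @return A `planted_scene` with `planted_graph` set; `objects` has one
#'   row per branch.
#' @export
generate_mycelium_scene <- function(n_branches = 24,
                                    branch_length_range = c(60, 140),
                                    branch_width = 3,
                                    gradient_amplitude = 0.1,
                                    noise_sigma = 0.05,
                                    size = c(1024, 1024), seed = 1) {
  stopifnot(n_branches >= 1, branch_width %% 2 == 1, all(size >= 64))
  with_seed(seed, {
    tree <- grow_tree(n_branches, branch_length_range, size)
    optics <- list(ph1 = stats::runif(1, 0, 2 * pi),
                   ph2 = stats::runif(1, 0, 2 * pi),
                   gth = stats::runif(1, 0, 2 * pi),
                   gph = stats::runif(1, 0, 2 * pi))
    sc <- render_mycelium(tree, nrow(tree$edges), branch_width,
                          gradient_amplitude, noise_sigma, size, optics)
    objects <- data.frame(type = rep("hypha", nrow(tree$edges)),
                          branch = seq_len(nrow(tree$edges)),
                          length_px = tree$edges$length_px)
    new_planted_scene(sc$image, sc$truth, objects, seed,
                      planted_graph = tree)
  })
}

#' Generate a monotone growth series of mycelium scenes
#'
#' Grows one tree and renders nested prefixes of its branches as
#' consecutive frames, emulating hourly imaging of a growing colony: frame
#' `k` contains the first `k * growth_per_frame` branches, so each frame's
#' planted structure is a supergraph of the previous frame's and planted
#' total length increases monotonically. Illumination and intensity fields
#' are fixed across frames; noise is redrawn per frame.
#'
#' @param n_frames Number of frames.
#' @param growth_per_frame Branches added per frame.
#' @param seed Integer seed.
#' @inheritParams generate_mycelium_scene
#' @return List of `planted_scene`s, one per frame, each with its own
#'   `planted_graph` prefix.
#' @export
generate_growth_series <- function(n_frames = 6, growth_per_frame = 4,
                                   seed = 1,
                                   branch_length_range = c(60, 140),
                                   branch_width = 3,
                                   gradient_amplitude = 0.1,
                                   noise_sigma = 0.05,
                                   size = c(1024, 1024)) {
  stopifnot(n_frames >= 1, growth_per_frame >= 1)
  with_seed(seed, {
    tree <- grow_tree(n_frames * growth_per_frame, branch_length_range, size)
    optics <- list(ph1 = stats::runif(1, 0, 2 * pi),
                   ph2 = stats::runif(1, 0, 2 * pi),
                   gth = stats::runif(1, 0, 2 * pi),
                   gph = stats::runif(1, 0, 2 * pi))
    total <- nrow(tree$edges)
    lapply(seq_len(n_frames), function(k) {
      upto <- min(total, k * growth_per_frame)
      sc <- render_mycelium(tree, upto, branch_width, gradient_amplitude,
                            noise_sigma, size, optics)
      sub <- subset_tree(tree, upto)
      objects <- data.frame(type = rep("hypha", upto),
                            branch = seq_len(upto),
                            length_px = sub$edges$length_px)
      new_planted_scene(sc$image, sc$truth, objects, seed,
                        planted_graph = sub)
    })
  })
}

# Draw one trap cluster: concentric-ish rings of width ~2 around the
# center plus radial spokes that guarantee a single connected component,
# grown until the cluster exceeds `min_px` pixels.
draw_trap_cluster <- function(nr, nc, cr, ccol, min_px = 2200) {
  half <- 34L
  rs <- max(1L, cr - half):min(nr, cr + half)
  cs <- max(1L, ccol - half):min(nc, ccol + half)
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - ccol)
  local <- matrix(FALSE, length(rs), length(cs))
  add_ring <- function() {
    orr <- stats::runif(1, -10, 10); occ_ <- stats::runif(1, -10, 10)
    rad <- stats::runif(1, 8, 18)
    d <- sqrt((dr - orr)^2 + (dc - occ_)^2)
    local <<- local | (abs(d - rad) <= 1)
  }
  for (i in 1:12) add_ring()
  # spokes through the center connect every ring
  for (th in stats::runif(6, 0, pi)) {
    t <- seq(-28, 28, by = 0.5)
    pr <- round(t * sin(th)); pc <- round(t * cos(th))
    ok <- pr >= min(dr) & pr <= max(dr) & pc >= min(dc) & pc <= max(dc)
    ij <- unique(cbind(pr[ok] - min(dr) + 1L, pc[ok] - min(dc) + 1L))
    for (ddr in -1:1) for (ddc in -1:1) {
      rr <- ij[, 1] + ddr; cc2 <- ij[, 2] + ddc
      ok2 <- rr >= 1 & rr <= nrow(local) & cc2 >= 1 & cc2 <= ncol(local)
      local[cbind(rr[ok2], cc2[ok2])] <- TRUE
    }
  }
  while (sum(local) < min_px) add_ring()
  w <- which(local, arr.ind = TRUE)
  cbind(rs[w[, 1]], cs[w[, 2]])
}

#' Generate a trap scene: dense clusters on a sparse hyphal background
#'
#' Plants `n_traps` dense ring-and-spoke clusters (emulating the compact
#' adhesive networks of nematode-trapping fungi) over `background_hyphae`
#' long thin hyphal strands, rendered in the brightfield convention: traps
#' darkest, hyphae intermediate, background bright. Traps are placed with
#' clearance from the strands and from each other so the planted trap count
#' is an exact oracle for [count_traps()] under trap-scale gates
#' (`preset_params("traps")`); every cluster exceeds 2200 pixels, well
#' above a single hypha cross-section.
#'
#' @param n_traps Number of trap clusters.
#' @param background_hyphae Number of background strands.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param size Image shape `c(rows, cols)`.
#' @param seed Integer seed.
#' @return A `planted_scene`; `objects` lists trap centers (type
#'   `"trap"`) and strands (type `"hypha"`).
#' @export
generate_trap_scene <- function(n_traps = 10, background_hyphae = 8,
                                noise_sigma = 0.03, size = c(1024, 1024),
                                seed = 1) {
  stopifnot(n_traps >= 0, background_hyphae >= 0, all(size >= 256))
  with_seed(seed, {
    nr <- size[1]; nc <- size[2]
    centerhy <- matrix(FALSE, nr, nc)
    for (h in seq_len(background_hyphae)) {
      r0 <- stats::runif(1, 0.08 * nr, 0.92 * nr)
      ang <- stats::runif(1, -0.3, 0.3)
      pos <- c(r0, 10)
      pts <- list(pos)
      for (i in seq_len(nc)) {
        ang <- ang + stats::rnorm(1, 0, 0.02)
        cand <- pos + c(sin(ang), cos(ang))
        rc <- round(cand)
        if (rc[1] < 8 || rc[1] > nr - 8 || rc[2] > nc - 8) break
        if (i > 15 && any_in_window(centerhy, rc[1], rc[2], 8)) break
        pos <- cand
        pts[[length(pts) + 1L]] <- pos
      }
      px <- dedupe_path(round(do.call(rbind, pts)))
      centerhy[cbind(px[, 1], px[, 2])] <- TRUE
    }
    hymask <- EBImage::dilate(centerhy * 1, EBImage::makeBrush(3, "disc")) > 0
    trapmask <- matrix(FALSE, nr, nc)
    centers <- list()
    occupied <- function() centerhy | trapmask
    for (t in seq_len(n_traps)) {
      placed <- FALSE
      occ <- occupied()
      for (try in seq_len(400)) {
        cr <- round(stats::runif(1, 50, nr - 50))
        ccol <- round(stats::runif(1, 50, nc - 50))
        if (any_in_window(occ, cr, ccol, 45)) next
        px <- draw_trap_cluster(nr, nc, cr, ccol)
        trapmask[cbind(px[, 1], px[, 2])] <- TRUE
        centers[[length(centers) + 1L]] <- c(cr, ccol)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place trap ", t, "; reduce n_traps or hyphal density")
    }
    img <- matrix(0.9, nr, nc)
    img[hymask] <- 0.5
    img[trapmask] <- 0.25
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
    img[img < 0] <- 0; img[img > 1] <- 1
    objects <- data.frame(
      type = c(rep("trap", length(centers)),
               rep("hypha", background_hyphae)),
      row = c(vapply(centers, `[`, 0, 1), rep(NA_real_, background_hyphae)),
      col = c(vapply(centers, `[`, 0, 2), rep(NA_real_, background_hyphae)))
    new_planted_scene(img, hymask | trapmask, objects, seed)
  })
}

#' Write a planted scene to disk as paired files
#'
#' Writes the image (`<basename>.png` or `.tif`), the ground-truth mask
#' (`<basename>_truth.png`) and a JSON descriptor sidecar
#' (`<basename>.json`) with the seed and planted-object table.
#'
#' @param scene A `planted_scene`.
#' @param dir Output directory (created if needed).
#' @param basename File stem.
#' @param format `"png"` or `"tiff"` for the image.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, basename = "scene",
                        format = c("png", "tiff")) {
  stopifnot(inherits(scene, "planted_scene"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(basename,
                                    if (format == "png") ".png" else ".tif"))
  if (format == "png") png::writePNG(scene$image, img_path)
  else tiff::writeTIFF(scene$image, img_path)
  truth_path <- file.path(dir, paste0(basename, "_truth.png"))
  png::writePNG(scene$truth_mask * 1, truth_path)
  json_path <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(list(seed = scene$seed, objects = scene$objects),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, truth = truth_path, descriptor = json_path))
}
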