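# Mycelial graph extraction and metrics.
#
# A cleaned 1-pixel-wide skeleton is converted into a mathematical graph:
# nodes are hyphal tips (pixels with one skeleton neighbor) and junctions
# (pixels with three or more), edges are the maximal chains of degree-2
# pixels connecting them, each carrying its pixel path and a step-rule
# length (1 per orthogonal step, sqrt(2) per diagonal step).
#
# Pixel degree is computed on a reduced adjacency rather than raw
# 8-connectivity: a diagonal link between two skeleton pixels is ignored
# whenever one of the two orthogonal pixels bridging them is also on the
# skeleton (the connection already exists through the bridge). Raw
# 8-neighbor counts misclassify the staircase corners of near-diagonal
# skeleton runs as junctions; the reduced adjacency leaves them as plain
# degree-2 chain pixels, and never disconnects anything because a dropped
# diagonal always has a 2-step orthogonal detour.

.orth4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
.diag4 <- cbind(dr = c(-1, -1, 1, 1), dc = c(-1, 1, -1, 1))

# Per-pixel degree under the reduced adjacency.
reduced_degree <- function(skel) {
  cnt <- matrix(0L, nrow(skel), ncol(skel))
  for (i in 1:4)
    cnt <- cnt + nbr_at(skel, .orth4[i, 1], .orth4[i, 2])
  for (i in 1:4) {
    diag <- nbr_at(skel, .diag4[i, 1], .diag4[i, 2])
    bridge <- nbr_at(skel, .diag4[i, 1], 0) | nbr_at(skel, 0, .diag4[i, 2])
    cnt <- cnt + (diag & !bridge)
  }
  cnt[!skel] <- 0L
  cnt
}

new_mycelial_graph <- function(nodes, edges, paths, dim) {
  structure(list(nodes = nodes, edges = edges, paths = paths, dim = dim),
            class = "mycelial_graph")
}

empty_graph <- function(dim = c(0L, 0L)) {
  new_mycelial_graph(
    nodes = data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                       degree = integer(0)),
    edges = data.frame(from = integer(0), to = integer(0),
                       length_px = numeric(0)),
    paths = list(), dim = dim)
}

#' @export
print.mycelial_graph <- function(x, ...) {
  cat("Mycelial graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      sum(x$nodes$degree == 1), "tips\n")
  invisible(x)
}

#' Convert a thinned skeleton into a mathematical graph
#'
#' Skeleton pixels whose degree differs from two become nodes: degree-1
#' pixels are hyphal tips, pixels of degree three or more are junction
#' pixels, and isolated pixels become isolated nodes. Degree is counted on
#' a reduced 8-adjacency that ignores a diagonal link whenever an
#' orthogonal skeleton pixel bridges the same pair, so the staircase
#' corners of near-diagonal runs read as ordinary chain pixels rather than
#' junctions. Adjacent junction pixels (thinning often produces small junction
#' clusters) are merged into a single node placed at their centroid, which
#' prevents spurious zero-length edges. Maximal chains of degree-2 pixels
#' between nodes become edges carrying their ordered pixel path; a closed
#' loop containing no junction becomes a single node with a self-loop edge
#' (which contributes 2 to that node's degree).
#'
#' The input must be thinned (see [thin_skeleton()]); on thick shapes the
#' node/edge decomposition is not meaningful.
#'
#' @param skel Logical matrix, a 1-pixel-wide skeleton.
#' @return A `mycelial_graph`: list with `nodes` (data frame `id`, `row`,
#'   `col`, `degree`), `edges` (data frame `from`, `to`, `length_px`),
#'   `paths` (list of 2-column pixel-coordinate matrices, one per edge) and
#'   `dim` (image shape).
#' @examples
#' sk <- matrix(FALSE, 5, 12); sk[3, 2:11] <- TRUE
#' g <- skeleton_to_graph(sk)
#' g$edges$length_px  # 9 orthogonal steps
#' @export
skeleton_to_graph <- function(skel) {
  skel <- check_binary(skel)
  nr <- nrow(skel); nc <- ncol(skel)
  if (!any(skel)) return(empty_graph(c(nr, nc)))
  ncnt <- reduced_degree(skel)
  junction <- skel & ncnt >= 3L
  tipiso <- skel & ncnt <= 1L
  jlab <- label_components(junction)
  njunc <- max(jlab)
  nodeid <- matrix(0L, nr, nc)
  nodeid[junction] <- jlab[junction]
  tip_idx <- which(tipiso)
  if (length(tip_idx)) nodeid[tip_idx] <- njunc + seq_along(tip_idx)
  n_nodes <- njunc + length(tip_idx)
  node_row <- numeric(n_nodes); node_col <- numeric(n_nodes)
  if (njunc > 0L) {
    ji <- which(jlab > 0L)
    jl <- jlab[ji]
    jr <- ((ji - 1L) %% nr) + 1L
    jc <- ((ji - 1L) %/% nr) + 1L
    cnt <- tabulate(jl, nbins = njunc)
    node_row[seq_len(njunc)] <- rowsum(jr, jl)[, 1] / cnt
    node_col[seq_len(njunc)] <- rowsum(jc, jl)[, 1] / cnt
  }
  if (length(tip_idx)) {
    node_row[njunc + seq_along(tip_idx)] <- ((tip_idx - 1L) %% nr) + 1L
    node_col[njunc + seq_along(tip_idx)] <- ((tip_idx - 1L) %/% nr) + 1L
  }

  visited <- matrix(FALSE, nr, nc)
  e_from <- integer(0); e_to <- integer(0); e_len <- numeric(0)
  e_paths <- list()
  add_edge <- function(from, to, path) {
    k <- length(e_from) + 1L
    e_from[k] <<- from; e_to[k] <<- to
    d <- diff(path)
    e_len[k] <<- sum(sqrt(d[, 1]^2 + d[, 2]^2))
    e_paths[[k]] <<- path
  }
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && skel[r, c]
  skel_nbrs <- function(r, c) {
    out <- matrix(0L, 8L, 2L); n <- 0L
    for (i in 1:4) {
      rr <- r + .orth4[i, 1]; cc <- c + .orth4[i, 2]
      if (at(rr, cc)) { n <- n + 1L; out[n, ] <- c(rr, cc) }
    }
    for (i in 1:4) {
      rr <- r + .diag4[i, 1]; cc <- c + .diag4[i, 2]
      if (at(rr, cc) && !at(rr, c) && !at(r, cc)) {
        n <- n + 1L; out[n, ] <- c(rr, cc)
      }
    }
    out[seq_len(n), , drop = FALSE]
  }
  trace_chain <- function(id0, r0, c0, r1, c1) {
    pr <- r0; pc <- c0; cr <- r1; cc <- c1
    path_r <- c(r0, r1); path_c <- c(c0, c1)
    repeat {
      visited[cr, cc] <<- TRUE
      nb <- skel_nbrs(cr, cc)
      nxt <- nb[!(nb[, 1] == pr & nb[, 2] == pc), , drop = FALSE]
      if (nrow(nxt) == 0L) break  # degenerate: should not occur on thin input
      pr <- cr; pc <- cc
      cr <- nxt[1, 1]; cc <- nxt[1, 2]
      path_r <- c(path_r, cr); path_c <- c(path_c, cc)
      if (nodeid[cr, cc] != 0L) break
    }
    add_edge(id0, nodeid[cr, cc], cbind(path_r, path_c))
  }

  node_px <- which(nodeid != 0L)
  for (i in node_px) {
    r0 <- ((i - 1L) %% nr) + 1L
    c0 <- ((i - 1L) %/% nr) + 1L
    id0 <- nodeid[i]
    nb <- skel_nbrs(r0, c0)
    for (j in seq_len(nrow(nb))) {
      r1 <- nb[j, 1]; c1 <- nb[j, 2]
      id1 <- nodeid[r1, c1]
      if (id1 != 0L) {
        if (id0 < id1)  # direct node-node adjacency, record once
          add_edge(id0, id1, cbind(c(r0, r1), c(c0, c1)))
      } else if (!visited[r1, c1]) {
        trace_chain(id0, r0, c0, r1, c1)
      }
    }
  }

  # Pure cycles: chains never reached from any node become self-loops.
  remaining <- which(skel & ncnt == 2L & !visited & nodeid == 0L)
  while (length(remaining)) {
    i <- remaining[1]
    r0 <- ((i - 1L) %% nr) + 1L
    c0 <- ((i - 1L) %/% nr) + 1L
    n_nodes <- n_nodes + 1L
    nodeid[i] <- n_nodes
    node_row[n_nodes] <- r0; node_col[n_nodes] <- c0
    visited[i] <- TRUE
    nb <- skel_nbrs(r0, c0)
    trace_chain(n_nodes, r0, c0, nb[1, 1], nb[1, 2])
    remaining <- which(skel & ncnt == 2L & !visited & nodeid == 0L)
  }

  deg <- tabulate(c(e_from, e_to), nbins = n_nodes)
  nodes <- data.frame(id = seq_len(n_nodes), row = node_row[seq_len(n_nodes)],
                      col = node_col[seq_len(n_nodes)], degree = deg)
  edges <- data.frame(from = e_from, to = e_to, length_px = e_len)
  new_mycelial_graph(nodes, edges, e_paths, c(nr, nc))
}

shoelace_area <- function(x, y) {
  0.5 * abs(sum(x * c(y[-1], y[1])) - sum(y * c(x[-1], x[1])))
}

#' Growth metrics of a mycelial graph
#'
#' Computes the measures used to track colony development:
#' * `total_length` — sum of all edge lengths (step rule), times `scale`;
#' * `n_tips` — number of nodes of degree 1, i.e. nodes connected to
#'   exactly one edge (isolated nodes are not tips);
#' * `n_edges` — number of hyphal segments;
#' * `hull_area` — area of the convex hull of the node coordinates
#'   (shoelace formula), times `scale^2`; fewer than three non-collinear
#'   nodes give area 0;
#' * `hull_vertices` — hull vertex coordinates in order.
#'
#' @param g A `mycelial_graph`.
#' @param scale Microns per pixel.
#' @return A list of class `mycelium_metrics`.
#' @examples
#' sk <- matrix(FALSE, 5, 12); sk[3, 2:11] <- TRUE
#' graph_metrics(skeleton_to_graph(sk))
#' @export
graph_metrics <- function(g, scale = 1) {
  stopifnot(inherits(g, "mycelial_graph"))
  if (scale <= 0) stop("scale must be > 0")
  total_length <- sum(g$edges$length_px) * scale
  n_tips <- sum(g$nodes$degree == 1)
  n_edges <- nrow(g$edges)
  hull_area <- 0
  hull_vertices <- data.frame(row = numeric(0), col = numeric(0))
  if (nrow(g$nodes) >= 3) {
    h <- grDevices::chull(g$nodes$col, g$nodes$row)
    if (length(h) >= 3) {
      hull_area <- shoelace_area(g$nodes$col[h], g$nodes$row[h]) * scale^2
      hull_vertices <- data.frame(row = g$nodes$row[h], col = g$nodes$col[h])
    }
  }
  structure(list(total_length = total_length, n_tips = n_tips,
                 n_edges = n_edges, hull_area = hull_area,
                 hull_vertices = hull_vertices),
            class = "mycelium_metrics")
}

#' @export
print.mycelium_metrics <- function(x, ...) {
  cat(sprintf("total_length %.2f | tips %d | edges %d | hull_area %.2f\n",
              x$total_length, x$n_tips, x$n_edges, x$hull_area))
  invisible(x)
}

#' Binary segmentation stage of the mycelium pipeline
#'
#' Background subtraction (Gaussian estimate, radius `gaussian_radius`)
#' followed by hysteresis binarization with `b1`/`b2`, and mask subtraction
#' if a mask is supplied. This is the segmentation that accuracy metrics
#' are computed against; the 3x3 dilation applied later in
#' [analyze_mycelium_image()] is a gap-closing regularization for
#' skeletonization, not part of the segmented mask.
#'
#' @param img Numeric matrix in `[0, 1]`, bright mycelium on dark
#'   background.
#' @param params A `calibration_params` object.
#' @param mask Optional logical matrix of pixels to remove.
#' @return Logical matrix.
#' @export
mycelium_binary <- function(img, params, mask = NULL) {
  stopifnot(inherits(params, "calibration_params"))
  flat <- gaussian_background_subtract(img, params$gaussian_radius)
  bw <- hysteresis_binarize(flat, params$b1, params$b2)
  if (!is.null(mask)) bw <- subtract_mask(bw, mask)
  bw
}

#' Full mycelium characterization of one image
#'
#' Pipeline: Gaussian background subtraction, hysteresis binarization, 3x3
#' dilation (closing small gaps caused by out-of-focus or weakly stained
#' stretches), thinning to a skeleton, deletion/pruning of structures below
#' `min_hyphae` pixels, optional mask subtraction, graph extraction, and
#' metric computation.
#'
#' @inheritParams mycelium_binary
#' @return A list with elements `graph` (a `mycelial_graph`), `metrics`
#'   (a `mycelium_metrics`) and `skeleton` (the cleaned logical skeleton).
#' @seealso [analyze_time_series()] to apply the same parameters over an
#'   ordered image series.
#' @export
analyze_mycelium_image <- function(img, params, mask = NULL) {
  stopifnot(inherits(params, "calibration_params"))
  bw <- mycelium_binary(img, params)
  bw <- dilate_3x3(bw)
  sk <- thin_skeleton(bw)
  sk <- clean_skeleton(sk, params$min_hyphae)
  if (!is.null(mask)) sk <- subtract_mask(sk, mask)
  g <- skeleton_to_graph(sk)
  list(graph = g, metrics = graph_metrics(g, params$scale), skeleton = sk)
}

#' Mycelium metrics over an ordered time series
#'
#' Applies [analyze_mycelium_image()] with identical parameters to every
#' frame and returns one metrics row per timepoint, in input order. All
#' frames must share the same shape.
#'
#' @param imgs List of numeric matrices, ordered by time.
#' @param params A `calibration_params` object.
#' @param mask Optional logical matrix subtracted from every frame.
#' @return A data frame with columns `timepoint`, `total_length`, `n_tips`,
#'   `n_edges`, `hull_area`; the per-frame analyses are attached as the
#'   `"analyses"` attribute.
#' @export
analyze_time_series <- function(imgs, params, mask = NULL) {
  stopifnot(is.list(imgs))
  out <- data.frame(timepoint = integer(0), total_length = numeric(0),
                    n_tips = integer(0), n_edges = integer(0),
                    hull_area = numeric(0))
  if (!length(imgs)) return(out)
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames in a time series must share the same shape")
  analyses <- vector("list", length(imgs))
  for (k in seq_along(imgs)) {
    a <- analyze_mycelium_image(imgs[[k]], params, mask)
    analyses[[k]] <- a
    out[k, ] <- list(k, a$metrics$total_length, a$metrics$n_tips,
                     a$metrics$n_edges, a$metrics$hull_area)
  }
  attr(out, "analyses") <- analyses
  out
}
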