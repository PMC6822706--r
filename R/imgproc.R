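# Low-level image operations shared by all quantification pipelines.
#
# Image conventions: a grayscale image is a numeric matrix with values in
# [0, 1], indexed [row, column]; a binary image is a logical matrix of the
# same shape. All neighborhood operations use 8-connectivity so that thin
# diagonal hyphae remain connected.

check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric matrix as grayscale image")
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("grayscale image values must lie in [0, 1]")
  invisible(img)
}

check_binary <- function(img) {
  if (is.matrix(img) && is.numeric(img) && all(img %in% c(0, 1)))
    return(matrix(as.logical(img), nrow(img)))
  if (!is.matrix(img) || !is.logical(img))
    stop("expected a logical (or 0/1 numeric) matrix as binary image")
  if (anyNA(img)) stop("binary image contains NA")
  img
}

# Value of the 8-neighbor at offset (dr, dc), seen from every pixel.
# Out-of-image neighbors read as `fill`.
nbr_at <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)  # source rows
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

.offsets8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                   dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Number of foreground 8-neighbors of every pixel.
neighbor_count <- function(bw) {
  acc <- matrix(0L, nrow(bw), ncol(bw))
  for (i in seq_len(8))
    acc <- acc + nbr_at(bw, .offsets8[i, 1], .offsets8[i, 2])
  acc
}

#' Invert a grayscale image
#'
#' Maps every pixel `p` to `1 - p`. Used by the counting pipelines so that
#' dark objects on a bright brightfield background become bright foreground.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @return Matrix of the same shape.
#' @examples
#' invert_image(matrix(c(0, 0.3, 1), 1))
#' @export
invert_image <- function(img) {
  check_gray(img)
  1 - img
}

#' Gaussian background subtraction
#'
#' Estimates the image background as a Gaussian blur of the image itself and
#' subtracts it, clipping the result to `[0, 1]`. This flattens uneven
#' illumination and slowly varying staining artifacts while leaving thin
#' bright structures (hyphae) largely intact. `radius` is the standard
#' deviation of the Gaussian kernel in pixels; the kernel support extends to
#' three standard deviations and image borders are replicated. `radius = 0`
#' returns an all-zero image (the image minus itself).
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param radius Gaussian kernel standard deviation in pixels, `>= 0`.
#' @return Background-subtracted matrix, clipped to `[0, 1]`.
#' @export
gaussian_background_subtract <- function(img, radius) {
  check_gray(img)
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius < 0)
    stop("radius must be a single number >= 0")
  if (radius == 0) return(matrix(0, nrow(img), ncol(img)))
  nr <- nrow(img); nc <- ncol(img)
  k <- 2 * ceiling(3 * radius) + 1  # gblur kernel support
  pr <- max(0L, ceiling((k - nr) / 2) + 1L)
  pc <- max(0L, ceiling((k - nc) / 2) + 1L)
  if (pr > 0 || pc > 0) {  # image smaller than the kernel: replicate-pad
    ir <- pmin(pmax(seq_len(nr + 2 * pr) - pr, 1L), nr)
    ic <- pmin(pmax(seq_len(nc + 2 * pc) - pc, 1L), nc)
    bg <- EBImage::gblur(img[ir, ic], sigma = radius,
                         boundary = "replicate")
    bg <- bg[pr + seq_len(nr), pc + seq_len(nc)]
  } else {
    bg <- EBImage::gblur(img, sigma = radius, boundary = "replicate")
  }
  out <- img - bg
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Label connected components (8-connectivity)
#'
#' Assigns consecutive positive integer labels to the 8-connected components
#' of a binary image; background is 0.
#'
#' @param bw Logical matrix.
#' @return Integer matrix of labels.
#' @export
label_components <- function(bw) {
  bw <- check_binary(bw)
  lab <- EBImage::bwlabel(bw * 1)  # 4-connected labeling
  lab <- matrix(as.integer(round(lab)), nrow(bw))
  n <- max(lab)
  if (n == 0L) return(lab)
  # Merge labels that touch diagonally (union-find over label ids only).
  nr <- nrow(lab); nc <- ncol(lab)
  pr <- rbind(cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
              cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pr <- pr[pr[, 1] > 0L & pr[, 2] > 0L & pr[, 1] != pr[, 2], , drop = FALSE]
  if (nrow(pr)) {
    pr <- unique(cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2])))
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pr))) {
      a <- find(pr[k, 1]); b <- find(pr[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, 1L)
  } else root <- seq_len(n)
  ids <- sort(unique(root))
  remap <- integer(n); remap[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- remap[root[lab[pos]]]
  lab
}

#' Hysteresis (double-threshold) binarization
#'
#' Foreground consists of all pixels with value strictly greater than `b1`
#' (strong pixels), plus all pixels strictly greater than `b2` that are
#' 8-connected to a strong pixel through pixels greater than `b2`.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param b1 Strong threshold.
#' @param b2 Weak threshold, `b2 <= b1`.
#' @return Logical matrix.
#' @examples
#' hysteresis_binarize(matrix(c(0.9, 0.5, 0.2, 0.5, 0.9), 1), 0.8, 0.4)
#' @export
hysteresis_binarize <- function(img, b1, b2) {
  check_gray(img)
  if (b2 > b1) stop("thresholds must satisfy b2 <= b1")
  if (b1 < 0 || b1 > 1 || b2 < 0) stop("thresholds must lie in [0, 1]")
  strong <- img > b1
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  weak <- img > b2
  lab <- label_components(weak)
  keep <- unique(lab[strong])
  matrix(lab %in% keep & weak, nrow(img))
}

#' Binary dilation with a 3x3 box
#'
#' A pixel is foreground in the output iff any pixel of its 3x3 neighborhood
#' (clipped at image borders) is foreground in the input. Used to close
#' small gaps in segmented hyphae before skeletonization.
#'
#' @param bw Logical matrix.
#' @return Logical matrix.
#' @export
dilate_3x3 <- function(bw) {
  bw <- check_binary(bw)
  out <- bw
  for (i in seq_len(8))
    out <- out | nbr_at(bw, .offsets8[i, 1], .offsets8[i, 2])
  out
}

#' Topology-preserving thinning (skeletonization)
#'
#' Reduces foreground shapes to 8-connected centerlines of single-pixel
#' width using the two-subiteration parallel thinning scheme of the
#' Zhang–Suen family, iterated to its fixed point. Connectivity and holes
#' are preserved for shapes wider than two pixels; an already thin line is
#' left unchanged.
#'
#' @param bw Logical matrix.
#' @return Logical matrix containing the skeleton.
#' @export
thin_skeleton <- function(bw) {
  p <- check_binary(bw)
  if (!any(p)) return(p)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- nbr_at(p, -1, 0); P3 <- nbr_at(p, -1, 1)
      P4 <- nbr_at(p, 0, 1);  P5 <- nbr_at(p, 1, 1)
      P6 <- nbr_at(p, 1, 0);  P7 <- nbr_at(p, 1, -1)
      P8 <- nbr_at(p, 0, -1); P9 <- nbr_at(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cond <- if (sub == 1) !(P2 & P4 & P6) & !(P4 & P6 & P8)
              else          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      del <- p & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        p[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

#' Remove small skeleton components and prune short terminal branches
#'
#' Two cleaning rules controlled by a single pixel threshold: (1) connected
#' skeleton components with fewer than `min_hyphae` pixels are deleted;
#' (2) terminal branches — skeleton paths ending at a degree-1 pixel and
#' attached to a junction — whose removable pixel count (the path excluding
#' the junction pixel) is below `min_hyphae` are pruned back to their
#' junction. Pruning is iterated until stable, so branches that become
#' terminal after a first pass are also examined. `min_hyphae = 0` is the
#' identity.
#'
#' @param skel Logical matrix, expected to be a thinned skeleton
#'   (see [thin_skeleton()]).
#' @param min_hyphae Pixel threshold, `>= 0`.
#' @return Cleaned skeleton as a logical matrix.
#' @export
clean_skeleton <- function(skel, min_hyphae) {
  skel <- check_binary(skel)
  if (min_hyphae < 0) stop("min_hyphae must be >= 0")
  if (min_hyphae == 0 || !any(skel)) return(skel)
  repeat {
    lab <- label_components(skel)
    if (max(lab) > 0L) {
      sz <- tabulate(lab[lab > 0L], nbins = max(lab))
      drop <- which(sz < min_hyphae)
      if (length(drop)) skel[matrix(lab %in% drop, nrow(skel))] <- FALSE
    }
    if (!any(skel)) return(skel)
    g <- skeleton_to_graph(skel)
    if (nrow(g$edges) == 0) break
    deg <- g$nodes$degree[order(g$nodes$id)]
    d_from <- deg[g$edges$from]; d_to <- deg[g$edges$to]
    term <- (d_from == 1 & d_to >= 3) | (d_to == 1 & d_from >= 3)
    if (!any(term)) break
    removed <- FALSE
    for (e in which(term)) {
      path <- g$paths[[e]]
      # orient path so the tip end comes first
      if (deg[g$edges$from[e]] >= 3) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
      n_removable <- nrow(path) - 1L   # junction-side pixel is kept
      if (n_removable < min_hyphae && n_removable > 0L) {
        idx <- path[seq_len(n_removable), , drop = FALSE]
        skel[cbind(idx[, 1], idx[, 2])] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Subtract a mask from a binary image
#'
#' Clears every pixel of `img` that is set in `mask` (logical AND NOT).
#' Used to remove constant artifacts such as well edges from segmentations
#' and skeletons.
#'
#' @param img,mask Logical matrices of identical shape.
#' @return Logical matrix.
#' @export
subtract_mask <- function(img, mask) {
  img <- check_binary(img)
  mask <- check_binary(mask)
  if (!all(dim(img) == dim(mask)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(dim(img), collapse = "x"))
  img & !mask
}
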