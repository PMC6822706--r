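# Image reading and overlay rendering.

#' Read an image file as a normalized grayscale matrix
#'
#' Supports PNG and TIFF (8- and 16-bit; both are returned already scaled
#' to `[0, 1]` by the underlying readers). RGB(A) images are converted to
#' gray as the unweighted mean of the R, G and B channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' for file: ", path))
  if (is.list(arr)) arr <- arr[[1]]  # multi-page TIFF: first page
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3) (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
           else arr[, , 1]
  }
  arr[arr < 0] <- 0; arr[arr > 1] <- 1
  arr
}

# Gray matrix -> RGB array, with selected pixels tinted toward a color.
gray_to_rgb <- function(img) {
  array(rep(img, 3), c(dim(img), 3))
}

tint_pixels <- function(rgb, px, color, alpha = 0.7) {
  if (is.null(px) || nrow(px) == 0) return(rgb)
  for (ch in 1:3) {
    i <- cbind(px, ch)
    rgb[i] <- (1 - alpha) * rgb[i] + alpha * color[ch]
  }
  rgb
}

# Pixel coordinates of a straight segment between two (row, col) points.
segment_pixels <- function(p0, p1) {
  n <- max(abs(p1 - p0)) * 2 + 2
  t <- seq(0, 1, length.out = n)
  unique(cbind(round(p0[1] + t * (p1[1] - p0[1])),
               round(p0[2] + t * (p1[2] - p0[2]))))
}

clip_px <- function(px, dim) {
  px[px[, 1] >= 1 & px[, 1] <= dim[1] &
     px[, 2] >= 1 & px[, 2] <= dim[2], , drop = FALSE]
}

#' Render a detection overlay for spore/trap counting or morphometry
#'
#' Paints the pixels of the kept components in blue over the original
#' grayscale image, matching the visual output convention of the counting
#' functions.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param result A `spore_count` object or the data frame returned by
#'   [measure_spores()].
#' @param params The `calibration_params` used (to re-derive kept labels).
#' @return RGB array (rows x cols x 3).
#' @export
overlay_components <- function(img, result, params) {
  bw <- if (inherits(result, "spore_count")) result$binary
        else attr(result, "binary")
  kept <- if (inherits(result, "spore_count")) result$components
          else attr(result, "components")
  rgb <- gray_to_rgb(img)
  if (is.null(bw) || is.null(kept) || nrow(kept) == 0) return(rgb)
  lab <- label_components(bw)
  px <- which(matrix(lab %in% kept$label, nrow(lab)), arr.ind = TRUE)
  tint_pixels(rgb, px, c(0.1, 0.3, 1))
}

#' Render a mycelium overlay: graph, hull and tips
#'
#' Draws the skeleton graph edges in green, the convex-hull outline in
#' blue, and the hyphal tips as yellow dots over the original image.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param analysis Result of [analyze_mycelium_image()].
#' @return RGB array (rows x cols x 3).
#' @export
overlay_mycelium <- function(img, analysis) {
  rgb <- gray_to_rgb(img)
  g <- analysis$graph
  if (nrow(g$edges)) {
    px <- do.call(rbind, g$paths)
    rgb <- tint_pixels(rgb, px, c(0.1, 0.9, 0.2), alpha = 0.9)
  }
  hv <- analysis$metrics$hull_vertices
  if (nrow(hv) >= 3) {
    hpx <- do.call(rbind, lapply(seq_len(nrow(hv)), function(i) {
      j <- if (i == nrow(hv)) 1L else i + 1L
      segment_pixels(round(c(hv$row[i], hv$col[i])),
                     round(c(hv$row[j], hv$col[j])))
    }))
    rgb <- tint_pixels(rgb, clip_px(hpx, dim(img)), c(0.2, 0.4, 1),
                       alpha = 0.9)
  }
  tips <- g$nodes[g$nodes$degree == 1, , drop = FALSE]
  if (nrow(tips)) {
    tpx <- do.call(rbind, lapply(seq_len(nrow(tips)), function(i) {
      as.matrix(expand.grid(round(tips$row[i]) + (-1:1),
                            round(tips$col[i]) + (-1:1)))
    }))
    rgb <- tint_pixels(rgb, clip_px(tpx, dim(img)), c(1, 0.95, 0.1),
                       alpha = 1)
  }
  rgb
}
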