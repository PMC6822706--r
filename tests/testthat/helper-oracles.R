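# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation (double loops, BFS,
# gift wrapping) kept separate from the package's algorithms.

# Rasterize a filled disk by scanning every pixel.
draw_disk <- function(nr, nc, cr, cc, r) {
  bw <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) bw[i, j] <- TRUE
  bw
}

# Rasterize a filled axis-aligned ellipse by scanning every pixel.
draw_ellipse_mask <- function(nr, nc, cr, cc, a_row, b_col) {
  bw <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if (((i - cr) / a_row)^2 + ((j - cc) / b_col)^2 <= 1) bw[i, j] <- TRUE
  bw
}

# Brute-force hysteresis: BFS flood fill over weak pixels from strong seeds.
hysteresis_oracle <- function(img, b1, b2) {
  nr <- nrow(img); nc <- ncol(img)
  weak <- img > b2
  out <- img > b1
  queue <- which(out)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      j <- (cc - 1) * nr + rr
      if (weak[j] && !out[j]) {
        out[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  out
}

# Brute-force convex hull area: gift wrapping followed by the shoelace
# formula; handles collinear/degenerate inputs by returning 0.
hull_area_oracle <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (p == 1) 2 else 1
    for (q in seq_len(n)) {
      if (q == p) next
      cr <- cross(pts[p, ], pts[cand, ], pts[q, ])
      if (cand == p || cr < 0 ||
          (cr == 0 && sum((pts[q, ] - pts[p, ])^2) >
                      sum((pts[cand, ] - pts[p, ])^2)))
        cand <- q
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > n + 1) stop("gift wrapping failed")
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  0.5 * abs(sum(hx * c(hy[-1], hy[1])) - sum(hy * c(hx[-1], hx[1])))
}

# Draw a 1-px straight segment into a logical matrix (inclusive endpoints).
draw_segment <- function(bw, r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  bw[cbind(rr, cc)] <- TRUE
  bw
}

# Y-shaped skeleton: three straight arms meeting at (cr, cc).
draw_y_skeleton <- function(nr = 48, nc = 48, cr = 24, cc = 24,
                            arms = c(20, 20, 20)) {
  bw <- matrix(FALSE, nr, nc)
  bw <- draw_segment(bw, cr, cc, cr - arms[1], cc)          # up
  bw <- draw_segment(bw, cr, cc, cr + arms[2], cc - arms[2]) # down-left diag
  bw <- draw_segment(bw, cr, cc, cr, cc + arms[3])           # right
  bw
}

# All 3-level intensity grids of a given shape, as a generator of matrices.
# Levels straddle the thresholds: below b2, between b2 and b1, above b1.
all_three_level_grids <- function(nr, nc, levels = c(0.1, 0.6, 0.95)) {
  n <- nr * nc
  total <- 3^n
  lapply(seq_len(total) - 1L, function(code) {
    digits <- integer(n)
    for (k in seq_len(n)) {
      digits[k] <- code %% 3L
      code <- code %/% 3L
    }
    matrix(levels[digits + 1L], nr, nc)
  })
}
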