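# programmatic fixtures shared across test files

# filled axis-aligned rectangle mask (zero-based pixel bounds, inclusive)
rect_mask <- function(width, height, x0, x1, y0, y1) {
  m <- matrix(0L, nrow = height, ncol = width)
  m[(y0:y1) + 1, (x0:x1) + 1] <- 1L
  as_mask(m)
}

# filled disk mask
disk_mask <- function(width, height, cx, cy, r) {
  xx <- matrix(rep(0:(width - 1), each = height), nrow = height)
  yy <- matrix(rep(0:(height - 1), times = width), nrow = height)
  as_mask(matrix(as.integer((xx - cx)^2 + (yy - cy)^2 <= r^2), nrow = height))
}

# points sampled exactly on a circle (closed curve, no duplicate endpoint)
circle_contour <- function(r, n = 200, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(index = seq_len(n), x = cx + r * cos(th), y = cy + r * sin(th))
}

# brute-force convex hull vertex test: p is a hull vertex iff some line
# through it leaves all other points strictly on one side (O(n^2) per point)
brute_hull_vertices <- function(x, y) {
  n <- length(x)
  is_vertex <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      # candidate edge i -> j: all other points on one side?
      cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      cr <- cr[-c(i, j)]
      if (all(cr >= 0) || all(cr <= 0)) {
        is_vertex[i] <- TRUE
        break
      }
    }
  }
  is_vertex
}

landmark_errors <- function(detected, truth) {
  m <- merge(as.data.frame(detected), as.data.frame(truth),
             by = "landmark", suffixes = c("", ".t"))
  stats::setNames(sqrt((m$x - m$x.t)^2 + (m$y - m$y.t)^2), m$landmark)
}
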