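#' Distance from a point to a line in implicit form
#'
#' Computes the perpendicular distance from a pixel point to the line
#' `a*x + b*y + c = 0`, the rule used to pick the chest-front point (closest
#' to the nose--hoof chord) and the withers (farthest from the head--hip
#' chord) on a side-view contour.
#'
#' @param x,y Point coordinates (px). Vectorised.
#' @param line Numeric vector `c(a, b, c)` of the implicit line equation.
#' @return Nonnegative distance(s) in pixels:
#'   `|a*x + b*y + c| / sqrt(a^2 + b^2)`.
#' @examples
#' point_line_distance(0, 1, c(0, 1, 0)) # horizontal axis -> 1
#' @export
point_line_distance <- function(x, y, line) {
  stopifnot(is.numeric(line), length(line) == 3)
  a <- line[[1]]; b <- line[[2]]; cc <- line[[3]]
  if (a == 0 && b == 0) {
    stop("invalid line: (a, b) must not both be zero")
  }
  abs(a * x + b * y + cc) / sqrt(a^2 + b^2)
}

#' Implicit line through two points
#'
#' @param p1,p2 Numeric length-2 vectors `c(x, y)`.
#' @return `c(a, b, c)` with `a*x + b*y + c = 0` through both points.
#' @export
line_through <- function(p1, p2) {
  a <- p2[[2]] - p1[[2]]
  b <- p1[[1]] - p2[[1]]
  if (a == 0 && b == 0) stop("points coincide; line undefined")
  c(a, b, -(a * p1[[1]] + b * p1[[2]]))
}

#' u-chord (Menger) curvature along a closed contour
#'
#' Estimates curvature at contour points as the inverse circumradius of the
#' triangle formed with neighbours `u` chord steps away on each side
#' (wraparound indexing). On points sampled exactly on a circle of radius
#' `r` this returns exactly `1/r` for every index and admissible `u`; on a
#' straight edge it returns 0. The estimator is rotation invariant, which is
#' why it is used to localise skeletal prominences (sciatic tuberosity,
#' sternum, scapular and hip bulges) on sheep silhouettes.
#'
#' @param contour A contour tibble with `x`, `y` columns (see
#'   [extract_contour()]), or any data frame of ordered closed-curve points.
#' @param index Optional integer vector of point indices at which to evaluate;
#'   default all points.
#' @param u Chord step in points (integer >= 1). Default 1% of the contour
#'   point count (minimum 3).
#' @param signed If `TRUE`, attach the orientation sign of the turn so that,
#'   for a clockwise contour in image coordinates, convex (outward) bulges are
#'   positive and concavities negative.
#' @return Numeric vector of curvatures (1/px), one per requested index.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' circ <- tibble::tibble(x = 50 * cos(th), y = 50 * sin(th))
#' u_chord_curvature(circ, index = 1, u = 10) # ~ 1/50
#' @export
u_chord_curvature <- function(contour, index = NULL, u = NULL, signed = FALSE) {
  x <- contour$x
  y <- contour$y
  n <- length(x)
  if (is.null(u)) u <- max(3L, round(0.01 * n))
  u <- as.integer(u)
  if (u < 1) stop("u must be >= 1")
  if (n <= 2 * u) stop("contour too short for chord step u = ", u)
  if (is.null(index)) index <- seq_len(n)

  im <- ((index - 1 - u) %% n) + 1
  ip <- ((index - 1 + u) %% n) + 1
  ax <- x[im]; ay <- y[im]
  bx <- x[index]; by <- y[index]
  cx <- x[ip]; cy <- y[ip]

  cross <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  e1 <- sqrt((bx - ax)^2 + (by - ay)^2)
  e2 <- sqrt((cx - bx)^2 + (cy - by)^2)
  e3 <- sqrt((cx - ax)^2 + (cy - ay)^2)
  denom <- e1 * e2 * e3
  kappa <- ifelse(denom == 0, 0, 2 * abs(cross) / denom)
  if (signed) {
    # clockwise image-coordinate contours have positive cross product at
    # convex (outward) points, so the raw sign already marks convexity
    kappa <- kappa * ifelse(cross == 0, 0, sign(cross))
  }
  kappa
}

#' Convex hull of contour points
#'
#' Wraps [grDevices::chull()] and normalises the result: vertices are returned
#' counterclockwise in mathematical orientation (y upward), collinear interior
#' vertices are dropped, and an all-collinear input degenerates to its two
#' extreme points.
#'
#' @param contour Data frame with `x`, `y` columns.
#' @return Tibble of hull vertices (`x`, `y`) plus `index`, the row of the
#'   input each vertex came from.
#' @export
convex_hull <- function(contour) {
  x <- contour$x
  y <- contour$y
  if (length(x) < 2) stop("need at least 2 points")
  idx <- grDevices::chull(x, y)
  if (length(idx) <= 2) {
    # chull already degenerate; fall through to extreme-point rule below
  }
  hx <- x[idx]; hy <- y[idx]
  if (length(idx) >= 3) {
    # drop collinear interior vertices
    keep <- rep(TRUE, length(idx))
    m <- length(idx)
    for (k in seq_len(m)) {
      a <- if (k == 1) m else k - 1
      b <- if (k == m) 1 else k + 1
      cr <- (hx[k] - hx[a]) * (hy[b] - hy[a]) - (hy[k] - hy[a]) * (hx[b] - hx[a])
      if (cr == 0) keep[k] <- FALSE
    }
    idx <- idx[keep]
    hx <- hx[keep]; hy <- hy[keep]
  }
  if (length(idx) <= 2) {
    # all points collinear: return the two extremes of the point set
    o <- order(x, y)
    lo <- o[1]; hi <- o[length(o)]
    return(tibble::tibble(x = x[c(lo, hi)], y = y[c(lo, hi)],
                          index = c(lo, hi)))
  }
  # enforce counterclockwise orientation in mathematical (y-up) axes
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (area2 < 0) {
    idx <- rev(idx); hx <- rev(hx); hy <- rev(hy)
  }
  tibble::tibble(x = hx, y = hy, index = idx)
}

#' Which contour points lie on the convex hull boundary
#'
#' Used by the hoof detector, which searches hull-supported contour points
#' only ("the polygon around the outline of the sheep").
#'
#' @param contour Data frame with `x`, `y`.
#' @param tol Maximum distance (px) from a hull edge to count as on the hull.
#' @return Logical vector over contour rows.
#' @export
on_hull <- function(contour, tol = 0.5) {
  h <- convex_hull(contour)
  m <- nrow(h)
  res <- rep(FALSE, nrow(contour))
  for (k in seq_len(m)) {
    p1 <- c(h$x[k], h$y[k])
    p2 <- c(h$x[if (k == m) 1 else k + 1], h$y[if (k == m) 1 else k + 1])
    ln <- line_through(p1, p2)
    d <- point_line_distance(contour$x, contour$y, ln)
    within <- contour$x >= min(p1[1], p2[1]) - tol &
      contour$x <= max(p1[1], p2[1]) + tol &
      contour$y >= min(p1[2], p2[2]) - tol &
      contour$y <= max(p1[2], p2[2]) + tol
    res <- res | (d <= tol & within)
  }
  res
}

#' Perimeter of an ellipse by Gauss--Legendre quadrature
#'
#' Evaluates `4 * integral_0^{pi/2} sqrt(alpha^2 cos^2 t + beta^2 sin^2 t) dt`,
#' the arc length of an ellipse with semi-axes `alpha` and `beta`. This is how
#' chest circumference is reconstructed from chest width (dorsal view) and
#' chest depth (side view), the two semi-axes of the near-elliptical ovine
#' thorax cross-section.
#'
#' Uses a fixed 64-node Gauss--Legendre rule with a split-interval refinement
#' check; the result is accurate to well below 1e-8 for any axis ratio met in
#' practice.
#'
#' @param alpha,beta Semi-axes (same unit as the result; nonnegative).
#' @return Perimeter length.
#' @examples
#' ellipse_perimeter(1, 1) # 2*pi
#' ellipse_perimeter(2, 1) # 9.688448
#' @export
ellipse_perimeter <- function(alpha, beta) {
  if (alpha < 0 || beta < 0) stop("semi-axes must be nonnegative")
  if (alpha == 0 && beta == 0) return(0)
  f <- function(t) sqrt(alpha^2 * cos(t)^2 + beta^2 * sin(t)^2)
  gl <- pracma::gaussLegendre(64, 0, pi / 2)
  v1 <- sum(gl$w * f(gl$x))
  # refinement check: same rule on two half intervals
  g1 <- pracma::gaussLegendre(64, 0, pi / 4)
  g2 <- pracma::gaussLegendre(64, pi / 4, pi / 2)
  v2 <- sum(g1$w * f(g1$x)) + sum(g2$w * f(g2$x))
  if (abs(v2 - v1) > 1e-8 * max(1, abs(v2))) v1 <- v2
  4 * v1
}

#' Axis-aligned search box as fractions of a bounding box
#'
#' Search regions for landmark detection ("range 2--8") are expressed as
#' fractions of the silhouette bounding box so that they transfer across
#' animals and image scales.
#'
#' @param x_lo,x_hi,y_lo,y_hi Fractions in `[0, 1]`, `lo < hi`.
#' @return A named list of class `range_box`.
#' @export
range_box <- function(x_lo = 0, x_hi = 1, y_lo = 0, y_hi = 1) {
  stopifnot(x_lo < x_hi, y_lo < y_hi,
            x_lo >= 0, y_lo >= 0, x_hi <= 1, y_hi <= 1)
  structure(list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi),
            class = "range_box")
}

#' Restrict contour rows to a fractional box of its bounding box
#' @param contour Data frame with `x`, `y`.
#' @param box A [range_box()].
#' @return Logical vector over contour rows.
#' @export
in_range_box <- function(contour, box) {
  x0 <- min(contour$x); x1 <- max(contour$x)
  y0 <- min(contour$y); y1 <- max(contour$y)
  w <- x1 - x0; h <- y1 - y0
  contour$x >= x0 + box$x_lo * w & contour$x <= x0 + box$x_hi * w &
    contour$y >= y0 + box$y_lo * h & contour$y <= y0 + box$y_hi * h
}

#' Extremal contour point within a fractional search box
#'
#' Implements the range-restricted extremum rule: intersect the contour with
#' a search box (fractions of its bounding box), then return the point with
#' the minimal or maximal `x` or `y`. Ties are broken by the smallest contour
#' index, making the result deterministic.
#'
#' @param contour Contour tibble (`index`, `x`, `y`).
#' @param box A [range_box()].
#' @param axis `"x"` or `"y"`.
#' @param mode `"min"` or `"max"`.
#' @return One-row tibble (`index`, `x`, `y`).
#' @export
restricted_extremum <- function(contour, box = range_box(),
                                axis = c("x", "y"), mode = c("min", "max")) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  sel <- which(in_range_box(contour, box))
  if (length(sel) == 0) stop("empty range: no contour point inside search box")
  v <- contour[[axis]][sel]
  target <- if (mode == "min") min(v) else max(v)
  hit <- sel[v == target]
  i <- hit[which.min(contour$index[hit])]
  contour[i, c("index", "x", "y")]
}
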