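test_that("point-line distance matches the implicit formula and a projection oracle", {
  # point on the line
  expect_equal(point_line_distance(2, 2, c(1, -1, 0)), 0)
  # unit offset from the x axis
  expect_equal(point_line_distance(0, 1, c(0, 1, 0)), 1)

  withr::with_seed(11, {
    for (k in 1:25) {
      p <- stats::runif(2, -50, 50)
      a <- stats::runif(1, -3, 3); b <- stats::runif(1, -3, 3)
      if (a == 0 && b == 0) a <- 1
      cc <- stats::runif(1, -10, 10)
      # oracle: distance to the foot of the perpendicular, via projection of
      # the offset from an arbitrary point on the line onto the unit normal
      x0 <- if (b != 0) 0 else -cc / a
      y0 <- if (b != 0) -(cc + a * x0) / b else 0
      nvec <- c(a, b) / sqrt(a^2 + b^2)
      d_oracle <- abs(sum((p - c(x0, y0)) * nvec))
      expect_equal(point_line_distance(p[1], p[2], c(a, b, cc)), d_oracle,
                   tolerance = 1e-12)
      # invariance under rescaling the implicit coefficients
      expect_equal(point_line_distance(p[1], p[2], 7.3 * c(a, b, cc)),
                   point_line_distance(p[1], p[2], c(a, b, cc)),
                   tolerance = 1e-12)
    }
  })
  expect_error(point_line_distance(1, 1, c(0, 0, 3)), "invalid line")
})

test_that("u-chord curvature is exactly 1/r on circles, 0 on lines, 1/R on triangles", {
  circ <- circle_contour(50, n = 240)
  # exact on circle points for every index and several chord steps
  for (u in c(1, 5, 10, 40)) {
    k <- u_chord_curvature(circ, u = u)
    expect_equal(k, rep(1 / 50, 240), tolerance = 1e-10)
  }
  # collinear points -> 0
  line_ct <- tibble::tibble(index = 1:9, x = as.numeric(1:9), y = 2 * (1:9))
  expect_equal(u_chord_curvature(line_ct, index = 5, u = 2), 0)
  # triangle with known circumradius: R = abc / (4 * Area)
  tri <- tibble::tibble(index = 1:3, x = c(0, 4, 1), y = c(0, 0, 3))
  aa <- sqrt(sum((c(4, 0) - c(1, 3))^2)); bb <- sqrt(sum(c(1, 3)^2)); cc <- 4
  area <- abs(4 * 3) / 2
  R <- aa * bb * cc / (4 * area)
  expect_equal(u_chord_curvature(tri, index = 2, u = 1), 1 / R,
               tolerance = 1e-12)
  expect_error(u_chord_curvature(circ[1:5, ], u = 3), "too short")
})

test_that("signed curvature marks convex bulges positive on clockwise contours", {
  sq <- rect_mask(30, 30, 5, 24, 5, 24)
  ct <- extract_contour(sq)
  k <- u_chord_curvature(ct, u = 3, signed = TRUE)
  expect_true(all(k >= 0)) # a convex shape has no negative turns
  expect_gt(max(k), 0)
})

test_that("convex hull matches a brute-force oracle and handles degeneracies", {
  # square corners plus centre
  pts <- tibble::tibble(x = c(0, 10, 10, 0, 5), y = c(0, 0, 10, 10, 5))
  h <- convex_hull(pts)
  expect_setequal(h$index, 1:4)

  withr::with_seed(21, {
    for (k in 1:10) {
      n <- 60
      pts <- tibble::tibble(x = stats::runif(n, 0, 100),
                            y = stats::runif(n, 0, 100))
      h <- convex_hull(pts)
      truth <- which(brute_hull_vertices(pts$x, pts$y))
      expect_setequal(h$index, truth)
      # counterclockwise in mathematical (y-up) orientation
      area2 <- sum(h$x * c(h$y[-1], h$y[1]) - c(h$x[-1], h$x[1]) * h$y)
      expect_gt(area2, 0)
      # idempotence and containment
      h2 <- convex_hull(h)
      expect_setequal(paste(h2$x, h2$y), paste(h$x, h$y))
      expect_true(all(on_hull(pts, tol = 1e-6) | !brute_hull_vertices(pts$x, pts$y)))
    }
  })

  # collinear input degenerates to the two extremes
  col <- tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 2))
  h <- convex_hull(col)
  expect_equal(nrow(h), 2)
  expect_setequal(h$x, c(0, 2))
})

test_that("ellipse perimeter matches closed forms and the elliptic-integral oracle", {
  expect_equal(ellipse_perimeter(3, 3), 2 * pi * 3, tolerance = 1e-10)
  expect_equal(ellipse_perimeter(2, 0), 8, tolerance = 1e-10)
  expect_equal(ellipse_perimeter(0, 0), 0)
  # oracle: complete elliptic integral of the second kind, P = 4 a E(m)
  for (ab in list(c(2, 1), c(5, 4), c(10, 1), c(20, 10), c(1, 1e-3))) {
    a <- max(ab); b <- min(ab)
    m <- 1 - (b / a)^2
    oracle <- 4 * a * pracma::ellipke(m)$e
    expect_equal(ellipse_perimeter(ab[1], ab[2]), oracle, tolerance = 1e-6)
  }
  expect_equal(ellipse_perimeter(2, 1), 9.688448, tolerance = 1e-6)
  # symmetry, monotonicity, and circle bounds
  expect_equal(ellipse_perimeter(2, 1), ellipse_perimeter(1, 2))
  expect_lt(ellipse_perimeter(2, 1), ellipse_perimeter(2, 1.5))
  expect_gte(ellipse_perimeter(2, 1), 2 * pi * 1)
  expect_lte(ellipse_perimeter(2, 1), 2 * pi * 2)
  expect_error(ellipse_perimeter(-1, 2), "nonnegative")
})

test_that("restricted extremum respects the box, axis, mode and tie rule", {
  sq <- extract_contour(rect_mask(40, 40, 10, 29, 10, 29))
  # full box, min y: topmost row; tie broken by smallest index (trace starts
  # at the topmost-leftmost pixel)
  top <- restricted_extremum(sq, range_box(), axis = "y", mode = "min")
  expect_equal(top$y, 10)
  expect_equal(top$index, 1)
  expect_equal(top$x, 10)
  # right-half box, max x
  right <- restricted_extremum(sq, range_box(x_lo = 0.5), axis = "x",
                               mode = "max")
  expect_equal(right$x, 29)
  # empty box
  expect_error(
    restricted_extremum(sq, range_box(0.1, 0.4, 0.1, 0.4), "x", "min"),
    "empty range")
})
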