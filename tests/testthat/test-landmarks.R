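# a blocky "sheep": body rectangle with a raised head block on the right and
# two leg rectangles; coarse but with unambiguous extrema
blocky_sheep <- function() {
  m <- matrix(0L, 100, 160)
  m[40:70, 20:120] <- 1L    # body: y 39..69, x 19..119
  m[20:40, 105:135] <- 1L   # head block raised on the right (y 19..39)
  m[70:90, 30:41] <- 1L     # rear leg
  m[70:90, 109:120] <- 1L   # front leg, 12 px wide (x 108..119)
  as_mask(m)
}

test_that("extremum-rule landmarks find the blocky-sheep corners", {
  ct <- extract_contour(blocky_sheep())
  hv <- detect_head_vertex(ct)
  expect_equal(hv$y, 19) # top of the head block
  expect_gte(hv$x, 104)
  expect_lte(hv$x, 134)
  fv <- detect_facial_vertex(ct)
  expect_equal(fv$x, max(ct$x))
  # oracle: plain linear scan with index tie-break
  cand <- which(ct$x == max(ct$x))
  expect_equal(fv$index, min(cand))
  ht <- detect_hip_top(ct)
  expect_equal(ht$y, 39) # body top left of centre
  fh <- detect_front_hoof(ct)
  # outer bottom corner of the front leg (1 px slack along the hull edge)
  expect_equal(fh$x, 119)
  expect_gte(fh$y, 88)
})

test_that("head vertex errors when the silhouette misses the search box", {
  left_only <- rect_mask(100, 40, 5, 30, 10, 30)
  ct <- extract_contour(left_only)
  # box confined to the far right of the image: shift the fractions so no
  # contour point can fall inside
  expect_error(
    restricted_extremum(ct, range_box(0.3, 0.45, 0.3, 0.45), "y", "min"),
    "empty range")
})

test_that("withers maximises and chest front minimises chord distance", {
  # triangle-wave dorsal arc: apex strictly farthest from the anchor chord
  m <- matrix(0L, 80, 200)
  for (x in 20:180) {
    ytop <- 50 - round(20 * (1 - abs(x - 100) / 80))
    m[ytop:70, x] <- 1L
  }
  ct <- extract_contour(as_mask(m))
  xl <- min(ct$x); xr <- max(ct$x)
  left <- ct[which(ct$x == xl & ct$y == min(ct$y[ct$x == xl])), ][1, ]
  right <- ct[which(ct$x == xr & ct$y == min(ct$y[ct$x == xr])), ][1, ]
  wi <- detect_withers(ct, head_vertex = right, hip_top = left)
  expect_equal(wi$x, 99, tolerance = 2)
  expect_equal(wi$y, 29, tolerance = 2)
  expect_error(detect_withers(ct, right, right), "coincide")

  # straight dorsal segment: all distances 0, the tie rule returns the
  # smallest contour index on the arc
  sq <- extract_contour(rect_mask(60, 40, 10, 49, 10, 29))
  a1 <- sq[sq$x == 12 & sq$y == 10, ][1, ]
  a2 <- sq[sq$x == 45 & sq$y == 10, ][1, ]
  wi0 <- detect_withers(sq, head_vertex = a2, hip_top = a1)
  expect_equal(wi0$index, min(a1$index, a2$index))
})

test_that("shank width is read off the leg cross-section nearest the hoof", {
  ct <- extract_contour(blocky_sheep())
  cb <- tibble::tibble(index = NA_integer_, x = 70, y = 69)
  fh <- detect_front_hoof(ct)
  w <- detect_shank(ct, cb, fh)
  expect_equal(w, 12)
  # legless body: no crossings below the body
  body <- extract_contour(rect_mask(100, 60, 10, 90, 10, 40))
  expect_error(
    detect_shank(body, tibble::tibble(index = NA, x = 50, y = 45),
                 tibble::tibble(index = NA, x = 90, y = 55)),
    "no contour crossings")
})

test_that("curvature landmarks lock onto corners and respect the tie rule", {
  # rounded rectangle: put the search range over one corner
  m <- matrix(0L, 100, 150)
  m[30:70, 20:130] <- 1L
  ct <- extract_contour(as_mask(m))
  # sciatic box (left, vertically central) contains the bottom-left corner
  st <- detect_sciatic_tuberosity(ct, range_config(
    sciatic = range_box(0, 0.15, 0.5, 1.0)), u = 5)
  expect_equal(c(st$x, st$y), c(20, 70), tolerance = 3)

  # constant-curvature arc in range: smallest index wins
  dm <- disk_mask(80, 80, 40, 40, 25)
  ctd <- extract_contour(dm)
  pk <- detect_sciatic_tuberosity(ctd, range_config(
    sciatic = range_box(0, 0.3, 0.3, 0.7)), u = 8)
  sel <- which(in_range_box(ctd, range_box(0, 0.3, 0.3, 0.7)))
  k <- u_chord_curvature(ctd, sel, u = 8, signed = TRUE)
  expect_equal(pk$index, min(ctd$index[sel][k >= max(k) - 1e-9]))
})

test_that("landmarks are translation invariant and mirror-symmetric", {
  spec <- sample_sheep_spec("female", seed = 42)
  r <- render_sheep_side(spec, px_per_cm = 8)
  lm1 <- detect_landmarks_side(extract_contour(r$mask))

  # translation: pad 17 px left, 9 px top
  m <- unclass(r$mask)
  m2 <- matrix(0L, nrow(m) + 9, ncol(m) + 17)
  m2[9 + seq_len(nrow(m)), 17 + seq_len(ncol(m))] <- m
  lm2 <- detect_landmarks_side(extract_contour(as_mask(m2)))
  expect_equal(lm2$x, lm1$x + 17)
  expect_equal(lm2$y, lm1$y + 9)

  # mirroring then pose normalization restores the geometry
  mflip <- as_mask(m[, rev(seq_len(ncol(m)))])
  np <- normalize_pose(mflip)
  expect_true(np$flipped)
  lm3 <- detect_landmarks_side(extract_contour(np$mask))
  expect_equal(lm3$x, lm1$x)
  expect_equal(lm3$y, lm1$y)
  expect_false(normalize_pose(r$mask)$flipped)
})

test_that("detected landmarks lie on the contour and near renderer truth", {
  for (sd in c(3, 14)) {
    spec <- sample_sheep_spec(if (sd %% 2) "female" else "male", seed = sd)
    r <- render_sheep_side(spec)
    ct <- extract_contour(r$mask)
    lm <- detect_landmarks_side(ct)
    # membership in the contour point list
    expect_true(all(paste(lm$x, lm$y) %in% paste(ct$x, ct$y)))
    errs <- landmark_errors(lm, r$landmarks)
    expect_lt(max(errs), 8)
    expect_lt(abs(attr(lm, "ground_y") - r$ground_y), 2)
    expect_lt(abs(attr(lm, "shank_width_px") - r$shank_width_px), 2.5)
  }
})

test_that("dorsal width detection matches the rendered protrusions", {
  spec <- sample_sheep_spec("male", seed = 8)
  r <- render_sheep_dorsal(spec)
  ct <- extract_contour(r$mask)
  lm <- detect_landmarks_dorsal(ct)
  errs <- landmark_errors(lm, r$landmarks)
  expect_lt(max(errs), 5)
  expect_lt(abs(attr(lm, "shoulder_width_px") - r$shoulder_width_px), 3)
  expect_lt(abs(attr(lm, "rump_width_px") - r$rump_width_px), 3)
  # straight-sided rectangle: widths equal the rectangle height, tie rule
  rect <- extract_contour(rect_mask(240, 80, 20, 219, 20, 59))
  lmr <- detect_dorsal_widths(rect, u = 5)
  expect_equal(attr(lmr, "shoulder_width_px"), 39)
  expect_equal(attr(lmr, "rump_width_px"), 39)
})

test_that("landmark sets serialize to JSON", {
  spec <- sample_sheep_spec("female", seed = 5)
  r <- render_sheep_side(spec, px_per_cm = 8)
  lm <- detect_landmarks_side(extract_contour(r$mask))
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(lm, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$view, "side")
  expect_true("withers" %in% names(obj$points))
  expect_equal(obj$ground_y, attr(lm, "ground_y"))
})
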