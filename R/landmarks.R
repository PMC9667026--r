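#' Default landmark search regions
#'
#' Search boxes for each landmark, expressed as fractions of the silhouette
#' bounding box (`x` rightward, `y` downward; the animal faces right in a
#' normalized side view). The published protocol shows these ranges only
#' pictorially, so the defaults encode typical ovine proportions and every
#' box is configurable.
#'
#' @param head,hoof,hip,chest_bottom,sciatic,shoulder,rump,shank
#'   [range_box()] objects overriding the defaults.
#' @return Named list of class `range_config`.
#' @export
range_config <- function(head = range_box(0.55, 1.0, 0.0, 0.5),
                         hoof = range_box(0.50, 1.0, 0.5, 1.0),
                         hip = range_box(0.0, 0.45, 0.0, 0.5),
                         chest_bottom = range_box(0.45, 0.80, 0.4, 0.8),
                         sciatic = range_box(0.0, 0.20, 0.3, 0.8),
                         shoulder = range_box(0.55, 0.80, 0.0, 1.0),
                         rump = range_box(0.10, 0.35, 0.0, 1.0),
                         shank = range_box(0.60, 1.0, 0.7, 1.0)) {
  structure(list(head = head, hoof = hoof, hip = hip,
                 chest_bottom = chest_bottom, sciatic = sciatic,
                 shoulder = shoulder, rump = rump, shank = shank),
            class = "range_config")
}

.lm_row <- function(name, pt) {
  tibble::tibble(landmark = name, index = pt$index[[1]],
                 x = pt$x[[1]], y = pt$y[[1]])
}

#' Head vertex: topmost point of the right half
#'
#' The head of a right-facing sheep is the highest structure in the right
#' part of the silhouette; the detector returns the y-minimal contour point
#' inside the head search box.
#'
#' @param contour Side-view contour (animal facing right).
#' @param cfg A [range_config()].
#' @return One-row tibble (`index`, `x`, `y`).
#' @export
detect_head_vertex <- function(contour, cfg = range_config()) {
  restricted_extremum(contour, cfg$head, axis = "y", mode = "min")
}

#' Hip top: topmost point of the left half
#'
#' The hip-height point is found by the same rule as the head vertex but on
#' the left (rear) part of the silhouette.
#' @inheritParams detect_head_vertex
#' @export
detect_hip_top <- function(contour, cfg = range_config()) {
  restricted_extremum(contour, cfg$hip, axis = "y", mode = "min")
}

#' Facial vertex: globally rightmost contour point
#'
#' In a normalized pose (facing right) the rightmost silhouette point is the
#' tip of the face. Ties break to the smallest contour index.
#' @param contour Side-view contour.
#' @export
detect_facial_vertex <- function(contour) {
  restricted_extremum(contour, range_box(), axis = "x", mode = "max")
}

#' Front hoof: x-maximal hull-supported point of the lower half
#'
#' Restricts to contour points that lie on the convex hull (the "polygon
#' around the outline"), intersects with the lower-half search box, and takes
#' the x-maximal point: the ground-contact corner of the leading foreleg.
#' @inheritParams detect_head_vertex
#' @export
detect_front_hoof <- function(contour, cfg = range_config()) {
  sel <- in_range_box(contour, cfg$hoof) & on_hull(contour)
  if (!any(sel)) {
    # degenerate silhouettes (e.g. a legless ellipse) may have no hull vertex
    # inside the box; fall back to all contour points in the box
    sel <- in_range_box(contour, cfg$hoof)
  }
  if (!any(sel)) stop("empty range: no contour point in hoof search box")
  sub <- contour[sel, , drop = FALSE]
  hit <- which(sub$x == max(sub$x))
  sub[hit[which.min(sub$index[hit])], c("index", "x", "y")]
}

# contour arc between two landmark indices; of the two arcs of the closed
# curve, picks `which` = "upper" (smaller mean y), "shorter" (fewer points)
.contour_arc <- function(contour, i, j, which = c("upper", "shorter")) {
  which <- match.arg(which)
  n <- nrow(contour)
  if (i == j) stop("anchor points coincide")
  fwd <- if (i <= j) i:j else c(i:n, 1:j)
  bwd <- if (j <= i) j:i else c(j:n, 1:i)
  if (which == "shorter") {
    if (length(fwd) <= length(bwd)) fwd else bwd
  } else {
    if (mean(contour$y[fwd]) <= mean(contour$y[bwd])) fwd else bwd
  }
}

#' Withers: farthest dorsal point from the head--hip chord
#'
#' Defines the chord ("straight line b") through the head vertex and the hip
#' top, walks the dorsal arc between the two anchors, and returns the point
#' with the greatest perpendicular distance to the chord — the withers hump.
#'
#' @param contour Side-view contour.
#' @param head_vertex,hip_top One-row landmark tibbles on this contour.
#' @export
detect_withers <- function(contour, head_vertex, hip_top) {
  if (head_vertex$x == hip_top$x && head_vertex$y == hip_top$y) {
    stop("anchor points coincide")
  }
  ln <- line_through(c(hip_top$x, hip_top$y), c(head_vertex$x, head_vertex$y))
  arc <- .contour_arc(contour, hip_top$index, head_vertex$index, "upper")
  d <- point_line_distance(contour$x[arc], contour$y[arc], ln)
  hit <- arc[d == max(d)]
  i <- hit[which.min(contour$index[hit])]
  contour[i, c("index", "x", "y")]
}

#' Chest front: closest point to the nose--hoof chord
#'
#' Walks the frontal arc between the facial vertex and the front hoof and
#' returns the point with the smallest perpendicular distance to the chord
#' through them: the brisket (anterior shoulder) point, the front anchor of
#' body slanting length.
#'
#' @param contour Side-view contour.
#' @param facial_vertex,front_hoof One-row landmark tibbles on this contour.
#' @param trim_nose,trim_hoof Fractions of the arc excluded next to each
#'   anchor. The chord passes through both anchors, so nearby points are
#'   trivially close to it: the muzzle and chin occupy roughly the first
#'   quarter of the arc below the nose, and the lower foreleg converges onto
#'   the chord all the way down to the hoof. The defaults exclude the
#'   head-dominated quarter on the nose side and the leg-dominated 30% on
#'   the hoof side, leaving the neck underside and chest.
#' @export
detect_chest_front <- function(contour, facial_vertex, front_hoof,
                               trim_nose = 0.25, trim_hoof = 0.30) {
  if (facial_vertex$x == front_hoof$x && facial_vertex$y == front_hoof$y) {
    stop("anchor points coincide")
  }
  ln <- line_through(c(facial_vertex$x, facial_vertex$y),
                     c(front_hoof$x, front_hoof$y))
  arc <- .contour_arc(contour, facial_vertex$index, front_hoof$index, "shorter")
  # orient the arc to run from the facial vertex toward the hoof
  if (arc[1] != facial_vertex$index) arc <- rev(arc)
  t1 <- ceiling(trim_nose * length(arc))
  t2 <- ceiling(trim_hoof * length(arc))
  arc <- arc[(t1 + 1):(length(arc) - t2)]
  d <- point_line_distance(contour$x[arc], contour$y[arc], ln)
  hit <- arc[d == min(d)]
  i <- hit[which.min(contour$index[hit])]
  contour[i, c("index", "x", "y")]
}

# maximum convexity-filtered u-chord curvature inside a box; skeletal
# prominences are convex, so concave leg/neck junction corners are excluded
.curvature_peak <- function(contour, box, u = NULL, sel_extra = NULL) {
  sel <- in_range_box(contour, box)
  if (!is.null(sel_extra)) sel <- sel & sel_extra
  if (!any(sel)) stop("empty range: no contour point in search box")
  idx <- which(sel)
  k <- u_chord_curvature(contour, index = idx, u = u, signed = TRUE)
  if (all(k <= 0)) k <- abs(k) # degenerate: nothing convex in range
  hit <- idx[k == max(k)]
  i <- hit[which.min(contour$index[hit])]
  contour[i, c("index", "x", "y")]
}

#' Sciatic tuberosity: curvature peak of the rear range
#'
#' The rearmost pelvic prominence is the point of maximal u-chord curvature
#' (convex side) inside the sciatic search box; it is the rear anchor of body
#' slanting length.
#'
#' @inheritParams detect_head_vertex
#' @param u Chord step for the curvature estimator; default 1% of the contour
#'   point count.
#' @export
detect_sciatic_tuberosity <- function(contour, cfg = range_config(), u = NULL) {
  .curvature_peak(contour, cfg$sciatic, u = u)
}

#' Chest bottom: curvature peak of the sternum range
#'
#' The lower sternum edge is the point of maximal u-chord curvature (convex
#' side) inside the chest-bottom search box; chest depth is measured from the
#' withers down to this point.
#' @inheritParams detect_sciatic_tuberosity
#' @export
detect_chest_bottom <- function(contour, cfg = range_config(), u = NULL) {
  .curvature_peak(contour, cfg$chest_bottom, u = u)
}

#' Ground line: lowest contour row
#'
#' Heights (withers, hip) are measured down to the ground, taken as the
#' maximal `y` over the contour (hoof--ground contact).
#' @param contour Side-view contour.
#' @return Ground row `y` (px).
#' @export
ground_line <- function(contour) {
  max(contour$y)
}

#' Shank width at one third of the chest-to-ground drop
#'
#' Measures the horizontal width of the leading foreleg at the row one third
#' of the way down from the chest-bottom point to the hoof, where the
#' metacarpus is thinnest. Contour crossings on that row are clustered into
#' leg sections; the pair closest in `x` to the hoof is used.
#'
#' @param contour Side-view contour.
#' @param chest_bottom,front_hoof One-row landmark tibbles.
#' @return Width in pixels.
#' @export
detect_shank <- function(contour, chest_bottom, front_hoof) {
  y_row <- round(chest_bottom$y + (front_hoof$y - chest_bottom$y) / 3)
  on_row <- which(contour$y == y_row)
  if (length(on_row) == 0) stop("no contour crossings at shank height")
  xs <- sort(unique(contour$x[on_row]))
  # cluster boundary pixels into edge groups (gap > 2 px separates edges),
  # then pair consecutive edges into leg cross-sections
  brk <- c(0, which(diff(xs) > 2), length(xs))
  edges <- vapply(seq_len(length(brk) - 1), function(k) {
    mean(range(xs[(brk[k] + 1):brk[k + 1]]))
  }, numeric(1))
  if (length(edges) < 2) stop("no leg cross-section at shank height")
  if (length(edges) %% 2 == 1) edges <- edges[-length(edges)]
  pair_i <- seq(1, length(edges), by = 2)
  mids <- (edges[pair_i] + edges[pair_i + 1]) / 2
  k <- pair_i[which.min(abs(mids - front_hoof$x))]
  edges[k + 1] - edges[k] + 1
}

#' Dorsal shoulder and rump edge points
#'
#' On the dorsal (top-down) view the scapulae and hip joints protrude
#' laterally. For each search box (shoulders, rump) the detector finds the
#' maximal convex-curvature point on each side of the body axis (the
#' horizontal line through the silhouette centroid); the width is the
#' absolute difference of the two `y` values.
#'
#' @param contour Dorsal-view contour, body axis along `x`.
#' @inheritParams detect_sciatic_tuberosity
#' @return Tibble with rows `shoulder_left`, `shoulder_right`, `rump_left`,
#'   `rump_right` and attributes `shoulder_width_px`, `rump_width_px`.
#' @export
detect_dorsal_widths <- function(contour, cfg = range_config(), u = NULL) {
  axis_y <- mean(contour$y)
  upper <- contour$y < axis_y
  lower <- contour$y > axis_y
  pick <- function(box, side_sel, nm) {
    if (!any(in_range_box(contour, box) & side_sel)) {
      stop("empty range: no ", nm, " points on one side of the body axis")
    }
    .curvature_peak(contour, box, u = u, sel_extra = side_sel)
  }
  sl <- pick(cfg$shoulder, upper, "shoulder")
  sr <- pick(cfg$shoulder, lower, "shoulder")
  rl <- pick(cfg$rump, upper, "rump")
  rr <- pick(cfg$rump, lower, "rump")
  out <- dplyr::bind_rows(
    .lm_row("shoulder_left", sl), .lm_row("shoulder_right", sr),
    .lm_row("rump_left", rl), .lm_row("rump_right", rr)
  )
  attr(out, "shoulder_width_px") <- abs(sr$y - sl$y)
  attr(out, "rump_width_px") <- abs(rr$y - rl$y)
  out
}

#' Normalize side-view pose to face right
#'
#' The landmark rules assume the animal faces right (the facial vertex is the
#' rightmost point). The head carries the highest silhouette point, so if the
#' topmost contour pixel falls in the left half of the bounding box the mask
#' is mirrored left-right.
#'
#' @param mask A `sheep_mask`.
#' @return List with `mask` (possibly flipped) and `flipped` (logical).
#' @export
normalize_pose <- function(mask) {
  ct <- extract_contour(mask)
  top <- ct[which.min(ct$y), ]
  midx <- (min(ct$x) + max(ct$x)) / 2
  if (top$x < midx) {
    m <- unclass(mask)[, rev(seq_len(ncol(mask))), drop = FALSE]
    list(mask = as_mask(m), flipped = TRUE)
  } else {
    list(mask = mask, flipped = FALSE)
  }
}

#' Detect the full side-view landmark set
#'
#' Runs every side-view rule in dependency order: head vertex, hip top and
#' facial vertex by range-restricted extremum; front hoof on the hull; withers
#' and chest front by chord-distance; sciatic tuberosity and chest bottom by
#' curvature; ground line; shank width.
#'
#' @param contour Side-view contour, animal facing right.
#' @param cfg A [range_config()].
#' @param u Curvature chord step (default 1% of contour points).
#' @return Tibble of class `landmark_set` (`landmark`, `index`, `x`, `y`) with
#'   attributes `view`, `ground_y` and `shank_width_px`.
#' @export
detect_landmarks_side <- function(contour, cfg = range_config(), u = NULL) {
  hv <- detect_head_vertex(contour, cfg)
  ht <- detect_hip_top(contour, cfg)
  fv <- detect_facial_vertex(contour)
  fh <- detect_front_hoof(contour, cfg)
  wi <- detect_withers(contour, hv, ht)
  cf <- detect_chest_front(contour, fv, fh)
  st <- detect_sciatic_tuberosity(contour, cfg, u = u)
  cb <- detect_chest_bottom(contour, cfg, u = u)
  gy <- ground_line(contour)
  sh <- detect_shank(contour, cb, fh)
  out <- dplyr::bind_rows(
    .lm_row("head_vertex", hv), .lm_row("hip_top", ht),
    .lm_row("facial_vertex", fv), .lm_row("front_hoof", fh),
    .lm_row("withers", wi), .lm_row("chest_front", cf),
    .lm_row("sciatic_tuberosity", st), .lm_row("chest_bottom", cb)
  )
  attr(out, "view") <- "side"
  attr(out, "ground_y") <- gy
  attr(out, "shank_width_px") <- sh
  class(out) <- c("landmark_set", class(out))
  out
}

#' Detect the dorsal-view landmark set
#' @param contour Dorsal-view contour.
#' @inheritParams detect_landmarks_side
#' @return Tibble of class `landmark_set` with attributes `view`,
#'   `shoulder_width_px`, `rump_width_px`.
#' @export
detect_landmarks_dorsal <- function(contour, cfg = range_config(), u = NULL) {
  out <- detect_dorsal_widths(contour, cfg, u = u)
  attr(out, "view") <- "dorsal"
  class(out) <- c("landmark_set", class(out))
  out
}

#' Serialize a landmark set to JSON
#' @param landmarks A `landmark_set`.
#' @param path JSON file path.
#' @export
write_landmarks_json <- function(landmarks, path) {
  obj <- list(
    view = attr(landmarks, "view"),
    points = stats::setNames(
      lapply(seq_len(nrow(landmarks)),
             function(i) list(x = landmarks$x[i], y = landmarks$y[i])),
      landmarks$landmark
    )
  )
  if (!is.null(attr(landmarks, "ground_y"))) {
    obj$ground_y <- attr(landmarks, "ground_y")
  }
  for (a in c("shank_width_px", "shoulder_width_px", "rump_width_px")) {
    if (!is.null(attr(landmarks, a))) obj[[a]] <- attr(landmarks, a)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a contour with detected landmarks
#'
#' Visual QC overlay: the contour polyline with landmark points labelled.
#'
#' @param contour Contour tibble.
#' @param landmarks Optional `landmark_set` to overlay.
#' @return A ggplot object (y axis reversed to match image coordinates).
#' @export
plot_landmarks <- function(contour, landmarks = NULL) {
  p <- ggplot2::ggplot(contour, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.3, colour = "grey40") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (!is.null(landmarks)) {
    p <- p +
      ggplot2::geom_point(data = landmarks, colour = "red", size = 2) +
      ggplot2::geom_text(
        data = landmarks,
        ggplot2::aes(label = .data$landmark),
        nudge_y = -12, size = 2.7, colour = "red"
      )
  }
  p
}
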