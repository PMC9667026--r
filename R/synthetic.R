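#' Reference trait moments by sex
#'
#' Sex-stratified means, SDs and observed ranges of body weight and the eight
#' body-size traits of adult Ujumqin sheep (113 rams, 219 ewes), used as the
#' default moments of the trait simulator and as truncation bounds for
#' anatomically plausible draws.
#'
#' @return Tibble (`sex`, `trait`, `mean`, `sd`, `min`, `max`, `n`).
#' @export
trait_moments <- function() {
  tr <- c("BW", "BSL", "HW", "CD", "HH", "SW", "RW", "CC", "SC")
  tibble::tibble(
    sex = rep(c("male", "female"), each = length(tr)),
    trait = rep(tr, 2),
    mean = c(54.09, 72.56, 69.29, 30.90, 69.84, 20.61, 22.74, 95.88, 9.04,
             46.06, 67.50, 63.70, 29.18, 66.33, 20.21, 22.12, 101.31, 9.01),
    sd = c(9.36, 4.40, 3.85, 2.68, 3.71, 2.48, 2.81, 7.84, 0.84,
           9.85, 5.14, 4.15, 4.03, 4.08, 2.66, 2.65, 9.85, 0.73),
    min = c(36, 60, 59, 25, 61, 15, 18, 80, 6.5,
            24.1, 54, 51, 19, 55, 13, 15, 72, 6.5),
    max = c(77, 83, 79, 39.5, 81, 27, 29, 116, 10.6,
            71, 81, 74, 39, 74, 27, 28, 125, 11.2),
    n = rep(c(113L, 219L), each = length(tr))
  )
}

#' Reference calibration-plate scale equations
#'
#' Quadratic px-per-cm vs distance relations of the two-camera reference rig
#' (back plate moved over 0--105 cm, side plate over 0--50 cm, photographed
#' at 5 cm intervals).
#'
#' @param view `"back"` or `"side"`.
#' @return Named vector `c(c2, c1, c0)`.
#' @export
reference_scale_coefficients <- function(view = c("back", "side")) {
  view <- match.arg(view)
  switch(view,
         back = c(c2 = 0.0002, c1 = 0.0015, c0 = 1.9325),
         side = c(c2 = 0.0015, c1 = 0.1008, c0 = 21.314))
}

#' Simulation configuration
#'
#' @param moments Trait moments tibble, default [trait_moments()].
#' @param rho Exchangeable correlation among the eight size traits (only
#'   selected rank correlations are published for the reference flock, so a
#'   single configurable exchangeable value is the default), or a full 8x8
#'   positive semi-definite correlation matrix in trait order
#'   `BSL, HW, CD, HH, SW, RW, CC, SC`.
#' @param bw_noise_sd Residual SD (kg) of the body-weight generator, per sex;
#'   defaults are the standard errors of estimate of the final sex-specific
#'   weight equations (4.49 ewes, 3.75 rams).
#' @param sex_ratio Proportion of males (default 113/332).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(moments = trait_moments(), rho = 0.6,
                       bw_noise_sd = c(male = 3.75, female = 4.49),
                       sex_ratio = 113 / 332) {
  k <- length(.trait_names)
  if (is.matrix(rho)) {
    if (!isTRUE(all.equal(rho, t(rho))) ||
        any(eigen(rho, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
      stop("correlation matrix must be symmetric positive semi-definite")
    }
    R <- rho
  } else {
    if (rho < -1 / (k - 1) || rho >= 1) {
      stop("exchangeable rho outside the positive semi-definite range")
    }
    R <- matrix(rho, k, k); diag(R) <- 1
  }
  structure(list(moments = moments, corr = R, bw_noise_sd = bw_noise_sd,
                 sex_ratio = sex_ratio),
            class = "sim_config")
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# draw n size-trait vectors for one sex: truncated multivariate normal by
# rejection (componentwise bounds + mild anatomical consistency), with a
# clamp fallback after max_tries rounds
.draw_traits <- function(n, sex, config, max_tries = 200, anatomic = FALSE) {
  mo <- config$moments[config$moments$sex == sex, ]
  mo <- mo[match(.trait_names, mo$trait), ]
  mu <- mo$mean; sdv <- mo$sd
  Sigma <- config$corr * (sdv %o% sdv)
  ok_rows <- function(m) {
    inb <- rep(TRUE, nrow(m))
    for (j in seq_along(.trait_names)) {
      inb <- inb & m[, j] >= mo$min[j] & m[, j] <= mo$max[j]
    }
    if (anatomic) {
      # renderer consistency: hip roughly at or above wither height, chest
      # depth a plausible fraction of wither height
      hw <- m[, .trait_names == "HW"]; hh <- m[, .trait_names == "HH"]
      cd <- m[, .trait_names == "CD"]
      inb <- inb & hh / hw >= 0.985 & hh / hw <= 1.10 &
        cd / hw >= 0.35 & cd / hw <= 0.58
    }
    inb
  }
  out <- matrix(NA_real_, 0, length(.trait_names))
  tries <- 0
  while (nrow(out) < n && tries < max_tries) {
    m <- MASS::mvrnorm(max(2 * n, 20), mu = mu, Sigma = Sigma)
    out <- rbind(out, m[ok_rows(m), , drop = FALSE])
    tries <- tries + 1
  }
  if (nrow(out) < n) {
    m <- MASS::mvrnorm(n - nrow(out), mu = mu, Sigma = Sigma)
    for (j in seq_along(.trait_names)) {
      m[, j] <- pmin(pmax(m[, j], mo$min[j]), mo$max[j])
    }
    if (anatomic) {
      jhw <- which(.trait_names == "HW"); jhh <- which(.trait_names == "HH")
      jcd <- which(.trait_names == "CD")
      m[, jhh] <- pmin(pmax(m[, jhh], 0.985 * m[, jhw]), 1.10 * m[, jhw])
      m[, jcd] <- pmin(pmax(m[, jcd], 0.35 * m[, jhw]), 0.58 * m[, jhw])
    }
    out <- rbind(out, m)
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- .trait_names
  tibble::as_tibble(out)
}

#' Draw an anatomically consistent sheep specification
#'
#' Samples the eight size traits from a truncated multivariate normal with
#' the configured sex moments and correlation, and derives the renderer
#' geometry (shank diameter from shank girth, pose jitter from the seed).
#'
#' @param sex `"male"` or `"female"`.
#' @param seed Integer seed (drives both the trait draw and pose jitter).
#' @param config A [sim_config()].
#' @return List of class `sheep_spec`: sex, the traits (cm), and
#'   `shank_diameter` (cm).
#' @export
sample_sheep_spec <- function(sex = c("female", "male"), seed = NULL,
                              config = sim_config()) {
  sex <- match.arg(sex)
  tr <- .with_seed(seed, .draw_traits(1, sex, config, anatomic = TRUE))
  spec <- as.list(tr[1, ])
  spec$sex <- sex
  spec$shank_diameter <- spec$SC / pi
  spec$seed <- seed
  class(spec) <- "sheep_spec"
  spec
}

## ---- outline helpers (continuous geometry in cm) --------------------------

.seg <- function(p1, p2, step = 0.15) {
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(2, ceiling(len / step))
  t <- seq(0, 1, length.out = n)
  cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]))
}

.ease <- function(p1, p2, step = 0.15) {
  # half-cosine ease between two points (zero end slopes in the blended axis)
  len <- sqrt(sum((p2 - p1)^2))
  n <- max(4, ceiling(len / step))
  t <- seq(0, 1, length.out = n)
  s <- (1 - cos(pi * t)) / 2
  cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + s * (p2[2] - p1[2]))
}

.bez2 <- function(p1, ctrl, p2, step = 0.15) {
  len <- sqrt(sum((ctrl - p1)^2)) + sqrt(sum((p2 - ctrl)^2))
  n <- max(6, ceiling(len / step))
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p1[1] + 2 * t * (1 - t) * ctrl[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p1[2] + 2 * t * (1 - t) * ctrl[2] + t^2 * p2[2]
  cbind(x, y)
}

# intersection of the line through p1 (direction p1 - back1) with the line
# through p2 (direction d2); used to place tangent-matching bezier controls
.isect <- function(p1, back1, p2, d2) {
  d1 <- p1 - back1
  A <- cbind(d1, -d2)
  if (abs(det(A)) < 1e-9) return((p1 + p2) / 2)
  ts <- solve(A, p2 - p1)
  p1 + ts[1] * d1
}

.earc <- function(cx, cy, a, b, from_deg, to_deg, step = 0.15) {
  arc_len <- abs(to_deg - from_deg) / 360 * pi * (3 * (a + b))
  n <- max(8, ceiling(arc_len / step))
  phi <- seq(from_deg, to_deg, length.out = n) * pi / 180
  cbind(cx + a * cos(phi), cy + b * sin(phi))
}

# one leg, traversed downward on the leading (larger-x) edge, across the
# hoof, and upward on the trailing edge; legs taper from the belly to the
# metacarpus (half-width ws) at the knee and are parallel-sided below
.leg_path <- function(cx, wt, ws, h_att_f, h_att_r, h_knee, step = 0.15) {
  rbind(
    .seg(c(cx + wt, h_att_f), c(cx + ws, h_knee), step),
    .seg(c(cx + ws, h_knee), c(cx + ws, 0), step),
    .seg(c(cx + ws, 0), c(cx - ws, 0), step),
    .seg(c(cx - ws, 0), c(cx - ws, h_knee), step),
    .seg(c(cx - ws, h_knee), c(cx - wt, h_att_r), step)
  )
}

# side-view silhouette outline in cm (x rightward, h = height above ground),
# traversed clockwise in image coordinates; returns the outline and the
# ground-truth landmarks in the same frame
.side_outline <- function(spec, jitter = c(head = 0, far_front = 0, far_hind = 0)) {
  HW <- spec$HW; HH <- spec$HH; BSL <- spec$BSL; CD <- spec$CD
  ws <- spec$shank_diameter / 2

  h_B <- HW - CD              # sternum bottom edge
  h_F <- h_B + 6              # brisket (chest front) anchor
  h_S <- 0.78 * HH            # sciatic tuberosity height
  # chest-front x chosen so that the slant distance from the brisket to the
  # sciatic tip (at x = -2.3) equals the specified BSL
  x_F <- sqrt(BSL^2 - (h_F - h_S)^2) - 2.3
  head_lift <- 20 + jitter[["head"]]

  Tt <- c(0.16 * x_F, HH)                      # hip apex
  bk <- min(HW, HH) - 2.5                      # mid-back (saddle) level
  back0 <- c(0.40 * x_F, bk)                   # rear end of the level back
  W <- c(0.70 * x_F, HW)                       # withers
  hx <- x_F + 0.12 * BSL                       # head centre x
  hc <- HW + head_lift - 6.5                   # head centre height
  ear_h <- 3.2
  V <- c(hx + 9 * cos(95 * pi / 180), hc + 6.5 + ear_h) # head vertex: ear tip
  E1 <- c(hx + 9 * cos(112 * pi / 180), hc + 6.5 * sin(112 * pi / 180))
  E2 <- c(hx + 9 * cos(72 * pi / 180), hc + 6.5 * sin(72 * pi / 180))
  Nn <- c(hx + 9.6, hc)                        # nose tip (wedge apex)
  M1 <- c(hx + 9 * cos(38 * pi / 180), hc + 6.5 * sin(38 * pi / 180))
  M2 <- c(hx + 9 * cos(-38 * pi / 180), hc + 6.5 * sin(-38 * pi / 180))
  HJ <- c(hx + 9 * cos(140 * pi / 180), hc + 6.5 * sin(140 * pi / 180))
  Jj <- c(hx + 9 * cos(-100 * pi / 180), hc + 6.5 * sin(-100 * pi / 180))
  Ff <- c(x_F, h_F)                            # chest front
  Bb <- c(x_F - 3.5, h_B)                      # chest bottom (sternum)
  Ss <- c(-2.3, h_S)                           # sciatic tuberosity (pin-bone tip)
  Sb <- c(1.3, h_S - 4.5)                      # below the tip
  Sa <- c(1.5, h_S + 4.5)                      # above the tip
  C1 <- c(3.0, HH - 4.5)                       # croup turn start

  # legs: leading/far fore and hind pairs; far legs carry the pose jitter
  wt <- 3
  cf1 <- 0.815 * x_F
  cf2 <- cf1 - 8.5 + jitter[["far_front"]]
  ch1 <- 0.148 * x_F
  ch2 <- ch1 + 8.5 + jitter[["far_hind"]]
  h_knee <- 0.75 * h_B
  x_bt <- ch1 - wt                             # rear end of the belly line
  belly_h <- function(x) h_B + 2.5 * (Bb[1] - x) / (Bb[1] - x_bt)

  leg <- function(cx) {
    .leg_path(cx, wt, ws, belly_h(cx + wt), belly_h(cx - wt), h_knee)
  }

  # dorsal line starts at the hip ridge (a peak over the hip bones)
  hump_x <- seq(Tt[1] - 6, Tt[1] + 6, by = 0.15)
  hump <- cbind(hump_x, HH - 0.5 * abs(hump_x - Tt[1]))
  out <- rbind(
    hump,
    .ease(c(Tt[1] + 6, HH - 3), back0)[-1, , drop = FALSE],
    .seg(back0, W)[-1, , drop = FALSE],
    .seg(W, HJ)[-1, , drop = FALSE],
    .earc(hx, hc, 9, 6.5, 140, 112)[-1, , drop = FALSE], # up the back of head
    .seg(E1, V)[-1, , drop = FALSE],                     # ear, peaking at V
    .seg(V, E2)[-1, , drop = FALSE],
    .earc(hx, hc, 9, 6.5, 72, 38)[-1, , drop = FALSE],   # forehead
    .seg(M1, Nn)[-1, , drop = FALSE],                    # muzzle wedge to nose
    .seg(Nn, M2)[-1, , drop = FALSE],
    .earc(hx, hc, 9, 6.5, -38, -100)[-1, , drop = FALSE], # chin to jaw
    # neck underside bows back toward the body so that the brisket is the
    # unique closest point to the nose--hoof chord
    .bez2(Jj, c((Jj[1] + Ff[1]) / 2 - 2.5, (Jj[2] + Ff[2]) / 2),
          Ff)[-1, , drop = FALSE],
    .seg(Ff, Bb)[-1, , drop = FALSE],
    .seg(Bb, c(cf1 + wt, belly_h(cf1 + wt)))[-1, , drop = FALSE],
    leg(cf1)[-1, , drop = FALSE],
    .seg(c(cf1 - wt, belly_h(cf1 - wt)),
         c(cf2 + wt, belly_h(cf2 + wt)))[-1, , drop = FALSE],
    leg(cf2)[-1, , drop = FALSE],
    .seg(c(cf2 - wt, belly_h(cf2 - wt)),
         c(ch2 + wt, belly_h(ch2 + wt)))[-1, , drop = FALSE],
    leg(ch2)[-1, , drop = FALSE],
    .seg(c(ch2 - wt, belly_h(ch2 - wt)),
         c(ch1 + wt, belly_h(ch1 + wt)))[-1, , drop = FALSE],
    leg(ch1)[-1, , drop = FALSE],
    # buttock up to the protruding sciatic tip, straight rear line, and a
    # tangent-matched croup turn into the hip ridge
    .bez2(c(ch1 - wt, belly_h(ch1 - wt)), c(4.2, h_S - 7.5),
          Sb)[-1, , drop = FALSE],
    .seg(Sb, Ss)[-1, , drop = FALSE],
    .seg(Ss, Sa)[-1, , drop = FALSE],
    .seg(Sa, C1)[-1, , drop = FALSE],
    .bez2(C1, .isect(C1, Sa, c(Tt[1] - 6, HH - 3), c(1, 0.5)),
          c(Tt[1] - 6, HH - 3))[-1, , drop = FALSE]
  )
  truths <- list(
    head_vertex = V, facial_vertex = Nn, hip_top = Tt, withers = W,
    chest_front = Ff, chest_bottom = Bb, sciatic_tuberosity = Ss,
    front_hoof = c(cf1 + ws, 0)
  )
  list(outline = out, truths = truths, shank_diameter = spec$shank_diameter,
       x_F = x_F)
}

# dorsal silhouette: half-width profile with scapular and hip protrusions
.dorsal_outline <- function(spec, jitter = 0) {
  SW <- spec$SW; RW <- spec$RW; BSL <- spec$BSL
  L <- sqrt(BSL^2) + 18           # body plus head, matches the side span
  xr <- 0.18 * L                  # rump protrusion apex
  xs <- 0.65 * L                  # shoulder protrusion apex
  w_waist <- 0.42 * min(SW, RW)
  hw <- 5.5                       # head half-width
  hcx <- L - 8                    # head centre
  profile <- function(side) {
    base <- rbind(
      .earc(4, 0, 4, 0.8 * RW / 2, 180, 90)[, c(1, 2)],
      .seg(c(4, 0.8 * RW / 2), c(xr - 5, 0.9 * RW / 2))[-1, , drop = FALSE],
      .seg(c(xr - 5, 0.9 * RW / 2), c(xr, RW / 2))[-1, , drop = FALSE],
      .seg(c(xr, RW / 2), c(xr + 6, w_waist))[-1, , drop = FALSE],
      .seg(c(xr + 6, w_waist), c(xs - 6, 0.92 * SW / 2))[-1, , drop = FALSE],
      .seg(c(xs - 6, 0.92 * SW / 2), c(xs, SW / 2))[-1, , drop = FALSE],
      .seg(c(xs, SW / 2), c(xs + 6, 0.62 * SW / 2))[-1, , drop = FALSE],
      .seg(c(xs + 6, 0.62 * SW / 2),
           c(hcx - 7, hw * sqrt(1 - (7 / 8)^2)))[-1, , drop = FALSE],
      .earc(hcx, 0, 8, hw, 180 - acos(7 / 8) * 180 / pi, 90)[-1, , drop = FALSE]
    )
    base[, 2] <- base[, 2] * side
    base
  }
  # traverse: tail->nose along the upper (negative-y) side, around the nose
  # cap, then nose->tail along the lower side
  up <- profile(-1)
  down <- profile(1)
  out <- rbind(up, .earc(hcx, 0, 8, hw, -90, 90)[-1, , drop = FALSE],
               down[rev(seq_len(nrow(down))), ][-1, , drop = FALSE])
  truths <- list(
    shoulder_left = c(xs, -SW / 2), shoulder_right = c(xs, SW / 2),
    rump_left = c(xr, -RW / 2), rump_right = c(xr, RW / 2)
  )
  list(outline = out, truths = truths)
}

## ---- rasterization --------------------------------------------------------

#' Rasterize a closed polygon into a binary mask
#'
#' Even-odd scanline fill: a pixel `(x, y)` (zero-based, integer lattice) is
#' foreground when the point lies inside the polygon.
#'
#' @param xs,ys Polygon vertex coordinates in pixel units (closed implicitly).
#' @param width,height Output mask size.
#' @return A `sheep_mask`.
#' @export
rasterize_polygon <- function(xs, ys, width, height) {
  m <- matrix(0L, nrow = height, ncol = width)
  x1 <- xs; y1 <- ys
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  keep <- !(y1 == y2)
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  for (row in 0:(height - 1)) {
    cr <- (y1 <= row) != (y2 <= row)
    if (!any(cr)) next
    xc <- x1[cr] + (row - y1[cr]) / (y2[cr] - y1[cr]) * (x2[cr] - x1[cr])
    xc <- sort(xc)
    for (k in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[k]); hi <- floor(xc[k + 1] - 1e-9)
      if (hi >= lo) {
        lo <- max(lo, 0); hi <- min(hi, width - 1)
        if (hi >= lo) m[row + 1, (lo:hi) + 1] <- 1L
      }
    }
  }
  as_mask(m)
}

.truth_tibble <- function(truths, to_px) {
  purrr::map_dfr(names(truths), function(nm) {
    p <- to_px(truths[[nm]])
    tibble::tibble(landmark = nm, x = p[1], y = p[2])
  })
}

#' Render a side-view sheep silhouette with ground truth
#'
#' Builds a parametric right-facing silhouette (level back with hip hump and
#' withers, raised head on a rising neck, brisket and sternum corners,
#' sciatic prominence, four tapering legs) from a [sample_sheep_spec()] draw,
#' rasterizes it at a known scale, and records the true pixel location of
#' every landmark the detectors are supposed to find. Deterministic given
#' `(spec, px_per_cm)`.
#'
#' @param spec A `sheep_spec`.
#' @param px_per_cm True image scale (default 12, about a 1000 px body).
#' @param margin_cm Background margin around the animal.
#' @param jitter_pose Apply small seeded pose jitter (head lift, far-leg
#'   stance) drawn from `spec$seed`.
#' @return List: `mask`, `landmarks` (ground-truth tibble, px), `ground_y`,
#'   `shank_width_px`, `truth` (one-row tibble of true trait values, cm),
#'   `px_per_cm`.
#' @export
render_sheep_side <- function(spec, px_per_cm = 12, margin_cm = 6,
                              jitter_pose = TRUE) {
  jit <- c(head = 0, far_front = 0, far_hind = 0)
  if (jitter_pose && !is.null(spec$seed)) {
    jit_vals <- .with_seed(spec$seed + 1000003L,
                           stats::runif(3, c(-2, -1.2, -1.2), c(2, 1.2, 1.2)))
    jit <- c(head = jit_vals[1], far_front = jit_vals[2],
             far_hind = jit_vals[3])
  }
  geo <- .side_outline(spec, jitter = jit)
  out <- geo$outline
  x_min <- min(out[, 1]); x_max <- max(out[, 1])
  top <- max(out[, 2])
  s <- px_per_cm
  width <- ceiling((x_max - x_min + 2 * margin_cm) * s)
  height <- ceiling((top + 2 * margin_cm) * s)
  to_px <- function(p) {
    c((p[1] - x_min + margin_cm) * s, (top + margin_cm - p[2]) * s)
  }
  xs <- (out[, 1] - x_min + margin_cm) * s
  ys <- (top + margin_cm - out[, 2]) * s
  mask <- rasterize_polygon(xs, ys, width, height)
  lms <- .truth_tibble(geo$truths, to_px)
  truth <- tibble::tibble(
    HW = spec$HW, HH = spec$HH, BSL = spec$BSL, CD = spec$CD,
    SW = spec$SW, RW = spec$RW,
    CC = chest_circumference(spec$SW, spec$CD),
    SC = pi * spec$shank_diameter
  )
  list(mask = mask, landmarks = lms,
       ground_y = (top + margin_cm) * s,
       shank_width_px = spec$shank_diameter * s,
       truth = truth, px_per_cm = s)
}

#' Render a dorsal-view sheep silhouette with ground truth
#'
#' Top-down outline with lateral scapular and hip protrusions whose apex
#' separations equal the true shoulder and rump widths.
#'
#' @inheritParams render_sheep_side
#' @return List: `mask`, `landmarks` (truth tibble, px),
#'   `shoulder_width_px`, `rump_width_px`, `px_per_cm`.
#' @export
render_sheep_dorsal <- function(spec, px_per_cm = 12, margin_cm = 6) {
  geo <- .dorsal_outline(spec)
  out <- geo$outline
  x_min <- min(out[, 1]); y_min <- min(out[, 2])
  s <- px_per_cm
  width <- ceiling((max(out[, 1]) - x_min + 2 * margin_cm) * s)
  height <- ceiling((max(out[, 2]) - y_min + 2 * margin_cm) * s)
  to_px <- function(p) {
    c((p[1] - x_min + margin_cm) * s, (p[2] - y_min + margin_cm) * s)
  }
  xs <- (out[, 1] - x_min + margin_cm) * s
  ys <- (out[, 2] - y_min + margin_cm) * s
  mask <- rasterize_polygon(xs, ys, width, height)
  lms <- .truth_tibble(geo$truths, to_px)
  list(mask = mask, landmarks = lms,
       shoulder_width_px = spec$SW * s, rump_width_px = spec$RW * s,
       px_per_cm = s)
}

## ---- tabular generators ---------------------------------------------------

#' Generate a trait table with known weight model
#'
#' Draws size traits per sex from the configured truncated multivariate
#' normal and generates body weight from the final sex-specific published
#' weight equation plus Gaussian residual noise at the equation's standard
#' error of estimate (ewes: 3-predictor equation, SE 4.49; rams: 6-predictor
#' equation, SE 3.75).
#'
#' @param n Total number of animals.
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Trait table tibble (`animal_id`, `sex`, `BW`, eight traits).
#' @export
generate_trait_table <- function(n = 332, config = sim_config(), seed = NULL) {
  .with_seed(seed, {
    n_male <- round(n * config$sex_ratio)
    n_female <- n - n_male
    tabs <- purrr::map_dfr(c("male", "female"), function(sx) {
      nn <- if (sx == "male") n_male else n_female
      if (nn == 0) return(NULL)
      tr <- .draw_traits(nn, sx, config)
      eq <- if (sx == "male") "ram-6" else "ewe-3"
      mu_bw <- predict_weight(tr, eq)
      tr$BW <- mu_bw + stats::rnorm(nn, 0, config$bw_noise_sd[[sx]])
      tr$sex <- sx
      tr
    })
    tabs$animal_id <- sprintf("S%04d", seq_len(nrow(tabs)))
    dplyr::select(tabs, "animal_id", "sex", "BW", dplyr::all_of(.trait_names))
  })
}

#' Generate calibration-plate samples along a reference equation
#'
#' Evaluates the reference quadratic scale equation of the chosen view at
#' the given plate distances (default: the rig's 5 cm grid over the view's
#' range of motion) and adds optional Gaussian noise.
#'
#' @param view `"back"` or `"side"`.
#' @param heights Plate distances in cm; default `seq(0, 105, 5)` for the
#'   back and `seq(0, 50, 5)` for the side.
#' @param noise_sd Gaussian noise SD on the ratio (px per cm); default 0.
#' @param seed Integer seed for the noise.
#' @return Tibble (`view`, `distance`, `ratio`).
#' @export
generate_calibration_samples <- function(view = c("back", "side"),
                                         heights = NULL, noise_sd = 0,
                                         seed = NULL) {
  view <- match.arg(view)
  if (is.null(heights)) {
    heights <- seq(.scale_domains[[view]][1], .scale_domains[[view]][2], by = 5)
  }
  co <- reference_scale_coefficients(view)
  ratio <- co[["c2"]] * heights^2 + co[["c1"]] * heights + co[["c0"]]
  if (noise_sd > 0) {
    ratio <- .with_seed(seed, ratio + stats::rnorm(length(heights), 0, noise_sd))
  }
  tibble::tibble(view = view, distance = heights, ratio = ratio)
}

#' Generate a collection manifest with a missingness pattern
#'
#' Emulates field collection: `n_unrecorded` animals whose data were never
#' recorded, `n_missing_weight` missing the body weight, and
#' `n_missing_size` missing one random size trait; the affected records are
#' chosen at random without overlap.
#'
#' @param n_total Total animals in the manifest.
#' @param n_unrecorded,n_missing_weight,n_missing_size Counts of each defect.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Manifest tibble for [filter_complete()]: trait table columns plus
#'   `recorded`.
#' @export
generate_manifest <- function(n_total = 350, n_unrecorded = 11,
                              n_missing_weight = 4, n_missing_size = 3,
                              config = sim_config(), seed = NULL) {
  n_bad <- n_unrecorded + n_missing_weight + n_missing_size
  if (n_bad > n_total) stop("defect counts exceed n_total")
  .with_seed(seed, {
    tab <- generate_trait_table(n_total, config = config, seed = NULL)
    tab$recorded <- TRUE
    bad <- sample(n_total, n_bad)
    i_un <- bad[seq_len(n_unrecorded)]
    i_bw <- bad[n_unrecorded + seq_len(n_missing_weight)]
    i_sz <- bad[n_unrecorded + n_missing_weight + seq_len(n_missing_size)]
    if (n_unrecorded > 0) {
      tab$recorded[i_un] <- FALSE
      tab[i_un, c("BW", .trait_names)] <- NA_real_
    }
    if (n_missing_weight > 0) tab$BW[i_bw] <- NA_real_
    for (i in i_sz) {
      tab[i, sample(.trait_names, 1)] <- NA_real_
    }
    tab
  })
}
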