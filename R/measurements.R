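#' Side-view body measurements from landmarks
#'
#' Converts side-view landmark geometry to calibrated traits:
#' * `HW` (height at wither): ground to withers, vertical;
#' * `HH` (hip height): ground to hip top, vertical;
#' * `CD` (chest depth): withers to chest-bottom point, vertical;
#' * `BSL` (body slanting length): chest front to sciatic tuberosity,
#'   Euclidean;
#' * `shank_diameter`: foreleg width at the metacarpus.
#'
#' @param landmarks A side-view `landmark_set` from [detect_landmarks_side()].
#' @param model A side-view [scale_model()].
#' @param distance Calibration distance (cm) at which the animal was imaged.
#' @return One-row tibble with `HW`, `HH`, `CD`, `BSL`, `shank_diameter`
#'   (all cm).
#' @export
measure_side <- function(landmarks, model, distance = 0) {
  need <- c("withers", "hip_top", "chest_bottom", "chest_front",
            "sciatic_tuberosity")
  pt <- function(nm) {
    row <- landmarks[landmarks$landmark == nm, ]
    if (nrow(row) != 1 || is.na(row$x) || is.na(row$y)) {
      stop("missing landmark: ", nm)
    }
    row
  }
  for (nm in need) pt(nm)
  gy <- attr(landmarks, "ground_y")
  if (is.null(gy)) stop("missing landmark: ground line")
  shank_px <- attr(landmarks, "shank_width_px")
  if (is.null(shank_px)) stop("missing landmark: shank width")
  ratio <- scale_ratio(model, distance)
  if (ratio <= 0) stop("nonpositive scale ratio")
  wi <- pt("withers"); ht <- pt("hip_top"); cb <- pt("chest_bottom")
  cf <- pt("chest_front"); st <- pt("sciatic_tuberosity")
  tibble::tibble(
    HW = (gy - wi$y) / ratio,
    HH = (gy - ht$y) / ratio,
    CD = abs(cb$y - wi$y) / ratio,
    BSL = sqrt((cf$x - st$x)^2 + (cf$y - st$y)^2) / ratio,
    shank_diameter = shank_px / ratio
  )
}

#' Dorsal-view body measurements from landmarks
#'
#' Shoulder width (`SW`) and rump width (`RW`) are the absolute lateral
#' differences between the paired curvature points on the dorsal contour,
#' converted through the back-view scale model.
#'
#' @param landmarks A dorsal `landmark_set` from [detect_landmarks_dorsal()].
#' @param model A back-view [scale_model()].
#' @param distance Calibration distance (cm).
#' @return One-row tibble with `SW`, `RW` (cm).
#' @export
measure_dorsal <- function(landmarks, model, distance = 0) {
  sw_px <- attr(landmarks, "shoulder_width_px")
  rw_px <- attr(landmarks, "rump_width_px")
  if (is.null(sw_px)) stop("missing landmark: shoulder pair")
  if (is.null(rw_px)) stop("missing landmark: rump pair")
  ratio <- scale_ratio(model, distance)
  if (ratio <= 0) stop("nonpositive scale ratio")
  tibble::tibble(SW = sw_px / ratio, RW = rw_px / ratio)
}

#' Chest circumference from chest width and chest depth
#'
#' The ovine thorax cross-section is close to an ellipse whose axes are the
#' chest width (measured dorsally; shoulder width is its proxy) and the chest
#' depth (measured laterally). The circumference is the ellipse perimeter
#' with semi-axes `SW/2` and `CD/2`.
#'
#' @param SW Chest (shoulder) width in cm.
#' @param CD Chest depth in cm.
#' @return Chest circumference `CC` in cm.
#' @examples
#' chest_circumference(40, 20) # ~96.88
#' @export
chest_circumference <- function(SW, CD) {
  if (SW <= 0 || CD <= 0) stop("SW and CD must be positive")
  ellipse_perimeter(SW / 2, CD / 2)
}

#' Shank circumference from the measured leg diameter
#'
#' The metacarpus cross-section is close to a circle, so the girth is
#' `pi * d`.
#'
#' @param diameter Shank diameter in cm (nonnegative).
#' @return Shank circumference `SC` in cm.
#' @export
shank_circumference <- function(diameter) {
  if (diameter < 0) stop("diameter must be nonnegative")
  pi * diameter
}

#' Correction coefficient from paired manual/machine values
#'
#' Some traits (body length, chest circumference, shank circumference) carry
#' a systematic machine bias (wool, viewpoint); a validation set of paired
#' manual and machine values gives a multiplicative correction factor, the
#' mean of the per-animal manual/machine ratios, applied to subsequent
#' machine values of that trait.
#'
#' @param manual,machine Equal-length numeric vectors (cm); machine values
#'   must be positive.
#' @return The correction factor.
#' @examples
#' correction_coefficient(100, 90) # 1.1111
#' @export
correction_coefficient <- function(manual, machine) {
  if (length(manual) != length(machine)) stop("length mismatch")
  if (length(manual) == 0) stop("need at least one pair")
  if (any(machine <= 0)) stop("machine values must be positive")
  mean(manual / machine)
}

#' Percentage error between manual and machine values
#'
#' `Perr = |Da - Dm| / Da * 100`, with `Da` the manual and `Dm` the machine
#' measurement. Vectorised.
#' @param Da Manual values.
#' @param Dm Machine values.
#' @return Percentage error(s).
#' @export
percentage_error <- function(Da, Dm) {
  if (any(Da == 0)) stop("manual values must be nonzero")
  abs(Da - Dm) / Da * 100
}

#' Mean percentage error
#' @param perr Vector of percentage errors.
#' @return `A`, their arithmetic mean.
#' @export
mean_error <- function(perr) {
  if (length(perr) == 0) stop("empty error vector")
  mean(perr)
}

#' Manual-vs-machine error report over a batch
#'
#' @param manual,machine Data frames with matching trait columns (and equal
#'   row counts, one row per animal).
#' @param traits Trait columns to compare; default the intersection.
#' @return Tibble (`trait`, `A`, `n`) of mean percentage errors.
#' @export
error_report <- function(manual, machine,
                         traits = intersect(names(manual), names(machine))) {
  if (nrow(manual) != nrow(machine)) stop("row count mismatch")
  purrr::map_dfr(traits, function(tr) {
    pe <- percentage_error(manual[[tr]], machine[[tr]])
    tibble::tibble(trait = tr, A = mean_error(pe), n = length(pe))
  })
}

#' Full two-view measurement of one animal
#'
#' Runs the complete downstream pipeline on a segmented side and (optional)
#' dorsal mask: pose normalization, contour extraction, landmark detection,
#' pixel-to-cm conversion, and the derived circumferences. Chest
#' circumference combines the dorsal chest width with the lateral chest
#' depth, each converted through its own view's scale model before being
#' merged.
#'
#' @param side_mask Side-view `sheep_mask` (or path to a PNG).
#' @param dorsal_mask Dorsal-view mask or path; `NULL` for side-only traits
#'   (`SW`, `RW`, `CC` are then `NA`).
#' @param model_side,model_back [scale_model()]s for the two cameras.
#' @param distance_side,distance_back Calibration distances (cm).
#' @param cfg A [range_config()].
#' @param u Curvature chord step (default 1% of contour points).
#' @param corrections Optional named list of multiplicative correction
#'   factors (e.g. `list(BSL = 1.02, CC = 0.98, SC = 1.1)`), see
#'   [correction_coefficient()]. Default none (factor 1).
#' @return One-row tibble with the 8 traits (`HW`, `BSL`, `CD`, `HH`, `SW`,
#'   `RW`, `CC`, `SC`, cm).
#' @export
measure_sheep <- function(side_mask, dorsal_mask = NULL,
                          model_side = scale_model(1, view = "side"),
                          model_back = scale_model(1, view = "back"),
                          distance_side = 0, distance_back = 0,
                          cfg = range_config(), u = NULL,
                          corrections = list()) {
  if (is.character(side_mask)) side_mask <- read_mask(side_mask)
  side_mask <- normalize_pose(side_mask)$mask
  ct_s <- extract_contour(side_mask)
  lm_s <- detect_landmarks_side(ct_s, cfg, u = u)
  side <- measure_side(lm_s, model_side, distance_side)
  if (!is.null(dorsal_mask)) {
    if (is.character(dorsal_mask)) dorsal_mask <- read_mask(dorsal_mask)
    ct_d <- extract_contour(dorsal_mask)
    lm_d <- detect_landmarks_dorsal(ct_d, cfg, u = u)
    dors <- measure_dorsal(lm_d, model_back, distance_back)
  } else {
    dors <- tibble::tibble(SW = NA_real_, RW = NA_real_)
  }
  out <- tibble::tibble(
    HW = side$HW, BSL = side$BSL, CD = side$CD, HH = side$HH,
    SW = dors$SW, RW = dors$RW,
    CC = if (is.na(dors$SW)) NA_real_ else chest_circumference(dors$SW, side$CD),
    SC = shank_circumference(side$shank_diameter)
  )
  for (tr in names(corrections)) {
    if (tr %in% names(out)) out[[tr]] <- out[[tr]] * corrections[[tr]]
  }
  out
}
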