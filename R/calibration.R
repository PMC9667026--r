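#' Mean pixel-per-centimetre ratio from calibration-plate gaps
#'
#' The calibration target is a plate of squares of known physical size
#' (7 x 7 cm in the reference rig). Given the pixel distances between
#' adjacent block corners in one photograph, the scale at that camera
#' distance is the mean gap divided by the block size.
#'
#' @param pixel_gaps Numeric vector of pixel distances between adjacent
#'   calibration blocks.
#' @param plate_cm Physical block size in cm (default 7).
#' @return Scale in px per cm.
#' @examples
#' mean_ratio(c(13, 14, 15), plate_cm = 7) # 2
#' @export
mean_ratio <- function(pixel_gaps, plate_cm = 7) {
  if (length(pixel_gaps) == 0) stop("need at least one pixel gap")
  if (plate_cm <= 0) stop("plate size must be positive")
  mean(pixel_gaps) / plate_cm
}

# fitted plate-distance domains (cm) per view; the rig moved the back plate
# over 0-105 cm and the side plate over 0-50 cm
.scale_domains <- list(back = c(0, 105), side = c(0, 50))

#' Fit a quadratic pixel-to-centimetre scale model
#'
#' The px-per-cm ratio varies with the distance between calibration plate and
#' camera ("closer is large, farther is small" — and the relation is curved).
#' This fits `ratio = c2*d^2 + c1*d + c0` by ordinary least squares and
#' reports the coefficient of determination. The back and side cameras have
#' different optics and are modelled independently; models are never shared
#' across views.
#'
#' @param samples Data frame with columns `distance` (cm) and `ratio`
#'   (px per cm), e.g. from [generate_calibration_samples()] or
#'   [read_calibration_csv()].
#' @param view `"back"` or `"side"`.
#' @return Object of class `scale_model`: list with `view`, coefficients
#'   `c2`, `c1`, `c0`, `r_squared`, the fitting `domain`, and `n`.
#' @export
fit_scale_model <- function(samples, view = c("back", "side")) {
  view <- match.arg(view)
  d <- samples$distance
  r <- samples$ratio
  if (length(unique(d)) < 3) stop("need at least 3 distinct distances")
  if (any(r <= 0)) stop("ratios must be positive")
  fit <- stats::lm(r ~ d + I(d^2))
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((r - mean(r))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(view = view,
         c2 = unname(co[["I(d^2)"]]), c1 = unname(co[["d"]]),
         c0 = unname(co[["(Intercept)"]]),
         r_squared = r2, domain = .scale_domains[[view]],
         n = length(d)),
    class = "scale_model"
  )
}

#' Construct a scale model from known coefficients
#'
#' Useful for fixed-scale setups (constant px-per-cm) and for evaluating
#' published calibration equations.
#'
#' @param c2,c1,c0 Quadratic coefficients of `ratio(d) = c2 d^2 + c1 d + c0`.
#' @param view `"back"` or `"side"`.
#' @return A `scale_model`.
#' @export
scale_model <- function(c0, c1 = 0, c2 = 0, view = c("back", "side")) {
  view <- match.arg(view)
  structure(list(view = view, c2 = c2, c1 = c1, c0 = c0,
                 r_squared = NA_real_, domain = .scale_domains[[view]],
                 n = NA_integer_),
            class = "scale_model")
}

#' Evaluate the px-per-cm ratio of a scale model at a distance
#' @param model A `scale_model`.
#' @param distance Plate-to-reference distance (cm).
#' @param warn Warn when the distance is outside the fitted domain.
#' @return Ratio in px per cm.
#' @export
scale_ratio <- function(model, distance, warn = TRUE) {
  if (warn && !is.null(model$domain) &&
      any(distance < model$domain[1] | distance > model$domain[2])) {
    warning("distance outside fitted ", model$view, " domain [",
            model$domain[1], ", ", model$domain[2], "] cm")
  }
  model$c2 * distance^2 + model$c1 * distance + model$c0
}

#' Convert a pixel length to centimetres
#' @param length_px Length(s) in pixels.
#' @inheritParams scale_ratio
#' @return Length(s) in cm: `length_px / ratio(distance)`.
#' @export
pixels_to_cm <- function(length_px, distance, model, warn = TRUE) {
  r <- scale_ratio(model, distance, warn = warn)
  if (any(r <= 0)) stop("scale model gives nonpositive ratio at this distance")
  length_px / r
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("<scale_model %s> ratio(d) = %.6g d^2 + %.6g d + %.6g",
              x$view, x$c2, x$c1, x$c0))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.6f, n = %d)", x$r_squared, x$n))
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.scale_model <- function(x, ...) {
  tibble::tibble(term = c("d^2", "d", "(Intercept)"),
                 estimate = c(x$c2, x$c1, x$c0))
}

#' @importFrom generics glance
#' @export
glance.scale_model <- function(x, ...) {
  tibble::tibble(view = x$view, r.squared = x$r_squared, nobs = x$n,
                 domain_lo = x$domain[1], domain_hi = x$domain[2])
}

#' @export
predict.scale_model <- function(object, distance, ...) {
  scale_ratio(object, distance)
}

#' Plot a fitted scale model over its calibration samples
#' @param object A `scale_model`.
#' @param samples Optional data frame (`distance`, `ratio`) to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scale_model <- function(object, samples = NULL, ...) {
  dd <- seq(object$domain[1], object$domain[2], length.out = 200)
  curve_df <- tibble::tibble(distance = dd,
                             ratio = scale_ratio(object, dd, warn = FALSE))
  p <- ggplot2::ggplot(curve_df,
                       ggplot2::aes(x = .data$distance, y = .data$ratio)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "plate distance (cm)", y = "scale (px per cm)",
                  title = paste0(object$view, " view scale model"))
  if (!is.null(samples)) {
    p <- p + ggplot2::geom_point(data = samples, size = 1.5)
  }
  p
}

#' Read / write calibration samples as CSV
#'
#' Columns: `view`, `distance` (cm), `ratio` (px per cm).
#' @param path CSV path.
#' @export
read_calibration_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_calibration_csv
#' @param samples Data frame with `view`, `distance`, `ratio`.
#' @export
write_calibration_csv <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' Serialize / deserialize a scale model as JSON
#' @param model A `scale_model`.
#' @param path JSON path.
#' @export
write_scale_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale_model_json
#' @export
read_scale_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(view = obj$view, c2 = obj$c2, c1 = obj$c1, c0 = obj$c0,
                 r_squared = obj$r_squared %||% NA_real_,
                 domain = obj$domain %||% .scale_domains[[obj$view]],
                 n = obj$n %||% NA_integer_),
            class = "scale_model")
}
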