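#' Binary silhouette masks
#'
#' A mask is an integer matrix with `mask[row, col]` in `{0, 1}`, row 1 at the
#' top of the image. Pixel coordinates used throughout the package are
#' zero-based with `x` rightward (column) and `y` downward (row), so pixel
#' `(x, y)` is `mask[y + 1, x + 1]`. This matches the head-vertex rule of the
#' measurement algorithm, where "smallest y" means topmost.
#'
#' @param m Numeric or logical matrix. Grayscale values are thresholded.
#' @param threshold Binarization threshold for grayscale input on a 0--255
#'   scale (default 127). Matrices already in `{0,1}` pass through; values in
#'   `[0, 1]` are compared against `threshold/255`.
#' @return Integer 0/1 matrix of class `sheep_mask`.
#' @export
as_mask <- function(m, threshold = 127) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  if (is.logical(m)) {
    b <- m
  } else if (all(m %in% c(0, 1))) {
    b <- m == 1
  } else if (max(m) <= 1) {
    b <- m > threshold / 255
  } else {
    b <- m > threshold
  }
  out <- matrix(as.integer(b), nrow = nrow(m))
  class(out) <- c("sheep_mask", class(out))
  out
}

#' Read / write a silhouette mask as 8-bit PNG
#'
#' Foreground is written as 255, background as 0.
#'
#' @param path PNG file path.
#' @param threshold Binarization threshold, see [as_mask()].
#' @return `read_mask()` returns a `sheep_mask`; `write_mask()` returns `path`
#'   invisibly.
#' @export
read_mask <- function(path, threshold = 127) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  as_mask(img, threshold = threshold)
}

#' @rdname read_mask
#' @param mask A `sheep_mask` (or 0/1 matrix).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), path)
  invisible(path)
}

# clockwise Moore neighbourhood in image coordinates (x right, y down)
.moore_dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.moore_dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Trace the outer boundary of the largest foreground component
#'
#' Moore-neighbour boundary tracing with 8-connectivity on the largest
#' connected foreground component (smaller blobs and interior holes are
#' ignored). The trace starts at the topmost-then-leftmost boundary pixel and
#' runs clockwise in image coordinates, with Jacob's stopping criterion, so
#' the result is fully deterministic.
#'
#' @param mask A `sheep_mask` or 0/1 matrix (see [as_mask()]).
#' @return A tibble of class `sheep_contour` with columns `index` (1-based
#'   position along the trace), `x`, `y` (zero-based pixel coordinates);
#'   attributes `width` and `height` carry the mask size.
#' @export
extract_contour <- function(mask) {
  m <- unclass(as_mask(mask))
  if (sum(m) == 0) stop("no foreground: mask is empty")
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) {
    counts <- tabulate(lab[lab > 0])
    keep <- which.max(counts)
    m <- matrix(as.integer(lab == keep), nrow = nrow(m))
  }
  h <- nrow(m); w <- ncol(m)

  fg <- which(m == 1L)
  # column-major order scans down columns; find topmost row, then leftmost col
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  top <- min(rows)
  sc <- min(cols[rows == top])
  sr <- top

  if (sum(m) == 1L) {
    ct <- tibble::tibble(index = 1L, x = sc - 1L, y = sr - 1L)
    return(.as_contour(ct, w, h))
  }

  # pad with a background border so neighbour probes need no bounds checks
  mp <- matrix(0L, h + 2L, w + 2L)
  mp[2:(h + 1L), 2:(w + 1L)] <- m
  # direction index from (dy, dx) offset, via a 3x3 lookup
  dir_lut <- matrix(NA_integer_, 3, 3)
  for (k in 1:8) dir_lut[.moore_dy[k] + 2L, .moore_dx[k] + 2L] <- k

  # backtrack starts west of the start pixel (background by construction of
  # the scan order)
  cap <- 8L * (h + w) + 64L
  xs <- integer(cap); ys <- integer(cap)
  np <- 0L
  cr <- sr + 1L; ccol <- sc + 1L # padded coordinates
  bdir <- 5L # direction from current pixel toward backtrack pixel: west
  start_state <- NULL
  max_steps <- 4L * (h * w)
  steps <- 0L
  repeat {
    np <- np + 1L
    if (np > length(xs)) { xs <- c(xs, integer(cap)); ys <- c(ys, integer(cap)) }
    xs[np] <- ccol; ys[np] <- cr
    # scan clockwise starting just after the backtrack direction
    found <- FALSE
    k0 <- bdir %% 8L # 0-based index of the direction after backtrack
    for (j in 0:7) {
      k <- ((k0 + j) %% 8L) + 1L
      nr <- cr + .moore_dy[k]; ncl <- ccol + .moore_dx[k]
      if (mp[nr, ncl] == 1L) {
        # new backtrack: the previously checked (background) neighbour of the
        # old pixel, re-expressed as a direction from the new pixel
        prev_k <- if (j == 0) bdir else ((k0 + j - 1L) %% 8L) + 1L
        pr <- cr + .moore_dy[prev_k]; pc <- ccol + .moore_dx[prev_k]
        cr <- nr; ccol <- ncl
        bdir <- dir_lut[(pr - cr) + 2L, (pc - ccol) + 2L]
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    steps <- steps + 1L
    if (is.null(start_state)) {
      start_state <- c(cr, ccol, bdir)
    } else if ((cr == start_state[1] && ccol == start_state[2] &&
                bdir == start_state[3]) || steps > max_steps) {
      break
    }
  }
  xs <- xs[seq_len(np)] - 1L; ys <- ys[seq_len(np)] - 1L
  # the trace may record the start pixel twice when closing; deduplicate tail
  n <- length(xs)
  if (n > 1 && xs[n] == xs[1] && ys[n] == ys[1]) {
    xs <- xs[-n]; ys <- ys[-n]
  }
  ct <- tibble::tibble(index = seq_along(xs), x = xs - 1L, y = ys - 1L)
  .as_contour(ct, w, h)
}

.as_contour <- function(ct, width, height) {
  attr(ct, "width") <- width
  attr(ct, "height") <- height
  class(ct) <- c("sheep_contour", class(ct))
  ct
}

#' Polygon area of a contour (shoelace formula)
#' @param contour Contour tibble.
#' @return Area in px^2.
#' @export
contour_area <- function(contour) {
  x <- contour$x; y <- contour$y
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Total arc length of a closed contour (px)
#' @param contour Contour tibble.
#' @export
contour_length <- function(contour) {
  x <- contour$x; y <- contour$y
  dx <- c(x[-1], x[1]) - x
  dy <- c(y[-1], y[1]) - y
  sum(sqrt(dx^2 + dy^2))
}

#' Write / read a contour as CSV (`index,x,y`)
#' @param contour Contour tibble.
#' @param path File path.
#' @export
write_contour_csv <- function(contour, path) {
  readr::write_csv(contour[, c("index", "x", "y")], path)
  invisible(path)
}

#' @rdname write_contour_csv
#' @param width,height Optional mask dimensions to restore as attributes.
#' @export
read_contour_csv <- function(path, width = NA_integer_, height = NA_integer_) {
  ct <- readr::read_csv(path, show_col_types = FALSE)
  .as_contour(ct, width, height)
}

#' Export a contour as a GeoJSON-style polygon
#' @param contour Contour tibble.
#' @param path JSON file path.
#' @export
write_contour_json <- function(contour, path) {
  poly <- list(
    type = "Polygon",
    coordinates = list(
      lapply(seq_len(nrow(contour)), function(i) c(contour$x[i], contour$y[i]))
    )
  )
  jsonlite::write_json(poly, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
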