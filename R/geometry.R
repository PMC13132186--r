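# Box arithmetic shared by every other module.
#
# A box is a length-4 numeric vector c(x, y, w, h): top-left corner,
# width and height in pixels, top-left image origin, x rightward and
# y downward, 0-based continuous coordinates. Sets of boxes are n x 4
# matrices with the same column order.

#' Construct a box
#'
#' Boxes are plain numeric vectors `c(x, y, w, h)` in pixel units with a
#' top-left origin: `x` grows rightward, `y` downward. Width and height must
#' be non-negative; zero-area (degenerate) boxes are permitted.
#'
#' @param x,y top-left corner (px).
#' @param w,h width and height (px), both `>= 0`.
#' @return Named numeric vector `c(x, y, w, h)`.
#' @export
#' @examples
#' box(0, 0, 10, 20)
box <- function(x, y, w, h) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h))
  if (w < 0 || h < 0) stop("box width and height must be non-negative")
  c(x = as.numeric(x), y = as.numeric(y), w = as.numeric(w), h = as.numeric(h))
}

as_box_matrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  stopifnot(ncol(b) == 4)
  b
}

#' Intersection over union of two boxes
#'
#' Continuous (non-rasterized) geometry: areas are `w * h`, the intersection
#' is the overlap rectangle. Raises an error when both boxes are degenerate
#' (zero area), where the ratio is undefined.
#'
#' @param a,b boxes as returned by [box()].
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(box(0, 0, 2, 2), box(1, 1, 2, 2)) # 1/7
iou <- function(a, b) {
  area_a <- a[3] * a[4]
  area_b <- b[3] * b[4]
  if (area_a <= 0 && area_b <= 0) {
    stop("IoU undefined: both boxes have zero area")
  }
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  unname(inter / (area_a + area_b - inter))
}

#' Pairwise IoU matrix between two box sets
#'
#' @param A,B n x 4 and m x 4 matrices with columns x, y, w, h.
#' @return n x m matrix of IoU values (0 for pairs where the union has zero
#'   area).
#' @export
iou_matrix <- function(A, B) {
  A <- as_box_matrix(A)
  B <- as_box_matrix(B)
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(out)
  ax2 <- A[, 1] + A[, 3]; ay2 <- A[, 2] + A[, 4]
  bx2 <- B[, 1] + B[, 3]; by2 <- B[, 2] + B[, 4]
  area_a <- A[, 3] * A[, 4]; area_b <- B[, 3] * B[, 4]
  for (j in seq_len(m)) {
    ix <- pmax(0, pmin(ax2, bx2[j]) - pmax(A[, 1], B[j, 1]))
    iy <- pmax(0, pmin(ay2, by2[j]) - pmax(A[, 2], B[j, 2]))
    inter <- ix * iy
    uni <- area_a + area_b[j] - inter
    out[, j] <- ifelse(uni > 0, inter / uni, 0)
  }
  out
}

#' Scale a box about its center
#'
#' Multiplies width and height by `factor` while keeping the center fixed.
#' Used for the buffered-box variant of the keypoint-based detection
#' comparison, where keypoints near the box border still count.
#'
#' @param b a box.
#' @param factor positive scale factor.
#' @return The buffered box (coordinates may become negative).
#' @export
#' @examples
#' buffer_box(box(10, 10, 20, 20), 1.5) # c(5, 5, 30, 30)
buffer_box <- function(b, factor) {
  if (factor <= 0) stop("buffer factor must be positive")
  nw <- b[3] * factor
  nh <- b[4] * factor
  box(b[1] + (b[3] - nw) / 2, b[2] + (b[4] - nh) / 2, nw, nh)
}

#' Expand a box to a square
#'
#' Grows the shorter side symmetrically about the box center until it matches
#' the longer side. Rectangular annotation boxes are squared this way before
#' cropping, so classifier inputs are never anisotropically squeezed.
#'
#' @param b a box.
#' @return A square box with side `max(w, h)` that contains `b`.
#' @export
#' @examples
#' square_box(box(0, 0, 10, 20)) # c(-5, 0, 20, 20)
square_box <- function(b) {
  side <- max(b[3], b[4])
  box(b[1] + (b[3] - side) / 2, b[2] + (b[4] - side) / 2, side, side)
}

#' Closed-box point containment
#'
#' The boundary counts as inside: a keypoint lying exactly on a box edge is
#' contained.
#'
#' @param p point `c(x, y)`.
#' @param b a box.
#' @return `TRUE` iff `x <= px <= x + w` and `y <= py <= y + h`.
#' @export
point_in_box <- function(p, b) {
  p[1] >= b[1] && p[1] <= b[1] + b[3] && p[2] >= b[2] && p[2] <= b[2] + b[4]
}

# (cx, cy) center of a box
box_center <- function(b) c(b[1] + b[3] / 2, b[2] + b[4] / 2)

# box from center/size
box_from_center <- function(cx, cy, w, h) box(cx - w / 2, cy - h / 2, w, h)
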