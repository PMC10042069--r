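#' Motion-blur line kernel
#'
#' Builds the normalized convolution kernel of a linear motion blur: an
#' anti-aliased straight line of length `length` pixels through the center
#' of a `length x length` grid, at `angle` degrees measured counterclockwise
#' from the x-axis. Cell weights fall off linearly with perpendicular
#' distance from the line (tent profile, 1 px support) and are normalized to
#' sum to 1, so blurring never changes the mean intensity. For axis-aligned
#' angles this reduces to a uniform 1/L line.
#'
#' @param length odd kernel side / line length L in pixels, `>= 1`.
#' @param angle blur direction in degrees.
#' @return `length x length` numeric matrix of nonnegative weights summing
#'   to 1.
#' @export
motion_blur_kernel <- function(length = 9L, angle = 0) {
  length <- check_count(length, "length", min = 1L)
  if (length %% 2L == 0L) {
    stop("kernel `length` must be odd so the line is centered",
         call. = FALSE)
  }
  half <- (length - 1L) / 2
  offs <- seq(-half, half)
  theta <- angle * pi / 180
  ux <- cos(theta)
  uy <- sin(theta)
  gx <- matrix(offs, length, length, byrow = TRUE)  # column offset (x)
  gy <- matrix(offs, length, length)                # row offset (y)
  along <- gx * ux + gy * uy
  perp <- -gx * uy + gy * ux
  wts <- pmax(0, 1 - abs(perp)) * (abs(along) <= length / 2)
  wts / sum(wts)
}

#' Apply motion blur to an image
#'
#' Convolves the pixel grid with [motion_blur_kernel()] to emulate the image
#' degradation caused by catheter/vessel motion during OCT acquisition.
#' Borders are handled by edge replication, which avoids the darkened rim a
#' zero pad would produce in OCT-like imagery. Output has the same shape as
#' the input; a constant image is unchanged for any kernel.
#'
#' @param image an [image_record()] with pixels, or a plain numeric matrix.
#' @param length,angle kernel parameters, see [motion_blur_kernel()].
#' @return Blurred image of the same type and shape as `image`.
#' @export
motion_blur <- function(image, length = 9L, angle = 0) {
  px <- image_pixels(image)
  k <- motion_blur_kernel(length, angle)
  half <- (nrow(k) - 1L) / 2
  out <- convolve2d_replicate(px, k, half)
  set_image_pixels(image, out)
}

convolve2d_replicate <- function(px, k, half) {
  h <- nrow(px)
  w <- ncol(px)
  if (half == 0L) return(px * k[1L, 1L])
  # replicate-pad, then accumulate the k[i, j]-weighted shifts
  ri <- c(rep(1L, half), seq_len(h), rep(h, half))
  ci <- c(rep(1L, half), seq_len(w), rep(w, half))
  padded <- px[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      wt <- k[i, j]
      if (wt == 0) next
      out <- out + wt * padded[(i - 1L) + seq_len(h),
                               (j - 1L) + seq_len(w), drop = FALSE]
    }
  }
  out
}

#' Horizontal flip with bounding-box remapping
#'
#' Mirrors the image left-right and maps each box accordingly:
#' `(x_min, y_min, x_max, y_max) -> (W - x_max, y_min, W - x_min, y_max)`
#' with `W` the image width in pixels. Box order, areas and y-extents are
#' preserved, and flipping twice is the identity. This is the only
#' reflection appropriate for OCT frames — vertical flips and rotations
#' would reverse the fixed light-propagation direction and are deliberately
#' not provided.
#'
#' @param image an [image_record()] (pixels optional, width required) or a
#'   plain numeric matrix.
#' @param boxes optional boxes lying within the image (data frame from
#'   [bbox()], [ground_truth_frame()] or [detections_frame()]).
#' @return With `boxes = NULL`, the flipped image; otherwise a list
#'   `list(image = , boxes = )` with the box columns rewritten in place.
#' @export
horizontal_flip <- function(image, boxes = NULL) {
  if (is.matrix(image)) {
    w <- ncol(image)
    flipped <- image[, rev(seq_len(w)), drop = FALSE]
  } else {
    stopifnot(inherits(image, "image_record"))
    w <- image$width
    flipped <- image
    if (!is.null(image$pixels)) {
      flipped$pixels <- image$pixels[, rev(seq_len(w)), drop = FALSE]
    }
  }
  if (is.null(boxes)) return(flipped)
  m <- validate_boxes(boxes)
  if (nrow(m) > 0L && (any(m[, "x_min"] < 0) || any(m[, "x_max"] > w))) {
    stop("boxes must lie within the image to be flipped", call. = FALSE)
  }
  new_x_min <- w - m[, "x_max"]
  new_x_max <- w - m[, "x_min"]
  boxes$x_min <- new_x_min
  boxes$x_max <- new_x_max
  list(image = flipped, boxes = boxes)
}

image_pixels <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(inherits(image, "image_record"))
  if (is.null(image$pixels)) {
    stop("image record carries no pixel grid", call. = FALSE)
  }
  image$pixels
}

set_image_pixels <- function(image, px) {
  if (is.matrix(image)) return(px)
  image$pixels <- px
  image
}
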