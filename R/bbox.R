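#' Axis-aligned bounding boxes
#'
#' Boxes are kept in one internal convention throughout the package:
#' continuous pixel coordinates, origin at the top-left corner, x increasing
#' rightward and y downward, stored corner-form as the four columns
#' `x_min, y_min, x_max, y_max`. The normalized center form used by YOLO
#' annotation files exists only at the file boundary
#' (see [read_yolo_annotations()]).
#'
#' @param x_min,y_min,x_max,y_max numeric vectors (recycled to a common
#'   length) of box corners in pixels. Each box must have positive width and
#'   height and all-finite coordinates.
#'
#' @return A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   one row per box.
#' @examples
#' b <- bbox(0, 0, 10, 20)
#' iou(b, bbox(5, 0, 15, 20))
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_boxes(b)
  b
}

# Accepts a bbox data frame (possibly with extra columns) or a length-4
# numeric vector; returns an n x 4 double matrix in corner order.
as_box_matrix <- function(b) {
  if (is.numeric(b) && is.null(dim(b)) && length(b) == 4L) {
    m <- matrix(as.numeric(b), nrow = 1L)
  } else if (is.matrix(b) && ncol(b) == 4L) {
    m <- b
    storage.mode(m) <- "double"
  } else if (is.data.frame(b)) {
    need <- c("x_min", "y_min", "x_max", "y_max")
    if (!all(need %in% names(b))) {
      stop("box input must have columns x_min, y_min, x_max, y_max",
           call. = FALSE)
    }
    m <- as.matrix(b[, need, drop = FALSE])
    storage.mode(m) <- "double"
  } else {
    stop("cannot interpret input as bounding boxes", call. = FALSE)
  }
  colnames(m) <- c("x_min", "y_min", "x_max", "y_max")
  m
}

validate_boxes <- function(b, where = "box") {
  m <- as_box_matrix(b)
  if (nrow(m) == 0L) return(invisible(m))
  if (!all(is.finite(m))) {
    stop(sprintf("%s coordinates must all be finite", where), call. = FALSE)
  }
  bad <- m[, "x_max"] <= m[, "x_min"] | m[, "y_max"] <= m[, "y_min"]
  if (any(bad)) {
    stop(sprintf("%s %d has nonpositive width or height", where,
                 which(bad)[1L]), call. = FALSE)
  }
  invisible(m)
}

#' Intersection over union of bounding boxes
#'
#' The overlap criterion used to decide whether a detection matches a
#' ground-truth annotation: intersection area divided by union area, 0 for
#' disjoint boxes and 1 only for identical boxes.
#'
#' @param a,b boxes as produced by [bbox()] (data frames are recycled
#'   row-wise to a common length; a single box may be given as a length-4
#'   numeric vector `c(x_min, y_min, x_max, y_max)`).
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
iou <- function(a, b) {
  ma <- validate_boxes(a)
  mb <- validate_boxes(b)
  n <- max(nrow(ma), nrow(mb))
  if (n == 0L) return(numeric(0))
  idx_a <- rep_len(seq_len(nrow(ma)), n)
  idx_b <- rep_len(seq_len(nrow(mb)), n)
  ma <- ma[idx_a, , drop = FALSE]
  mb <- mb[idx_b, , drop = FALSE]
  iw <- pmax(0, pmin(ma[, 3L], mb[, 3L]) - pmax(ma[, 1L], mb[, 1L]))
  ih <- pmax(0, pmin(ma[, 4L], mb[, 4L]) - pmax(ma[, 2L], mb[, 2L]))
  inter <- iw * ih
  area_a <- (ma[, 3L] - ma[, 1L]) * (ma[, 4L] - ma[, 2L])
  area_b <- (mb[, 3L] - mb[, 1L]) * (mb[, 4L] - mb[, 2L])
  unname(inter / (area_a + area_b - inter))
}

# Cross IoU: n x m matrix between every box of `a` and every box of `b`.
iou_matrix <- function(a, b) {
  ma <- validate_boxes(a)
  mb <- validate_boxes(b)
  n <- nrow(ma)
  m <- nrow(mb)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(out)
  for (j in seq_len(m)) {
    out[, j] <- iou(ma, mb[j, ])
  }
  out
}

box_centers <- function(b) {
  m <- as_box_matrix(b)
  cbind(cx = (m[, "x_min"] + m[, "x_max"]) / 2,
        cy = (m[, "y_min"] + m[, "y_max"]) / 2)
}
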