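#' Image metadata record
#'
#' Carries the image identifier, pixel dimensions and (optionally) the
#' grayscale pixel grid itself. The dimensions are needed wherever
#' normalized coordinates meet pixel coordinates (YOLO annotation files,
#' box-center features); the pixel grid only by the augmentation operators.
#'
#' @param image_id non-empty string identifying the image.
#' @param width,height image size in pixels (positive integers).
#' @param pixels optional numeric matrix of grayscale intensities with
#'   `dim = c(height, width)` (rows are image rows).
#' @return An object of class `image_record`.
#' @export
image_record <- function(image_id, width, height, pixels = NULL) {
  if (!is.character(image_id) || length(image_id) != 1L || !nzchar(image_id)) {
    stop("`image_id` must be a non-empty string", call. = FALSE)
  }
  width <- check_count(width, "width", min = 1L)
  height <- check_count(height, "height", min = 1L)
  if (!is.null(pixels)) {
    if (!is.matrix(pixels) || !is.numeric(pixels)) {
      stop("`pixels` must be a numeric matrix", call. = FALSE)
    }
    if (nrow(pixels) != height || ncol(pixels) != width) {
      stop(sprintf("pixel grid is %d x %d but height x width is %d x %d",
                   nrow(pixels), ncol(pixels), height, width), call. = FALSE)
    }
  }
  structure(list(image_id = image_id, width = width, height = height,
                 pixels = pixels),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %s  %d x %d px  pixels: %s\n", x$image_id,
              x$width, x$height, if (is.null(x$pixels)) "absent" else "present"))
  invisible(x)
}

#' Ground-truth annotation table
#'
#' @param image_id character vector of image identifiers (non-empty).
#' @param class_id integer vector of class labels (`>= 0`).
#' @param boxes boxes as produced by [bbox()].
#' @return Data frame with columns `image_id`, `class_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @export
ground_truth_frame <- function(image_id, class_id, boxes) {
  m <- validate_boxes(boxes, where = "ground-truth box")
  n <- nrow(m)
  image_id <- rep_len(as.character(image_id), n)
  class_id <- rep_len(class_id, n)
  check_ids(image_id, class_id)
  data.frame(image_id = image_id, class_id = as.integer(class_id),
             x_min = m[, 1L], y_min = m[, 2L], x_max = m[, 3L],
             y_max = m[, 4L])
}

#' Detection table
#'
#' One row per predicted box: image, class, corner-form box, detector
#' confidence in `[0, 1]` and, once [apply_calibration()] has run, the
#' recalibrated confidence.
#'
#' @inheritParams ground_truth_frame
#' @param confidence numeric vector in `[0, 1]`.
#' @param calibrated_confidence optional numeric vector in `[0, 1]` (or `NA`).
#' @return Data frame with columns `image_id`, `class_id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence`, `calibrated_confidence`.
#' @export
detections_frame <- function(image_id, class_id, boxes, confidence,
                             calibrated_confidence = NA_real_) {
  m <- validate_boxes(boxes, where = "detection box")
  n <- nrow(m)
  image_id <- rep_len(as.character(image_id), n)
  class_id <- rep_len(class_id, n)
  confidence <- rep_len(as.numeric(confidence), n)
  calibrated_confidence <- rep_len(as.numeric(calibrated_confidence), n)
  check_ids(image_id, class_id)
  check_unit_interval(confidence, "confidence")
  ok <- is.na(calibrated_confidence) |
    (calibrated_confidence >= 0 & calibrated_confidence <= 1)
  if (!all(ok)) {
    stop("`calibrated_confidence` values must be in [0, 1] or NA",
         call. = FALSE)
  }
  data.frame(image_id = image_id, class_id = as.integer(class_id),
             x_min = m[, 1L], y_min = m[, 2L], x_max = m[, 3L],
             y_max = m[, 4L], confidence = confidence,
             calibrated_confidence = calibrated_confidence)
}

#' Calibration-record table
#'
#' The row type consumed by the uncertainty and calibration stages: the
#' detector's stated confidence, the predicted box center normalized by the
#' image size, and the binary correctness flag `z` (1 if the detection
#' matched a same-class ground-truth box under the IoU criterion).
#'
#' @param image_id character vector of image identifiers.
#' @param class_id integer vector of class labels (`>= 0`).
#' @param confidence numeric in `[0, 1]`.
#' @param cx_norm,cy_norm box-center coordinates divided by image width and
#'   height, in `[0, 1]`.
#' @param z binary correctness (0/1).
#' @param calibrated_confidence optional numeric in `[0, 1]` (or `NA`).
#' @return Data frame with those columns, one row per prediction.
#' @export
calibration_records <- function(image_id, class_id, confidence, cx_norm,
                                cy_norm, z, calibrated_confidence = NA_real_) {
  n <- max(length(image_id), length(class_id), length(confidence),
           length(cx_norm), length(cy_norm), length(z))
  image_id <- rep_len(as.character(image_id), n)
  class_id <- rep_len(class_id, n)
  confidence <- rep_len(as.numeric(confidence), n)
  cx_norm <- rep_len(as.numeric(cx_norm), n)
  cy_norm <- rep_len(as.numeric(cy_norm), n)
  z <- rep_len(z, n)
  calibrated_confidence <- rep_len(as.numeric(calibrated_confidence), n)
  check_ids(image_id, class_id)
  check_unit_interval(confidence, "confidence")
  check_unit_interval(cx_norm, "cx_norm")
  check_unit_interval(cy_norm, "cy_norm")
  if (!all(z %in% c(0, 1))) {
    stop("`z` must contain only 0 and 1", call. = FALSE)
  }
  data.frame(image_id = image_id, class_id = as.integer(class_id),
             confidence = confidence, cx_norm = cx_norm, cy_norm = cy_norm,
             z = as.integer(z),
             calibrated_confidence = calibrated_confidence)
}

check_ids <- function(image_id, class_id) {
  if (any(!nzchar(image_id)) || anyNA(image_id)) {
    stop("`image_id` values must be non-empty strings", call. = FALSE)
  }
  if (anyNA(class_id) || any(class_id != round(class_id)) ||
      any(class_id < 0)) {
    stop("`class_id` values must be integers >= 0", call. = FALSE)
  }
  invisible(NULL)
}

check_unit_interval <- function(x, name) {
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` values must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' Read YOLO-format annotations for one image
#'
#' Parses the one-file-per-image YOLO dialect: each non-empty line is
#' `class cx cy w h` with the center and size normalized to `(0, 1]`.
#' Coordinates are converted to corner-form pixel boxes against the image
#' dimensions. Boxes whose extent crosses an image border (legitimate for
#' centers near 0 or 1 with finite width) are clipped to the image, with a
#' warning. The `image_id` is taken from the `image` record, which by
#' convention is the annotation filename stem.
#'
#' @param path path to a YOLO-txt annotation file.
#' @param image an [image_record()] supplying `image_id`, `width`, `height`.
#' @return A ground-truth data frame (see [ground_truth_frame()]); zero rows
#'   for an empty file.
#' @export
read_yolo_annotations <- function(path, image) {
  stopifnot(inherits(image, "image_record"))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(ground_truth_frame(character(0), integer(0),
                              bbox(numeric(0), numeric(0), numeric(0),
                                   numeric(0))))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nt <- lengths(toks)
  if (any(nt != 5L)) {
    i <- which(nt != 5L)[1L]
    stop(sprintf("%s line %d: expected 5 fields (class cx cy w h), got %d",
                 path, line_no[i], nt[i]), call. = FALSE)
  }
  vals <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 5L,
                 byrow = TRUE)
  if (anyNA(vals)) {
    i <- which(apply(vals, 1L, anyNA))[1L]
    stop(sprintf("%s line %d: non-numeric field", path, line_no[i]),
         call. = FALSE)
  }
  cls <- vals[, 1L]
  if (any(cls != round(cls)) || any(cls < 0)) {
    i <- which(cls != round(cls) | cls < 0)[1L]
    stop(sprintf("%s line %d: class must be an integer >= 0", path,
                 line_no[i]), call. = FALSE)
  }
  norm <- vals[, 2:5, drop = FALSE]
  bad <- norm <= 0 | norm > 1
  if (any(bad)) {
    i <- which(apply(bad, 1L, any))[1L]
    stop(sprintf(
      "%s line %d: normalized cx, cy, w, h must lie in (0, 1]", path,
      line_no[i]), call. = FALSE)
  }
  x_min <- (norm[, 1L] - norm[, 3L] / 2) * image$width
  x_max <- (norm[, 1L] + norm[, 3L] / 2) * image$width
  y_min <- (norm[, 2L] - norm[, 4L] / 2) * image$height
  y_max <- (norm[, 2L] + norm[, 4L] / 2) * image$height
  clipped <- x_min < 0 | y_min < 0 | x_max > image$width |
    y_max > image$height
  if (any(clipped)) {
    warning(sprintf("%s: %d box(es) extended past the image border; clipped",
                    path, sum(clipped)), call. = FALSE)
  }
  ground_truth_frame(
    image$image_id, as.integer(cls),
    bbox(pmax(x_min, 0), pmax(y_min, 0),
         pmin(x_max, image$width), pmin(y_max, image$height)))
}

#' Read / write COCO-style detection lists
#'
#' The interchange format for detector output: a JSON array of objects with
#' fields `image_id`, `category_id`, `bbox` (`[x, y, w, h]` in pixels) and
#' `score`; a `calibrated_score` field is written when present and read back
#' if found. Invalid entries are rejected with their index, never skipped.
#'
#' @param path path to a JSON file.
#' @return `read_detections_json()` returns a detections data frame (see
#'   [detections_frame()]); `write_detections_json()` returns `path`
#'   invisibly.
#' @export
read_detections_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(x)) {
    stop("expected a top-level JSON array of detections", call. = FALSE)
  }
  n <- length(x)
  if (n == 0L) {
    return(detections_frame(character(0), integer(0),
                            bbox(numeric(0), numeric(0), numeric(0),
                                 numeric(0)), numeric(0)))
  }
  get_field <- function(entry, field, i) {
    v <- entry[[field]]
    if (is.null(v)) {
      stop(sprintf("detection %d: missing field `%s`", i, field),
           call. = FALSE)
    }
    v
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    e <- x[[i]]
    if (!is.list(e)) stop(sprintf("detection %d: not an object", i),
                          call. = FALSE)
    bb <- as.numeric(unlist(get_field(e, "bbox", i)))
    score <- as.numeric(get_field(e, "score", i))
    if (length(bb) != 4L || anyNA(bb)) {
      stop(sprintf("detection %d: bbox must be [x, y, w, h]", i),
           call. = FALSE)
    }
    if (bb[3L] <= 0 || bb[4L] <= 0) {
      stop(sprintf("detection %d: nonpositive box width/height", i),
           call. = FALSE)
    }
    if (length(score) != 1L || is.na(score) || score < 0 || score > 1) {
      stop(sprintf("detection %d: score outside [0, 1]", i), call. = FALSE)
    }
    cal <- e[["calibrated_score"]]
    rows[[i]] <- data.frame(
      image_id = as.character(get_field(e, "image_id", i)),
      class_id = as.integer(get_field(e, "category_id", i)),
      x_min = bb[1L], y_min = bb[2L], x_max = bb[1L] + bb[3L],
      y_max = bb[2L] + bb[4L], confidence = score,
      calibrated_confidence = if (is.null(cal)) NA_real_ else as.numeric(cal))
  }
  out <- do.call(rbind, rows)
  detections_frame(out$image_id, out$class_id, out, out$confidence,
                   out$calibrated_confidence)
}

#' @param detections a detections data frame.
#' @rdname read_detections_json
#' @export
write_detections_json <- function(detections, path) {
  n <- nrow(detections)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    d <- detections[i, ]
    e <- list(image_id = d$image_id, category_id = d$class_id,
              bbox = c(d$x_min, d$y_min, d$x_max - d$x_min,
                       d$y_max - d$y_min),
              score = d$confidence)
    if (!is.na(d$calibrated_confidence)) {
      e$calibrated_score <- d$calibrated_confidence
    }
    entries[[i]] <- e
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

records_csv_columns <- c("image_id", "class_id", "confidence", "cx_norm",
                         "cy_norm", "z")

#' Read / write calibration-record CSV
#'
#' Lossless plain-text interchange between the matching stage and the
#' calibration stage. The header is fixed:
#' `image_id,class_id,confidence,cx_norm,cy_norm,z`, optionally followed by
#' `calibrated_confidence`. Reading enforces the record invariants
#' (confidence and centers in `[0, 1]`, `z` in `{0, 1}`).
#'
#' @param records a calibration-record data frame
#'   (see [calibration_records()]).
#' @param path path to a CSV file.
#' @return `read_records_csv()` returns a calibration-record data frame;
#'   `write_records_csv()` returns `path` invisibly.
#' @export
write_records_csv <- function(records, path) {
  cols <- records_csv_columns
  if (!all(cols %in% names(records))) {
    stop("records are missing required columns", call. = FALSE)
  }
  out <- records[, cols, drop = FALSE]
  if ("calibrated_confidence" %in% names(records) &&
      any(!is.na(records$calibrated_confidence))) {
    out$calibrated_confidence <- records$calibrated_confidence
  }
  utils::write.csv(format(out, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character"))
  missing <- setdiff(records_csv_columns, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(calibration_records(character(0), integer(0), numeric(0),
                               numeric(0), numeric(0), integer(0)))
  }
  calibration_records(
    df$image_id, df$class_id, df$confidence, df$cx_norm, df$cy_norm, df$z,
    if ("calibrated_confidence" %in% names(df)) {
      df$calibrated_confidence
    } else NA_real_)
}
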