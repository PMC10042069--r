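#' Simulator configuration
#'
#' Defines a synthetic detection stream whose true calibration function is
#' known, emulating the situation of a trained detector on coronary OCT
#' frames: a set of ground-truth boxes per image, detections that are
#' noisy copies of the ground truth (some missed), spurious false-positive
#' boxes, and stated confidences that may be systematically overconfident.
#'
#' Two generation modes:
#' \describe{
#'   \item{`"posterior_driven"`}{each detection's correctness `z` is drawn
#'     from a stated logistic truth
#'     `P(z = 1 | s) = plogis(a0 + a_conf * logit(conf) +
#'     a_cx * (cx_norm - 0.5) + a_cy * (cy_norm - 0.5))`, so the exact
#'     posterior is available through [true_posterior()] for quantitative
#'     recovery tests. The default coefficients
#'     (`a0 = -1`, `a_conf = 0.5`, `a_cx = 2`, `a_cy = 0`) produce an
#'     overconfident, position-dependent stream: stated confidence exceeds
#'     the truth on average, and boxes on the right half of the image are
#'     more often correct than those on the left.}
#'   \item{`"iou_labeled"`}{`z` is obtained by actually matching the
#'     simulated detections to the simulated ground truth with
#'     [match_detections()], exactly as a real pipeline would; no closed-form
#'     truth exists, but the full stack is exercised.}
#' }
#'
#' @param n_images number of images to simulate.
#' @param image_width,image_height image size in pixels; defaults mirror an
#'   OCT B-scan cross-section (1024 x 1500).
#' @param boxes_per_image Poisson mean of the ground-truth box count per
#'   image.
#' @param box_size_range length-2 vector: uniform range of box side lengths
#'   in pixels.
#' @param loc_noise_sd localization noise (pixels, per corner coordinate)
#'   applied to the true box when emitting its detection.
#' @param miss_rate probability a ground truth yields no detection (FN).
#' @param fp_rate Poisson mean of spurious detections per image.
#' @param conf_shape,fp_conf_shape Beta shape pairs for the stated
#'   confidence of ground-truth-derived and spurious detections. The
#'   defaults (`Beta(5, 2)` vs `Beta(2, 5)`) give high-scoring real
#'   detections and low-scoring clutter.
#' @param mode `"posterior_driven"` or `"iou_labeled"` (see Details).
#' @param truth named coefficients `a0`, `a_conf`, `a_cx`, `a_cy` of the
#'   logistic truth used in posterior-driven mode.
#' @param iou_thresh IoU threshold defining correctness in IoU-labeled mode.
#' @param eps clipping epsilon for `logit(conf)` in the truth.
#' @param seed default seed used by [generate_dataset()].
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(n_images = 200,
                             image_width = 1024, image_height = 1500,
                             boxes_per_image = 2,
                             box_size_range = c(80, 300),
                             loc_noise_sd = 10,
                             miss_rate = 0.15,
                             fp_rate = 0.7,
                             conf_shape = c(5, 2),
                             fp_conf_shape = c(2, 5),
                             mode = c("posterior_driven", "iou_labeled"),
                             truth = c(a0 = -1, a_conf = 0.5,
                                       a_cx = 2, a_cy = 0),
                             iou_thresh = 0.5,
                             eps = 1e-6,
                             seed = 1L) {
  mode <- match.arg(mode)
  n_images <- check_count(n_images, "n_images", min = 1L)
  image_width <- check_count(image_width, "image_width", min = 1L)
  image_height <- check_count(image_height, "image_height", min = 1L)
  check_fraction(miss_rate, "miss_rate", closed = TRUE)
  check_fraction(iou_thresh, "iou_thresh", closed = TRUE)
  if (fp_rate < 0 || boxes_per_image < 0 || loc_noise_sd < 0) {
    stop("rates and noise scales must be nonnegative", call. = FALSE)
  }
  if (length(box_size_range) != 2L || any(box_size_range <= 0) ||
      box_size_range[1L] > box_size_range[2L]) {
    stop("`box_size_range` must be an increasing pair of positive sizes",
         call. = FALSE)
  }
  if (box_size_range[2L] > min(image_width, image_height)) {
    stop("boxes larger than the image are infeasible", call. = FALSE)
  }
  need <- c("a0", "a_conf", "a_cx", "a_cy")
  if (!all(need %in% names(truth))) {
    stop("`truth` must name coefficients a0, a_conf, a_cx, a_cy",
         call. = FALSE)
  }
  structure(list(n_images = n_images, image_width = image_width,
                 image_height = image_height,
                 boxes_per_image = boxes_per_image,
                 box_size_range = as.numeric(box_size_range),
                 loc_noise_sd = loc_noise_sd, miss_rate = miss_rate,
                 fp_rate = fp_rate, conf_shape = as.numeric(conf_shape),
                 fp_conf_shape = as.numeric(fp_conf_shape), mode = mode,
                 truth = truth[need], iou_thresh = iou_thresh, eps = eps,
                 seed = as.integer(seed)),
            class = "simulator_config")
}

#' True posterior of the simulated stream
#'
#' Evaluates the logistic truth configured in posterior-driven mode — the
#' probability that a detection with the given features is correct. This is
#' the oracle against which a fitted calibrator can be scored.
#'
#' @param config a [simulator_config()] in `"posterior_driven"` mode.
#' @param confidence,cx_norm,cy_norm detection features (vectors recycled to
#'   a common length).
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
true_posterior <- function(config, confidence, cx_norm, cy_norm = 0.5) {
  stopifnot(inherits(config, "simulator_config"))
  if (config$mode != "posterior_driven") {
    stop("the true posterior is only defined in posterior-driven mode; ",
         "IoU-labeled correctness has no logistic closed form",
         call. = FALSE)
  }
  a <- config$truth
  stats::plogis(a[["a0"]] +
                  a[["a_conf"]] * clipped_logit(confidence, config$eps) +
                  a[["a_cx"]] * (cx_norm - 0.5) +
                  a[["a_cy"]] * (cy_norm - 0.5))
}

#' Generate a synthetic detection dataset
#'
#' Simulates ground truths and a detection stream under the configured
#' geometry, noise and confidence model, and labels each detection's
#' correctness either by IoU matching against the simulated ground truth or
#' by the configured logistic truth (see [simulator_config()]). Identical
#' `(config, seed)` pairs produce identical datasets.
#'
#' @param config a [simulator_config()].
#' @param seed overrides `config$seed` when given.
#' @return An object of class `synthetic_dataset`: list with
#'   \describe{
#'     \item{ground_truth}{ground-truth data frame.}
#'     \item{detections}{detections data frame.}
#'     \item{records}{calibration-record data frame; in posterior-driven
#'       mode it carries the extra column `p_true`, the latent correctness
#'       probability of each detection.}
#'     \item{image_sizes}{data frame `image_id`, `width`, `height`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulator_config"))
  seed <- seed %||% config$seed
  with_seed(seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  w <- cfg$image_width
  h <- cfg$image_height
  ids <- sprintf("img_%05d", seq_len(cfg$n_images))

  sample_boxes <- function(n) {
    bw <- runif(n, cfg$box_size_range[1L], cfg$box_size_range[2L])
    bh <- runif(n, cfg$box_size_range[1L], cfg$box_size_range[2L])
    cx <- runif(n, bw / 2, w - bw / 2)
    cy <- runif(n, bh / 2, h - bh / 2)
    bbox(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
  }

  # ground truths, vectorized over images
  n_gt <- rpois(cfg$n_images, cfg$boxes_per_image)
  gt_img <- rep(ids, n_gt)
  gt <- ground_truth_frame(gt_img, 0L, sample_boxes(sum(n_gt)))

  # detections derived from ground truths, minus misses, plus corner noise
  emitted <- rbinom(nrow(gt), 1L, 1 - cfg$miss_rate) == 1L
  src <- gt[emitted, , drop = FALSE]
  n_tp <- nrow(src)
  if (n_tp > 0L) {
    noise <- matrix(rnorm(4L * n_tp, sd = cfg$loc_noise_sd), n_tp, 4L)
    xs <- cbind(src$x_min + noise[, 1L], src$x_max + noise[, 2L])
    ys <- cbind(src$y_min + noise[, 3L], src$y_max + noise[, 4L])
    # keep corners ordered and strictly inside the image
    x_lo <- pmin(xs[, 1L], xs[, 2L])
    x_hi <- pmax(xs[, 1L], xs[, 2L])
    y_lo <- pmin(ys[, 1L], ys[, 2L])
    y_hi <- pmax(ys[, 1L], ys[, 2L])
    x_lo <- pmin(pmax(x_lo, 0), w - 1)
    y_lo <- pmin(pmax(y_lo, 0), h - 1)
    x_hi <- pmax(pmin(x_hi, w), x_lo + 1)
    y_hi <- pmax(pmin(y_hi, h), y_lo + 1)
    tp_boxes <- bbox(x_lo, y_lo, x_hi, y_hi)
    tp_img <- src$image_id
  } else {
    tp_boxes <- bbox(numeric(0), numeric(0), numeric(0), numeric(0))
    tp_img <- character(0)
  }

  # spurious detections
  n_fp <- rpois(cfg$n_images, cfg$fp_rate)
  fp_img <- rep(ids, n_fp)
  fp_boxes <- sample_boxes(sum(n_fp))

  det_img <- c(tp_img, fp_img)
  det_boxes <- rbind(tp_boxes, fp_boxes)
  conf <- c(rbeta(n_tp, cfg$conf_shape[1L], cfg$conf_shape[2L]),
            rbeta(sum(n_fp), cfg$fp_conf_shape[1L], cfg$fp_conf_shape[2L]))
  dets <- detections_frame(det_img, 0L, det_boxes, conf)

  centers <- box_centers(dets)
  cx_norm <- centers[, "cx"] / w
  cy_norm <- centers[, "cy"] / h

  if (cfg$mode == "posterior_driven") {
    p_true <- true_posterior(cfg, dets$confidence, cx_norm, cy_norm)
    z <- rbinom(nrow(dets), 1L, p_true)
    records <- calibration_records(dets$image_id, dets$class_id,
                                   dets$confidence, cx_norm, cy_norm, z)
    records$p_true <- p_true
  } else {
    match <- match_detections(dets, gt, iou_thresh = cfg$iou_thresh,
                              conf_thresh = 0)
    # conf_thresh = 0 keeps every detection, so rows align with `dets`
    z <- integer(nrow(dets))
    z[match$matches$det_index] <- match$matches$z
    records <- calibration_records(dets$image_id, dets$class_id,
                                   dets$confidence, cx_norm, cy_norm, z)
  }

  structure(list(ground_truth = gt, detections = dets, records = records,
                 image_sizes = data.frame(image_id = ids, width = w,
                                          height = h),
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d image(s), %d ground truth(s), %d detection(s), mode %s\n",
    x$config$n_images, nrow(x$ground_truth), nrow(x$detections),
    x$config$mode))
  invisible(x)
}
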