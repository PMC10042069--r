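# Independent oracles and fixture generators shared across the suite.
# Each oracle deliberately takes the dumbest correct route (double loops,
# exhaustive search, explicit densities) so it shares no code path with the
# implementation it checks.

# Naive ECE: explicit double loop over bins and records.
ece_oracle <- function(conf, z, bins) {
  n <- length(conf)
  total <- 0
  for (m in seq_len(bins)) {
    lo <- (m - 1) / bins
    hi <- m / bins
    in_bin <- logical(n)
    for (i in seq_len(n)) {
      in_bin[i] <- if (m < bins) conf[i] >= lo && conf[i] < hi else {
        conf[i] >= lo && conf[i] <= hi
      }
    }
    if (!any(in_bin)) next
    total <- total + sum(in_bin) / n *
      abs(mean(z[in_bin]) - mean(conf[in_bin]))
  }
  total
}

# Exhaustive matching: search all injective detection -> ground-truth
# assignments with IoU >= thresh, maximizing TP count then total IoU.
# Returns the best achievable TP count.
match_oracle_tp <- function(iou_mat, thresh) {
  nd <- nrow(iou_mat)
  ng <- ncol(iou_mat)
  best <- list(tp = 0, iou = 0)
  recurse <- function(d, taken, tp, iou_sum) {
    if (d > nd) {
      if (tp > best$tp || (tp == best$tp && iou_sum > best$iou)) {
        best <<- list(tp = tp, iou = iou_sum)
      }
      return(invisible(NULL))
    }
    # leave detection d unmatched
    recurse(d + 1L, taken, tp, iou_sum)
    if (ng > 0L) {
      for (g in seq_len(ng)) {
        if (!taken[g] && iou_mat[d, g] >= thresh) {
          taken[g] <- TRUE
          recurse(d + 1L, taken, tp + 1L, iou_sum + iou_mat[d, g])
          taken[g] <- FALSE
        }
      }
    }
  }
  recurse(1L, rep(FALSE, ng), 0L, 0)
  best$tp
}

# Explicit multivariate normal log density (solve + det, no Cholesky reuse).
log_dmvnorm_explicit <- function(x, mu, sigma) {
  d <- length(mu)
  diff <- as.numeric(x) - mu
  -0.5 * d * log(2 * pi) - 0.5 * log(det(sigma)) -
    0.5 * as.numeric(t(diff) %*% solve(sigma) %*% diff)
}

# Random SPD matrix with moderate conditioning.
random_spd <- function(d) {
  a <- matrix(rnorm(d * d), d, d)
  crossprod(a) + diag(0.5, d)
}

# Random calibration-record frame.
random_records <- function(n) {
  calibration_records(
    image_id = sample(sprintf("img_%03d", 1:20), n, replace = TRUE),
    class_id = 0L,
    confidence = runif(n),
    cx_norm = runif(n),
    cy_norm = runif(n),
    z = rbinom(n, 1, 0.5))
}

# Random scene of detection/ground-truth boxes inside a 100 x 100 image.
random_scene <- function(n_det, n_gt, image_id = "scene") {
  rand_boxes <- function(k) {
    x <- runif(k, 0, 80)
    y <- runif(k, 0, 80)
    bbox(x, y, x + runif(k, 5, 20), y + runif(k, 5, 20))
  }
  list(
    detections = detections_frame(image_id, 0L, rand_boxes(n_det),
                                  confidence = runif(n_det)),
    ground_truth = ground_truth_frame(image_id, 0L, rand_boxes(n_gt)))
}
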