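#' Per-bin calibration statistics
#'
#' Confidence is partitioned into `bins` equal-width bins on `[0, 1]`:
#' `[0, 1/M), [1/M, 2/M), ..., [(M-1)/M, 1]` — half-open except the last,
#' which is closed so confidence exactly 1 is always counted. For each bin
#' the count, the empirical precision (mean of `z`) and the mean confidence
#' are reported; empty bins appear with count 0 and `NA` statistics.
#'
#' @param records calibration-record data frame; only the `confidence`
#'   (or `calibrated_confidence`) and `z` columns are used.
#' @param bins number of equal-width bins M (default 10, the dominant
#'   convention for expected calibration error).
#' @param use_calibrated if `TRUE`, bin the `calibrated_confidence` column
#'   instead of the raw confidence.
#' @return Data frame with columns `bin`, `lower`, `upper`, `count`,
#'   `precision`, `mean_confidence`.
#' @export
bin_statistics <- function(records, bins = 10, use_calibrated = FALSE) {
  bins <- check_count(bins, "bins", min = 1L)
  conf <- record_scores(records, use_calibrated)
  z <- records$z
  if (length(conf) == 0L) {
    stop("`records` is empty: calibration statistics are undefined",
         call. = FALSE)
  }
  if (is.null(z) || !all(z %in% c(0, 1))) {
    stop("`records` must have a binary `z` column", call. = FALSE)
  }
  idx <- pmin(floor(conf * bins) + 1L, bins)  # last bin right-closed
  count <- tabulate(idx, nbins = bins)
  prec <- rep(NA_real_, bins)
  mean_conf <- rep(NA_real_, bins)
  nonempty <- which(count > 0L)
  sums_z <- vapply(split(as.numeric(z), factor(idx, levels = seq_len(bins))),
                   sum, numeric(1))
  sums_c <- vapply(split(conf, factor(idx, levels = seq_len(bins))),
                   sum, numeric(1))
  prec[nonempty] <- sums_z[nonempty] / count[nonempty]
  mean_conf[nonempty] <- sums_c[nonempty] / count[nonempty]
  data.frame(bin = seq_len(bins),
             lower = (seq_len(bins) - 1) / bins,
             upper = seq_len(bins) / bins,
             count = count,
             precision = prec,
             mean_confidence = mean_conf)
}

record_scores <- function(records, use_calibrated) {
  col <- if (use_calibrated) "calibrated_confidence" else "confidence"
  conf <- records[[col]]
  if (is.null(conf)) {
    stop(sprintf("`records` has no `%s` column", col), call. = FALSE)
  }
  if (anyNA(conf) || any(conf < 0) || any(conf > 1)) {
    stop(sprintf("`%s` must be in [0, 1] with no missing values", col),
         call. = FALSE)
  }
  conf
}

#' Expected calibration error
#'
#' The bin-weighted mean absolute gap between empirical precision and mean
#' stated confidence:
#' `ECE = sum_m |B_m| / N * |Prec(m) - conf(m)|`
#' over `M` equal-width confidence bins. A perfectly calibrated detector —
#' one whose predictions at confidence c are correct with probability c —
#' has ECE near 0; overconfident detectors have precision below confidence
#' and a large ECE.
#'
#' @inheritParams bin_statistics
#' @return An object of class `ece_result`: list with `ece`, `bins` (the
#'   [bin_statistics()] table), `M` and `N`.
#' @examples
#' r <- calibration_records("a", 0L, c(0.9, 0.8, 0.2, 0.6),
#'                          0.5, 0.5, c(1, 1, 0, 1))
#' ece(r, bins = 2)
#' @export
ece <- function(records, bins = 10, use_calibrated = FALSE) {
  stats <- bin_statistics(records, bins = bins,
                          use_calibrated = use_calibrated)
  n <- sum(stats$count)
  nonempty <- stats$count > 0L
  value <- sum(stats$count[nonempty] / n *
                 abs(stats$precision[nonempty] -
                       stats$mean_confidence[nonempty]))
  structure(list(ece = value, bins = stats, M = nrow(stats), N = n),
            class = "ece_result")
}

#' @export
print.ece_result <- function(x, digits = 4, ...) {
  cat(sprintf("ECE = %.*f  (M = %d bins, N = %d predictions)\n", digits,
              x$ece, x$M, x$N))
  invisible(x)
}

#' Reliability curve
#'
#' The plotting companion of [ece()]: per-bin empirical precision against
#' per-bin mean confidence. For a calibrated detector the points lie on the
#' diagonal.
#'
#' @inheritParams bin_statistics
#' @return Data frame with columns `midpoint`, `precision`,
#'   `mean_confidence`, `count` (empty bins retained with `NA` statistics).
#' @export
reliability_curve <- function(records, bins = 10, use_calibrated = FALSE) {
  stats <- bin_statistics(records, bins = bins,
                          use_calibrated = use_calibrated)
  data.frame(midpoint = (stats$lower + stats$upper) / 2,
             precision = stats$precision,
             mean_confidence = stats$mean_confidence,
             count = stats$count)
}
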