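#' Feature specification for dependent logistic calibration
#'
#' Selects which prediction features enter the calibrator and how. The
#' available features are the detector confidence (`"conf"`) and the
#' normalized box-center coordinates (`"cx"`, `"cy"`); using the centers
#' alongside the confidence is what makes the calibration *dependent* — it
#' can capture position-dependent miscalibration that a score-only
#' calibrator cannot. Confidence is logit-transformed by default (after
#' clipping to `[eps, 1 - eps]`) because a variable bounded in `[0, 1]` is
#' poorly modelled by a Gaussian; raw mode is available.
#'
#' @param features character vector, an ordered subset of
#'   `c("conf", "cx", "cy")`, no duplicates, at least one entry.
#' @param logit_conf apply the logit transform to the confidence feature
#'   (default `TRUE`).
#' @param eps clipping epsilon for the logit transform, in `(0, 0.1)`.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(features = c("conf", "cx", "cy"),
                         logit_conf = TRUE, eps = 1e-6) {
  allowed <- c("conf", "cx", "cy")
  if (length(features) < 1L || !all(features %in% allowed) ||
      anyDuplicated(features)) {
    stop("`features` must be a non-empty, duplicate-free subset of ",
         "c(\"conf\", \"cx\", \"cy\")", call. = FALSE)
  }
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.1) {
    stop("`eps` must be in (0, 0.1)", call. = FALSE)
  }
  structure(list(features = as.character(features),
                 logit_conf = isTRUE(logit_conf), eps = eps),
            class = "feature_spec")
}

#' Assemble the calibration feature matrix
#'
#' Builds the feature vector `s` for each record, in the order given by the
#' spec: confidence (logit-transformed if flagged), then the normalized
#' center coordinates as-is.
#'
#' @param records calibration-record data frame (or any data frame with the
#'   needed columns `confidence`, `cx_norm`, `cy_norm`).
#' @param spec a [feature_spec()].
#' @return Numeric matrix, one row per record, columns named after the
#'   features.
#' @export
build_feature_matrix <- function(records, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  cols <- lapply(spec$features, function(f) {
    switch(f,
      conf = {
        v <- records[["confidence"]]
        if (is.null(v)) stop("records lack a `confidence` column",
                             call. = FALSE)
        if (spec$logit_conf) clipped_logit(v, spec$eps) else v
      },
      cx = records[["cx_norm"]] %||%
        stop("records lack a `cx_norm` column", call. = FALSE),
      cy = records[["cy_norm"]] %||%
        stop("records lack a `cy_norm` column", call. = FALSE))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- spec$features
  if (anyNA(m) || any(!is.finite(m))) {
    stop("non-finite feature values", call. = FALSE)
  }
  m
}

#' Construct dependent-logistic calibrator parameters
#'
#' Low-level constructor for a fitted (or externally supplied) calibrator:
#' the two Gaussian populations' means and covariances, their sizes, and the
#' log-likelihood-ratio constant
#' `c = 1/2 * ln(det(Sigma_minus) / det(Sigma_plus)) + ln(n_plus / n_minus)`
#' (the prior log-odds term is dropped when `include_prior = FALSE`).
#' Most users call [fit_dependent_logistic()] instead.
#'
#' @param mu_plus,mu_minus mean feature vectors of the correct (`z = 1`) and
#'   incorrect (`z = 0`) populations.
#' @param sigma_plus,sigma_minus covariance matrices of the two populations
#'   (symmetric positive definite).
#' @param n_plus,n_minus population sizes used for the prior log-odds.
#' @param spec the [feature_spec()] describing the columns of `s`, or `NULL`
#'   when the calibrator is used on raw feature matrices.
#' @param lambda regularization actually added to each covariance diagonal
#'   (bookkeeping; length-2 vector `c(plus, minus)`).
#' @param include_prior include `ln(n_plus / n_minus)` in the constant.
#' @return An object of class `calibrator_params`.
#' @export
calibrator_params <- function(mu_plus, mu_minus, sigma_plus, sigma_minus,
                              n_plus, n_minus, spec = NULL,
                              lambda = c(0, 0), include_prior = TRUE) {
  mu_plus <- unname(as.numeric(mu_plus))
  mu_minus <- unname(as.numeric(mu_minus))
  d <- length(mu_plus)
  sigma_plus <- unname(as.matrix(sigma_plus))
  sigma_minus <- unname(as.matrix(sigma_minus))
  if (length(mu_minus) != d || any(dim(sigma_plus) != d) ||
      any(dim(sigma_minus) != d)) {
    stop("parameter dimensions are inconsistent", call. = FALSE)
  }
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "feature_spec"))
    if (length(spec$features) != d) {
      stop("feature spec dimension does not match the mean vectors",
           call. = FALSE)
    }
  }
  # Cholesky factors double as the PD check and the stable solve/log-det
  chol_plus <- tryCatch(chol(sigma_plus), error = function(e) {
    stop("sigma_plus is not positive definite", call. = FALSE)
  })
  chol_minus <- tryCatch(chol(sigma_minus), error = function(e) {
    stop("sigma_minus is not positive definite", call. = FALSE)
  })
  logdet_plus <- 2 * sum(log(diag(chol_plus)))
  logdet_minus <- 2 * sum(log(diag(chol_minus)))
  const <- 0.5 * (logdet_minus - logdet_plus) +
    if (isTRUE(include_prior)) log(n_plus / n_minus) else 0
  structure(list(mu_plus = mu_plus, mu_minus = mu_minus,
                 sigma_plus = sigma_plus, sigma_minus = sigma_minus,
                 chol_plus = chol_plus, chol_minus = chol_minus,
                 c = const, n_plus = n_plus, n_minus = n_minus,
                 lambda = lambda, include_prior = isTRUE(include_prior),
                 spec = spec),
            class = "calibrator_params")
}

#' @export
print.calibrator_params <- function(x, ...) {
  d <- length(x$mu_plus)
  feats <- if (is.null(x$spec)) paste0(d, "-D raw features") else {
    paste(x$spec$features, collapse = ", ")
  }
  cat(sprintf(
    "<calibrator_params> features: %s | n+ = %d, n- = %d | c = %.4f\n",
    feats, x$n_plus, x$n_minus, x$c))
  invisible(x)
}

#' Fit the dependent logistic calibrator
#'
#' Splits the records by correctness, models each population's feature
#' vector as a multivariate Gaussian (sample mean; sample covariance with
#' denominator n - 1, plus a small ridge `lambda * I` for positive
#' definiteness), and assembles the log-likelihood-ratio calibration map.
#' With `K + 1` features, each population must contribute at least `K + 2`
#' records.
#'
#' @inheritParams build_feature_matrix
#' @param lambda_scale ridge scale: each covariance receives
#'   `lambda_scale * mean(diag(Sigma)) * I` (default `1e-6`).
#' @param include_prior include the prior log-odds `ln(n_plus / n_minus)`
#'   in the constant `c` (default `TRUE`; disable for the strict
#'   equal-prior log-likelihood ratio).
#' @return A [calibrator_params()] object carrying the spec, so it can be
#'   applied directly to records or detections.
#' @seealso [fit_gaussian_lr()] for fitting on a raw feature matrix.
#' @export
fit_dependent_logistic <- function(records, spec = feature_spec(),
                                   lambda_scale = 1e-6,
                                   include_prior = TRUE) {
  x <- build_feature_matrix(records, spec)
  z <- records$z
  if (is.null(z) || !all(z %in% c(0, 1))) {
    stop("`records` must have a binary `z` column", call. = FALSE)
  }
  params <- fit_gaussian_lr(x, z, lambda_scale = lambda_scale,
                            include_prior = include_prior)
  params$spec <- spec
  params
}

#' Fit a two-Gaussian log-likelihood-ratio model on a feature matrix
#'
#' The estimation core behind [fit_dependent_logistic()], usable on any
#' real-valued feature matrix with binary labels.
#'
#' @param x numeric matrix, one row per sample.
#' @param z binary labels (1 = correct population, 0 = incorrect).
#' @inheritParams fit_dependent_logistic
#' @return A [calibrator_params()] object with `spec = NULL`.
#' @export
fit_gaussian_lr <- function(x, z, lambda_scale = 1e-6,
                            include_prior = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite feature values", call. = FALSE)
  }
  if (!all(z %in% c(0, 1)) || length(z) != nrow(x)) {
    stop("`z` must be a 0/1 vector with one entry per row of `x`",
         call. = FALSE)
  }
  d <- ncol(x)
  n_plus <- sum(z == 1)
  n_minus <- sum(z == 0)
  if (n_plus < d + 1L) {
    stop(sprintf(
      "too few correct (z = 1) records: need at least %d, got %d",
      d + 1L, n_plus), call. = FALSE)
  }
  if (n_minus < d + 1L) {
    stop(sprintf(
      "too few incorrect (z = 0) records: need at least %d, got %d",
      d + 1L, n_minus), call. = FALSE)
  }
  fit_pop <- function(xs) {
    mu <- colMeans(xs)
    sigma <- stats::cov(xs)
    lambda <- lambda_scale * sum(diag(sigma)) / d
    if (lambda <= 0) lambda <- lambda_scale  # fully degenerate population
    list(mu = mu, sigma = sigma + diag(lambda, d), lambda = lambda)
  }
  pop_plus <- fit_pop(x[z == 1, , drop = FALSE])
  pop_minus <- fit_pop(x[z == 0, , drop = FALSE])
  calibrator_params(pop_plus$mu, pop_minus$mu, pop_plus$sigma,
                    pop_minus$sigma, n_plus = n_plus, n_minus = n_minus,
                    lambda = c(pop_plus$lambda, pop_minus$lambda),
                    include_prior = include_prior)
}

#' Log-likelihood ratio of the fitted calibrator
#'
#' Evaluates
#' `lr(s) = 1/2 * [ (s - mu_minus)' Sigma_minus^-1 (s - mu_minus)
#'                - (s - mu_plus)' Sigma_plus^-1 (s - mu_plus) ] + c`,
#' the log ratio of the correct-population to incorrect-population Gaussian
#' densities (plus prior log-odds when fitted with `include_prior = TRUE`).
#' Quadratic forms are computed through the stored Cholesky factors with
#' triangular solves; no covariance is ever explicitly inverted.
#'
#' @param params a [calibrator_params()] object.
#' @param s numeric feature vector, or a matrix with one feature vector per
#'   row.
#' @return Numeric vector of log-likelihood ratios, one per row of `s`.
#' @export
log_likelihood_ratio <- function(params, s) {
  stopifnot(inherits(params, "calibrator_params"))
  d <- length(params$mu_plus)
  if (is.null(dim(s))) {
    if (length(s) %% d != 0L) {
      stop(sprintf(
        "feature dimension mismatch: params are %d-D, input has length %d",
        d, length(s)), call. = FALSE)
    }
    s <- matrix(as.numeric(s), ncol = d, byrow = TRUE)
  }
  s <- as.matrix(s)
  if (ncol(s) != d) {
    stop(sprintf("feature dimension mismatch: params are %d-D, input is %d-D",
                 d, ncol(s)), call. = FALSE)
  }
  mahal_sq <- function(chol_sigma, mu) {
    # rows of `s` centered at mu; solve R' y = (s - mu)'; |y|^2 per column
    y <- backsolve(chol_sigma, t(s) - mu, transpose = TRUE)
    colSums(y^2)
  }
  0.5 * (mahal_sq(params$chol_minus, params$mu_minus) -
           mahal_sq(params$chol_plus, params$mu_plus)) + params$c
}

#' Apply the calibration map
#'
#' Maps each prediction through `g(s) = 1 / (1 + exp(-lr(s)))`, the sigmoid
#' of the log-likelihood ratio, and stores the result in the
#' `calibrated_confidence` column. The original confidence is preserved.
#'
#' @param params a fitted [calibrator_params()] with a feature spec.
#' @param records calibration-record data frame (any data frame carrying the
#'   columns the spec needs).
#' @return `records` with `calibrated_confidence` filled in.
#' @seealso [calibrate_scores()] to get the calibrated values for a raw
#'   feature matrix.
#' @export
apply_calibration <- function(params, records) {
  stopifnot(inherits(params, "calibrator_params"))
  if (is.null(params$spec)) {
    stop("params carry no feature spec; use calibrate_scores() on a ",
         "feature matrix", call. = FALSE)
  }
  s <- build_feature_matrix(records, params$spec)
  records$calibrated_confidence <- calibrate_scores(params, s)
  records
}

#' @param s feature matrix (rows are predictions) matching the params'
#'   dimension.
#' @rdname apply_calibration
#' @export
calibrate_scores <- function(params, s) {
  stats::plogis(log_likelihood_ratio(params, s))
}

#' Split records into calibration-fit and test sets
#'
#' Seeded random partition of prediction records, by default 60% to fit the
#' calibration model and 40% held out to measure it. With
#' `stratify = TRUE` the split is drawn within each correctness class, so
#' the fit set preserves the overall z ratio to within one record per
#' stratum.
#'
#' @param records calibration-record data frame (at least 2 rows).
#' @param fraction fraction assigned to the fit set, in `(0, 1)`
#'   (default 0.6).
#' @param seed integer seed for the shuffle; the same seed always yields the
#'   same partition. `NULL` uses the ambient RNG stream.
#' @param stratify stratify the split by `z`.
#' @return List with elements `fit` and `test`: disjoint, exhaustive subsets
#'   of `records`.
#' @export
split_fit_test <- function(records, fraction = 0.6, seed = NULL,
                           stratify = FALSE) {
  check_fraction(fraction, "fraction")
  n <- nrow(records)
  if (is.null(n) || n < 2L) {
    stop("need at least 2 records to split", call. = FALSE)
  }
  take <- with_seed(seed, {
    if (stratify) {
      if (is.null(records$z)) {
        stop("stratified split needs a `z` column", call. = FALSE)
      }
      picked <- logical(n)
      for (zv in unique(records$z)) {
        idx <- which(records$z == zv)
        k <- round(fraction * length(idx))
        picked[sample(idx, k)] <- TRUE
      }
      picked
    } else {
      picked <- logical(n)
      picked[sample.int(n, round(fraction * n))] <- TRUE
      picked
    }
  })
  if (!any(take) || all(take)) {
    stop("`fraction` leaves one side of the split empty", call. = FALSE)
  }
  list(fit = records[take, , drop = FALSE],
       test = records[!take, , drop = FALSE])
}

#' Serialize / deserialize calibrator parameters
#'
#' Writes the fitted calibrator to JSON (means, covariances row-major, the
#' constant `c`, regularization, population sizes, feature spec and a format
#' version) and reads it back losslessly.
#'
#' @param params a [calibrator_params()] object.
#' @param path path to a JSON file.
#' @return `read_calibrator_json()` returns the restored
#'   [calibrator_params()]; `write_calibrator_json()` returns `path`
#'   invisibly.
#' @export
write_calibrator_json <- function(params, path) {
  stopifnot(inherits(params, "calibrator_params"))
  obj <- list(
    format = "detcal-calibrator",
    version = 1L,
    features = if (is.null(params$spec)) NULL else params$spec$features,
    logit_conf = if (is.null(params$spec)) NULL else params$spec$logit_conf,
    eps = if (is.null(params$spec)) NULL else params$spec$eps,
    mu_plus = params$mu_plus,
    mu_minus = params$mu_minus,
    sigma_plus = as.vector(t(params$sigma_plus)),
    sigma_minus = as.vector(t(params$sigma_minus)),
    dim = length(params$mu_plus),
    c = params$c,
    lambda = params$lambda,
    n_plus = params$n_plus,
    n_minus = params$n_minus,
    include_prior = params$include_prior)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibrator_json
#' @export
read_calibrator_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "detcal-calibrator")) {
    stop(sprintf("%s is not a detcal calibrator file", path), call. = FALSE)
  }
  d <- obj$dim
  spec <- if (!is.null(obj$features)) {
    feature_spec(obj$features, logit_conf = obj$logit_conf, eps = obj$eps)
  }
  params <- calibrator_params(
    mu_plus = obj$mu_plus, mu_minus = obj$mu_minus,
    sigma_plus = matrix(obj$sigma_plus, d, d, byrow = TRUE),
    sigma_minus = matrix(obj$sigma_minus, d, d, byrow = TRUE),
    n_plus = obj$n_plus, n_minus = obj$n_minus, spec = spec,
    lambda = obj$lambda, include_prior = obj$include_prior)
  params
}
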