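test_that("feature vectors are assembled in spec order with optional logit", {
  r <- calibration_records("a", 0L, 0.9, 0.25, 0.5, 1)
  raw <- build_feature_matrix(r, feature_spec(c("conf", "cx", "cy"),
                                              logit_conf = FALSE))
  expect_equal(as.numeric(raw), c(0.9, 0.25, 0.5))

  sp <- feature_spec("conf", logit_conf = TRUE, eps = 1e-6)
  half <- calibration_records("a", 0L, 0.5, 0.5, 0.5, 1)
  expect_equal(as.numeric(build_feature_matrix(half, sp)), 0)
  one <- calibration_records("a", 0L, 1.0, 0.5, 0.5, 1)
  expect_equal(as.numeric(build_feature_matrix(one, sp)),
               log((1 - 1e-6) / 1e-6), tolerance = 1e-9)

  expect_error(feature_spec(character(0)), "features")
  expect_error(feature_spec(c("conf", "conf")), "features")
  expect_error(feature_spec("conf", eps = 0.5), "eps")
})

test_that("log-likelihood ratio matches hand evaluation in 1-D", {
  p <- calibrator_params(mu_plus = 1, mu_minus = 0, sigma_plus = 1,
                         sigma_minus = 1, n_plus = 10, n_minus = 10)
  expect_equal(p$c, 0)
  expect_equal(log_likelihood_ratio(p, 0.5), 0, tolerance = 1e-12)
  expect_equal(log_likelihood_ratio(p, 1.5),
               0.5 * (1.5^2 - 0.5^2), tolerance = 1e-12)
  expect_equal(calibrate_scores(p, 1.5), 1 / (1 + exp(-1)),
               tolerance = 1e-9)
  expect_error(log_likelihood_ratio(p, c(1, 2)), NA)  # two 1-D points
  p3 <- calibrator_params(rep(0, 3), rep(1, 3), diag(3), diag(3), 5, 5)
  expect_error(log_likelihood_ratio(p3, c(1, 2)), "dimension")
})

test_that("lr equals the explicit two-density log ratio plus prior odds", {
  set.seed(31)
  for (i in 1:100) {
    d <- sample(1:4, 1)
    p <- calibrator_params(
      mu_plus = rnorm(d), mu_minus = rnorm(d),
      sigma_plus = random_spd(d), sigma_minus = random_spd(d),
      n_plus = sample(10:1000, 1), n_minus = sample(10:1000, 1))
    for (j in 1:10) {
      s <- rnorm(d, sd = 2)
      oracle <- log(mclust::dmvnorm(matrix(s, 1), p$mu_plus,
                                    p$sigma_plus)) +
        log(p$n_plus) -
        log(mclust::dmvnorm(matrix(s, 1), p$mu_minus, p$sigma_minus)) -
        log(p$n_minus)
      expect_equal(log_likelihood_ratio(p, s), oracle, tolerance = 1e-9)
    }
  }
})

test_that("identical populations calibrate everything to about one half", {
  set.seed(37)
  n <- 20000
  x <- matrix(rnorm(2 * n * 2), ncol = 2)
  z <- rep(c(0, 1), each = n)
  p <- fit_gaussian_lr(x, z)
  grid <- matrix(rnorm(400), ncol = 2)
  expect_lte(mean(abs(calibrate_scores(p, grid) - 0.5)), 0.02)
  expect_lte(abs(p$c), 0.05)  # equal sizes, equal covariances
})

test_that("equal-variance 1-D gaussians recover the closed-form posterior", {
  set.seed(43)
  n <- 50000
  x <- matrix(c(rnorm(n, 1, 1), rnorm(n, 0, 1)), ncol = 1)
  z <- rep(c(1, 0), each = n)
  p <- fit_gaussian_lr(x, z)
  grid <- matrix(seq(-2, 3, length.out = 200), ncol = 1)
  # true posterior with equal priors: sigmoid(s - 1/2)
  expect_lte(mean(abs(calibrate_scores(p, grid) -
                        plogis(grid[, 1] - 0.5))), 0.01)
})

test_that("population size preconditions are enforced", {
  r <- calibration_records("a", 0L, c(0.9, 0.8, 0.1, 0.2, 0.3, 0.4, 0.5),
                           runif(7), runif(7), c(1, 1, 0, 0, 0, 0, 0))
  expect_error(fit_dependent_logistic(r), "correct \\(z = 1\\)")
  expect_error(fit_gaussian_lr(matrix(rnorm(10), ncol = 1),
                               rep(1, 10)), "incorrect")
})

test_that("shared-covariance truth yields an effectively affine lr", {
  set.seed(47)
  sigma <- random_spd(2)
  p <- calibrator_params(mu_plus = c(1, 0), mu_minus = c(0, 1),
                         sigma_plus = sigma, sigma_minus = sigma,
                         n_plus = 7, n_minus = 3)
  # affine in s: lr(a) + lr(b) = 2 lr((a+b)/2) for any a, b
  for (i in 1:20) {
    a <- rnorm(2)
    b <- rnorm(2)
    expect_equal(log_likelihood_ratio(p, a) + log_likelihood_ratio(p, b),
                 2 * log_likelihood_ratio(p, (a + b) / 2),
                 tolerance = 1e-9)
  }
  # g strictly increasing in lr
  lrs <- sort(log_likelihood_ratio(p, matrix(rnorm(40), ncol = 2)))
  expect_true(all(diff(plogis(lrs)) >= 0))
})

test_that("split_fit_test partitions 60/40, deterministically by seed", {
  r <- random_records(10)
  sp <- split_fit_test(r, fraction = 0.6, seed = 42)
  expect_equal(nrow(sp$fit), 6L)
  expect_equal(nrow(sp$test), 4L)
  expect_equal(nrow(rbind(sp$fit, sp$test)), 10L)
  expect_length(intersect(rownames(sp$fit), rownames(sp$test)), 0L)
  sp2 <- split_fit_test(r, fraction = 0.6, seed = 42)
  expect_identical(sp$fit, sp2$fit)

  set.seed(53)
  r100 <- calibration_records("a", 0L, runif(100), runif(100), runif(100),
                              rep(c(1, 0), c(30, 70)))
  st <- split_fit_test(r100, 0.6, seed = 1, stratify = TRUE)
  expect_lte(abs(sum(st$fit$z) - 18), 1)
  expect_equal(nrow(st$fit) + nrow(st$test), 100L)

  expect_error(split_fit_test(r[1, , drop = FALSE]), "at least 2")
  expect_error(split_fit_test(r, fraction = 1), "fraction")
})

test_that("calibrator parameters serialize and deserialize losslessly", {
  set.seed(59)
  r <- random_records(400)
  p <- fit_dependent_logistic(r, feature_spec(c("conf", "cx", "cy")))
  f <- withr::local_tempfile(fileext = ".json")
  write_calibrator_json(p, f)
  q <- read_calibrator_json(f)
  expect_equal(q$mu_plus, p$mu_plus, tolerance = 1e-12)
  expect_equal(q$sigma_minus, p$sigma_minus, tolerance = 1e-12)
  expect_equal(q$c, p$c, tolerance = 1e-12)
  expect_equal(q$spec$features, p$spec$features)
  # applying the restored calibrator gives identical scores
  test <- random_records(50)
  expect_equal(apply_calibration(q, test)$calibrated_confidence,
               apply_calibration(p, test)$calibrated_confidence,
               tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), f2, auto_unbox = TRUE)
  expect_error(read_calibrator_json(f2), "not a detcal calibrator")
})

test_that("calibrated confidences stay in (0, 1) and keep the original", {
  set.seed(61)
  r <- random_records(300)
  p <- fit_dependent_logistic(r)
  out <- apply_calibration(p, r)
  expect_true(all(out$calibrated_confidence > 0 &
                    out$calibrated_confidence < 1))
  expect_identical(out$confidence, r$confidence)
})
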