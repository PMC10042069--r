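test_that("one ground truth is matched at most once", {
  gt <- ground_truth_frame("a", 0L, bbox(0, 0, 10, 10))
  dets <- detections_frame("a", 0L,
                           bbox(c(0, 1), c(0, 0), c(10, 11), c(10, 10)),
                           confidence = c(0.9, 0.7))
  res <- match_detections(dets, gt, iou_thresh = 0.5, conf_thresh = 0)
  expect_equal(res$metrics$tp, 1L)
  expect_equal(res$metrics$fp, 1L)
  expect_equal(res$metrics$fn, 0L)
  # the higher-confidence detection got the match
  expect_equal(res$matches$z[res$matches$confidence == 0.9], 1L)
  expect_equal(res$matches$z[res$matches$confidence == 0.7], 0L)
})

test_that("empty detection or ground-truth sets give pure FN / FP", {
  gt <- ground_truth_frame(rep("a", 3), 0L,
                           bbox(c(0, 20, 40), 0, c(10, 30, 50), 10))
  none <- detections_frame(character(0), integer(0),
                           bbox(numeric(0), numeric(0), numeric(0),
                                numeric(0)), numeric(0))
  res <- match_detections(none, gt)
  expect_equal(c(res$metrics$tp, res$metrics$fp, res$metrics$fn),
               c(0L, 0L, 3L))

  res2 <- match_detections(
    detections_frame("a", 0L, bbox(0, 0, 5, 5), 0.8),
    ground_truth_frame(character(0), integer(0),
                       bbox(numeric(0), numeric(0), numeric(0),
                            numeric(0))))
  expect_equal(c(res2$metrics$tp, res2$metrics$fp, res2$metrics$fn),
               c(0L, 1L, 0L))
})

test_that("matching respects image and class boundaries", {
  gt <- ground_truth_frame(c("a", "b"), c(0L, 0L),
                           bbox(c(0, 0), c(0, 0), c(10, 10), c(10, 10)))
  # same geometry but wrong image / wrong class
  dets <- detections_frame(c("a", "b", "a"), c(1L, 0L, 0L),
                           bbox(c(0, 0, 50), c(0, 0, 50),
                                c(10, 10, 60), c(10, 10, 60)),
                           confidence = 0.9)
  res <- match_detections(dets, gt, conf_thresh = 0)
  expect_equal(res$metrics$tp, 1L)   # only the image-b class-0 detection
  expect_equal(res$matches$z, c(0L, 1L, 0L))
})

test_that("confidence threshold filters before matching, monotonically", {
  set.seed(5)
  scene <- random_scene(8, 5)
  prev_tp <- Inf
  prev_fp <- Inf
  for (ct in c(0, 0.25, 0.5, 0.75, 0.95)) {
    res <- match_detections(scene$detections, scene$ground_truth,
                            iou_thresh = 0.3, conf_thresh = ct)
    expect_lte(res$metrics$tp, prev_tp)
    expect_lte(res$metrics$fp, prev_fp)
    expect_equal(res$metrics$tp + res$metrics$fp,
                 sum(scene$detections$confidence >= ct))
    expect_equal(res$metrics$tp + res$metrics$fn,
                 nrow(scene$ground_truth))
    prev_tp <- res$metrics$tp
    prev_fp <- res$metrics$fp
  }
})

test_that("greedy matching agrees with the exhaustive oracle on small scenes", {
  set.seed(99)
  n_scenes <- 300
  agree <- 0L
  for (i in seq_len(n_scenes)) {
    scene <- random_scene(sample(0:6, 1), sample(0:6, 1))
    res <- match_detections(scene$detections, scene$ground_truth,
                            iou_thresh = 0.3, conf_thresh = 0)
    im <- detcal:::iou_matrix(scene$detections, scene$ground_truth)
    best_tp <- match_oracle_tp(im, 0.3)
    expect_equal(res$metrics$tp + res$metrics$fn,
                 nrow(scene$ground_truth))
    expect_equal(res$metrics$tp + res$metrics$fp,
                 nrow(scene$detections))
    if (res$metrics$tp == best_tp) agree <- agree + 1L
  }
  expect_gte(agree / n_scenes, 0.95)
})

test_that("detection metrics follow the count identities and conventions", {
  m <- detection_metrics(3, 1, 2)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))

  zero <- detection_metrics(0, 0, 0)
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))
  perfect <- detection_metrics(5, 0, 0)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  # f1 between precision and recall when both positive
  set.seed(2)
  for (i in 1:30) {
    mm <- detection_metrics(sample(1:20, 1), sample(0:20, 1),
                            sample(0:20, 1))
    expect_gte(mm$f1, min(mm$precision, mm$recall))
    expect_lte(mm$f1, max(mm$precision, mm$recall))
  }
  expect_error(detection_metrics(-1, 0, 0), "tp")
})

test_that("records_from_matches normalizes centers by the image size", {
  gt <- ground_truth_frame("a", 0L, bbox(10, 20, 30, 40))
  dets <- detections_frame("a", 0L, bbox(10, 20, 30, 40), 0.8)
  res <- match_detections(dets, gt, conf_thresh = 0)
  recs <- records_from_matches(
    dets, res, data.frame(image_id = "a", width = 100, height = 200))
  expect_equal(recs$cx_norm, 0.2)
  expect_equal(recs$cy_norm, 0.15)
  expect_equal(recs$z, 1L)
  expect_error(
    records_from_matches(dets, res,
                         data.frame(image_id = "b", width = 1, height = 1)),
    "no image size")
})
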