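mk_seq <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(frame = r[1], id = r[2], x = r[3], y = r[4], w = r[5], h = r[6],
               class_id = 0L)
  }))
  df
}

# two parallel constant tracks over n frames
two_tracks <- function(n) {
  do.call(rbind, lapply(seq_len(n) - 1, function(f) {
    data.frame(frame = f, id = 1:2, x = c(0, 100), y = 0, w = 10, h = 10,
               class_id = 0L)
  }))
}

test_that("frame matching maximizes IoU above the threshold", {
  g <- data.frame(x = c(0, 30), y = 0, w = 10, h = 10, class_id = 0L)
  p <- data.frame(x = c(0, 30), y = 0, w = 10, h = 10, class_id = 0L)
  fm <- frame_match(g, p, 0.5)
  expect_equal(nrow(fm$matches), 2)
  expect_equal(unname(fm$matches[, "iou"]), c(1, 1))

  # one prediction overlapping two GT boxes: matched to the better partner
  g <- data.frame(x = c(0, 8), y = 0, w = c(20, 22), h = 10, class_id = 0L)
  p <- data.frame(x = 2, y = 0, w = 20, h = 10, class_id = 0L)
  fm <- frame_match(g, p, 0.5)
  expect_equal(nrow(fm$matches), 1)
  expect_equal(unname(fm$matches[1, "gt"]), 1)
  expect_equal(fm$unmatched_gt, 2L)

  # nothing above threshold
  p <- data.frame(x = 50, y = 50, w = 10, h = 10, class_id = 0L)
  fm <- frame_match(g, p, 0.5)
  expect_equal(nrow(fm$matches), 0)
})

test_that("MOTA matches hand-computed counts", {
  gt <- two_tracks(5)
  expect_equal(mota(gt, gt)$MOTA, 100)
  # 10 GT boxes, 1 FN, 1 FP -> 80
  pred <- gt
  pred <- pred[-1, ]                       # one miss
  extra <- data.frame(frame = 2, id = 9, x = 300, y = 200, w = 10, h = 10,
                      class_id = 0L)
  pred <- rbind(pred, extra)
  r <- mota(gt, pred)
  expect_equal(r$FN, 1); expect_equal(r$FP, 1); expect_equal(r$IDSW, 0)
  expect_equal(r$MOTA, 80)
  # no predictions at all -> 0
  expect_equal(mota(gt, gt[0, ])$MOTA, 0)
  expect_error(mota(gt[0, ], gt), "no ground truth")
})

test_that("identity switches are counted between consecutive matched frames", {
  gt <- two_tracks(10)
  pred <- gt
  pred$id <- ifelse(pred$frame < 5, pred$id, pred$id + 10) # both swap at 5
  r <- mota(gt, pred)
  expect_equal(r$IDSW, 2L)
  expect_equal(r$MOTA, 100 * (1 - 2 / 20))
})

test_that("IDF1 reflects the optimal identity bijection", {
  gt <- two_tracks(10)
  expect_equal(idf1(gt, gt)$IDF1, 100)
  # swap ids at T/2 -> 50
  pred <- gt
  pred$id <- ifelse(pred$frame < 5, pred$id, 3 - pred$id)
  expect_equal(idf1(gt, pred)$IDF1, 50)
  expect_equal(idf1(gt, gt[0, ])$IDF1, 0)
})

test_that("HOTA equals 100 only for perfect tracking and decomposes", {
  gt <- two_tracks(10)
  r <- hota(gt, gt)
  expect_equal(r$HOTA, 100); expect_equal(r$DetA, 100); expect_equal(r$AssA, 100)
  # detection-perfect midpoint swap: DetA stays 100, association drops
  pred <- gt
  pred$id <- ifelse(pred$frame < 5, pred$id, 3 - pred$id)
  r <- hota(gt, pred)
  expect_equal(r$DetA, 100)
  expect_lt(r$AssA, 100)
  expect_equal(r$HOTA_alpha, sqrt(r$DetA_alpha * r$AssA_alpha), tolerance = 1e-9)
  # the half-swap has pairwise overlap 5 of 10 frames: A = 5/15 per TP
  expect_equal(r$AssA, 100 / 3, tolerance = 1e-6)
  expect_equal(hota(gt, gt[0, ])$HOTA, 0)
})

test_that("tracking metrics agree with independent enumeration oracles", {
  for (seed in 1:50) {
    s <- random_tracking_sequence(seed, max_ids = 4, n_frames = 20)
    expect_equal(mota(s$gt, s$pred)$MOTA, oracle_mota(s$gt, s$pred),
                 tolerance = 0.1)
    expect_equal(idf1(s$gt, s$pred)$IDF1, oracle_idf1(s$gt, s$pred),
                 tolerance = 0.1)
  }
  for (seed in 1:20) {
    s <- random_tracking_sequence(seed + 100, max_ids = 3, n_frames = 10)
    expect_equal(hota(s$gt, s$pred)$HOTA, oracle_hota(s$gt, s$pred),
                 tolerance = 0.1)
  }
})

test_that("adding a false positive never improves the tracking metrics", {
  set.seed(30)
  for (k in 1:10) {
    s <- random_tracking_sequence(k + 500, max_ids = 3, n_frames = 15)
    base <- metric_report(s$gt, s$pred)
    fp_row <- data.frame(frame = sample(0:14, 1), id = 777L,
                         x = runif(1, 0, 350), y = runif(1, 0, 250),
                         w = 30, h = 30, class_id = 0L)
    worse <- metric_report(s$gt, rbind(s$pred, fp_row))
    expect_lte(worse$MOTA, base$MOTA + 1e-9)
    expect_lte(worse$IDF1, base$IDF1 + 1e-9)
    expect_lte(worse$HOTA, base$HOTA + 1e-9)
  }
})

test_that("average precision follows the COCO recipe", {
  gt <- data.frame(image_id = 1, x = c(0, 50), y = 0, w = 10, h = 10,
                   class_id = 0L)
  pred <- gt; pred$score <- 1
  r <- average_precision(gt, pred)
  expect_equal(r$mAP, 1); expect_equal(r$AP50, 1)

  # 1 GT, hit ranked above a miss -> AP50 = 1
  gt1 <- data.frame(image_id = 1, x = 0, y = 0, w = 10, h = 10, class_id = 0L)
  pred1 <- data.frame(image_id = 1, x = c(0, 40), y = 0, w = 10, h = 10,
                      class_id = 0L, score = c(0.9, 0.8))
  r <- average_precision(gt1, pred1)
  expect_equal(r$AP50, 1)

  # AP50 >= mAP, and order of the prediction table does not matter
  set.seed(31)
  gtr <- data.frame(image_id = rep(1:3, each = 3), x = runif(9, 0, 200),
                    y = runif(9, 0, 200), w = 20, h = 20, class_id = 0L)
  predr <- gtr
  predr$x <- predr$x + rnorm(9, 0, 6)
  predr$score <- runif(9)
  r <- average_precision(gtr, predr)
  expect_gte(r$AP50, r$mAP)
  shuf <- predr[sample(nrow(predr)), ]
  r2 <- average_precision(gtr, shuf)
  expect_equal(r2$mAP, r$mAP)
})

test_that("box and keypoint detection comparison follows the counting rules", {
  # box mode: P = R = 1 -> F1 = 1
  gtb <- list(matrix(c(0, 0, 10, 10), 1))
  r <- detection_compare(gtb, pred_boxes = gtb)
  expect_equal(r$F1, 1)
  # harmonic mean arithmetic: P = 0.6, R = 0.9 -> F1 = 0.72
  expect_equal(2 * 0.6 * 0.9 / (0.6 + 0.9), 0.72)
  # keypoint mode: box with 1 keypoint inside, 2 inside the 1.5x buffer
  skel <- list(list(cbind(c(10, 20), c(10, 20)))) # extent (10,10)-(20,20)
  kps <- list(list(cbind(c(12, 22), c(12, 22)))) # second point outside tight box
  tight <- detection_compare(gtb, pred_skeletons = skel, gt_keypoints = kps,
                             buffer_factor = 1)
  buffered <- detection_compare(gtb, pred_skeletons = skel, gt_keypoints = kps,
                                buffer_factor = 1.5)
  expect_equal(tight$precision, 0)
  expect_equal(buffered$precision, 1)
  expect_equal(buffered$recall, 1)
})

test_that("keypoint error uses the closest same-type ground truth", {
  gt <- data.frame(x = c(0, 0), y = c(0, 12), type = c("nose", "nose"))
  pred <- data.frame(x = 3, y = 4, type = "nose")
  r <- keypoint_rmse(pred, gt)
  expect_equal(r$errors, 5)
  expect_equal(r$median, 5)
  # exact predictions -> zero error
  r <- keypoint_rmse(gt, gt)
  expect_equal(r$errors, c(0, 0))
  # type mismatch yields NA, not a cross-type match
  pred2 <- data.frame(x = 0, y = 0, type = "tail")
  expect_true(is.na(keypoint_rmse(pred2, gt)$errors))
})

test_that("annotation consistency averages Hungarian-matched IoU over all boxes", {
  a <- list(matrix(c(0, 0, 2, 2), 1))
  b <- list(matrix(c(1, 1, 2, 2), 1))
  expect_equal(annotation_consistency(a, a), 1)
  expect_equal(annotation_consistency(a, b), 1 / 7)
  a2 <- list(rbind(c(0, 0, 2, 2), c(50, 50, 2, 2)))
  expect_equal(annotation_consistency(a2, b), (1 / 7) / 2)
  expect_error(annotation_consistency(list(matrix(numeric(0), 0, 4)),
                                      list(matrix(numeric(0), 0, 4))),
               "undefined")
})
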