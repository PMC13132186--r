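unit_vec <- function(v) v / sqrt(sum(v^2))

test_that("association cost combines appearance and location on one scale", {
  e1 <- unit_vec(c(1, 0)); e2 <- unit_vec(c(-1, 0))
  tr <- list(list(class_id = 0L, embedding = e1))
  # identical embedding and box -> cost 0
  d <- list(detection(box(0, 0, 10, 10), 0.9, embedding = e1))
  expect_equal(association_cost(tr, d, list(box(0, 0, 10, 10)), 0.5)[1, 1], 0)
  # opposite embeddings and disjoint boxes -> cost 1 for any lambda
  d <- list(detection(box(50, 50, 10, 10), 0.9, embedding = e2))
  for (lam in c(0, 0.3, 1)) {
    expect_equal(association_cost(tr, d, list(box(0, 0, 10, 10)), lam)[1, 1], 1)
  }
  # lambda = 0 reduces to location only: boxes with IoU 1/7 -> cost 6/7
  d <- list(detection(box(1, 1, 2, 2), 0.9))
  expect_equal(association_cost(tr, d, list(box(0, 0, 2, 2)), 0)[1, 1], 6 / 7)
  # class mismatch is unmatchable
  d <- list(detection(box(0, 0, 10, 10), 0.9, class_id = 1L, embedding = e1))
  expect_equal(association_cost(tr, d, list(box(0, 0, 10, 10)), 0.5)[1, 1], Inf)
  # missing embeddings with positive lambda is a configuration error
  d <- list(detection(box(0, 0, 10, 10), 0.9))
  expect_error(association_cost(tr, d, list(box(0, 0, 10, 10)), 0.5), "embedding")
})

test_that("cold start instantiates tracks with increasing ids", {
  dets <- list(detection(box(20, 20, 30, 30), 0.9),
               detection(box(200, 200, 30, 30), 0.9))
  tt <- track_video(list(dets), c(640, 480), tracker_config(appearance_weight = 0))
  expect_equal(sort(tt$id), c(1L, 2L))
  expect_equal(tt$frame, c(0L, 0L))
})

test_that("overlapping unmatched detections do not spawn new tracks", {
  cfg <- tracker_config(appearance_weight = 0, match_threshold = 0.3)
  d1 <- list(detection(box(100, 100, 40, 40), 0.9))
  # second frame: a detection overlapping the track (IoU 0.8) but with
  # association cost above the tight threshold would start a track -- the
  # overlap gate must suppress it
  shift <- 40 * (1 - 0.8) / (1 + 0.8) # axis offset giving IoU 0.8
  d2 <- list(detection(box(100, 100, 40, 40), 0.9),
             detection(box(100 + 4.45, 100, 40, 40), 0.9))
  tt <- track_video(list(d1, d2), c(640, 480), cfg)
  expect_equal(length(unique(tt$id)), 1L)
})

test_that("border-margin filter removes edge detections", {
  cfg <- tracker_config(appearance_weight = 0)
  dets <- list(detection(box(-10, 100, 20, 20), 0.9),  # center x = 0
               detection(box(100, 100, 20, 20), 0.9))
  tt <- track_video(list(dets), c(640, 480), cfg)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$x, 100)
})

test_that("detection score threshold is applied", {
  cfg <- tracker_config(appearance_weight = 0, det_threshold = 0.1)
  dets <- list(detection(box(100, 100, 20, 20), 0.05),
               detection(box(200, 200, 20, 20), 0.5))
  tt <- track_video(list(dets), c(640, 480), cfg)
  expect_equal(nrow(tt), 1L)
})

test_that("frame indices must increase strictly", {
  st <- tracker_init()
  st <- tracker_step(st, list(), 0L, c(100, 100), tracker_config())
  expect_error(tracker_step(st, list(), 0L, c(100, 100), tracker_config()),
               "strictly increasing")
})

test_that("perfect detections of separated targets give K clean tracks", {
  for (lam in c(0, 0.5, 1)) {
    protos <- diag(3)
    stream <- lapply(0:59, function(f) {
      lapply(1:3, function(i) {
        detection(box(50 + 150 * (i - 1) + 2 * f, 100 + 50 * (i - 1), 40, 40),
                  0.9, embedding = protos[i, ])
      })
    })
    tt <- track_video(stream, c(800, 400), tracker_config(appearance_weight = lam))
    expect_equal(length(unique(tt$id)), 3L)
    gt <- do.call(rbind, lapply(0:59, function(f) {
      data.frame(frame = f, id = 1:3, x = 50 + 150 * (0:2) + 2 * f,
                 y = 100 + 50 * (0:2), w = 40, h = 40, class_id = 0L)
    }))
    expect_equal(mota(gt, tt)$IDSW, 0L)
  }
})

test_that("tracking is deterministic", {
  scene <- simulate_scene(scene_config(n_individuals = 2, n_frames = 60, seed = 3))
  t1 <- track_video(scene$detections, scene$cfg$image_size, tracker_config())
  t2 <- track_video(scene$detections, scene$cfg$image_size, tracker_config())
  expect_identical(t1, t2)
})

test_that("appearance disambiguates crossing targets under lambda = 1", {
  # two targets crossing mid-sequence with orthogonal embeddings
  e <- list(c(1, 0), c(0, 1))
  stream <- lapply(0:40, function(f) {
    lapply(1:2, function(i) {
      x <- if (i == 1) 50 + 10 * f else 450 - 10 * f
      detection(box(x, 200, 40, 40), 0.9, embedding = e[[i]])
    })
  })
  gt <- do.call(rbind, lapply(0:40, function(f) {
    data.frame(frame = f, id = 1:2,
               x = c(50 + 10 * f, 450 - 10 * f), y = 200, w = 40, h = 40,
               class_id = 0L)
  }))
  tt <- track_video(stream, c(800, 400), tracker_config(appearance_weight = 1))
  expect_equal(length(unique(tt$id)), 2L)
  expect_equal(mota(gt, tt)$IDSW, 0L)
})

test_that("the second association stage rescues jump landings", {
  res <- jump_ab_experiment(2)
  expect_equal(res$switches_second_stage, 0L)
  expect_gte(res$switches_kf_only, 1L)
})

test_that("raising the detection threshold never adds false-positive tracks", {
  scene <- simulate_scene(scene_config(n_individuals = 2, n_frames = 80,
                                       fp_rate = 0.3, seed = 9))
  n_fp_tracks <- function(thr) {
    tt <- track_video(scene$detections, scene$cfg$image_size,
                      tracker_config(det_threshold = thr))
    # false-positive track: a predicted id never matching any GT box
    fp <- 0L
    for (id in unique(tt$id)) {
      rows <- tt[tt$id == id, ]
      hit <- FALSE
      for (r in seq_len(nrow(rows))) {
        g <- scene$gt[scene$gt$frame == rows$frame[r], , drop = FALSE]
        if (nrow(g) && max(iou_matrix(cbind(rows$x[r], rows$y[r], rows$w[r], rows$h[r]),
                                      boxes_of_df(g))) >= 0.5) {
          hit <- TRUE; break
        }
      }
      if (!hit) fp <- fp + 1L
    }
    fp
  }
  counts <- sapply(c(0.1, 0.3, 0.5, 0.7), n_fp_tracks)
  expect_true(all(diff(counts) <= 0))
})
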