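test_that("inference crops are exact for aligned square boxes", {
  set.seed(50)
  img <- array(runif(300 * 300 * 3), c(300, 300, 3))
  spec <- crop_spec(output_side = 224)
  crop <- crop_square(img, box(0, 0, 224, 224), spec, training = FALSE)
  expect_identical(crop, img[1:224, 1:224, ])
})

test_that("rectangular boxes are squared and off-image parts zero-padded", {
  img <- array(0.5, c(100, 100, 3))
  # box (0,0,10,20): square is (-5,0,20,20); the left 5 px are off-image
  crop <- crop_square(img, box(0, 0, 10, 20), crop_spec(output_side = 224))
  left_cols <- round(224 * 5 / 20) # 56 zero-padded columns
  expect_true(all(crop[, 1:(left_cols - 1), ] == 0))
  expect_true(all(crop[, (left_cols + 2):224, ] == 0.5))
  expect_error(crop_square(img, box(500, 500, 10, 10), crop_spec()),
               "outside the image")
})

test_that("degenerate augmentation equals the inference crop and is seeded", {
  img <- array(runif(80 * 80 * 3), c(80, 80, 3))
  b <- box(10, 20, 30, 18)
  spec0 <- crop_spec(output_side = 64, jitter_max = 0, zoom_max = 0)
  expect_identical(crop_square(img, b, spec0, training = TRUE),
                   crop_square(img, b, spec0, training = FALSE))
  spec <- crop_spec(output_side = 64)
  set.seed(1); c1 <- crop_square(img, b, spec, training = TRUE)
  set.seed(1); c2 <- crop_square(img, b, spec, training = TRUE)
  expect_identical(c1, c2)
  # augmentation only enlarges: zoomed crop covers at least the original box
  set.seed(2)
  c3 <- crop_square(img, b, spec, training = TRUE)
  expect_equal(dim(c3), c(64, 64, 3))
})

test_that("vote scores follow the exponential weighting arithmetic", {
  conf <- rbind(c(0.9, 0.05, 0.05),
                c(0.1, 0.5, 0.4), c(0.1, 0.5, 0.4), c(0.1, 0.5, 0.4))
  stream <- list(conf = conf)
  # beta = 0: plain summation -> identity 2 (0-based 1)
  r0 <- vote_track(stream, vote_config(beta = 0))
  expect_equal(r0$scores, c(1.2, 1.55, 1.25), tolerance = 1e-9)
  expect_equal(r0$identity, 2L)
  # beta = 5: the confident frame dominates -> identity 1 (0-based 0)
  r5 <- vote_track(stream, vote_config(beta = 5))
  expected <- exp(5 * 0.9) * conf[1, ] + exp(5 * 0.5) * colSums(conf[2:4, ])
  expect_equal(r5$scores, expected, tolerance = 1e-6)
  expect_equal(r5$identity, 1L)
  # single frame: argmax for any beta
  for (b in c(0, 1, 10)) {
    expect_equal(vote_track(list(conf = rbind(c(0.9, 0.05, 0.05))),
                            vote_config(beta = b))$identity, 1L)
  }
})

test_that("vote is frame-order invariant and respects unsure exclusion", {
  set.seed(51)
  conf <- matrix(runif(30), 10, 3)
  r1 <- vote_track(list(conf = conf), vote_config(beta = 2))
  r2 <- vote_track(list(conf = conf[sample(10), ]), vote_config(beta = 2))
  expect_equal(r1$scores, r2$scores, tolerance = 1e-12)

  uns <- list(conf = conf, unsure = rep(TRUE, 10))
  expect_error(vote_track(uns, vote_config()), "all frames excluded")
  r3 <- vote_track(uns, vote_config(beta = 2, exclude_unsure = FALSE))
  expect_equal(r3$scores, r1$scores)
})

test_that("raising beta never hurts the identity holding the best frame", {
  set.seed(52)
  for (k in 1:20) {
    conf <- matrix(runif(24), 8, 3)
    conf <- conf / rowSums(conf)
    star <- which.max(apply(conf, 1, max))
    star_id <- which.max(conf[star, ])
    shares <- sapply(c(0, 1, 2, 4, 8), function(b) {
      s <- vote_track(list(conf = conf), vote_config(beta = b))$scores
      s[star_id] / sum(s)
    })
    expect_true(all(diff(shares) >= -1e-9))
  }
})

test_that("track votes amplify a weak per-frame classifier", {
  sim <- make_confidence_streams(60, 4, 60, accuracy = 0.6, seed = 8)
  pred <- sapply(sim$streams, function(s) vote_track(s, vote_config())$identity)
  expect_gte(mean(pred == sim$truth), 0.95)
  # perfect frames -> perfect tracks
  sim1 <- make_confidence_streams(20, 3, 10, accuracy = 1, seed = 9)
  pred1 <- sapply(sim1$streams, function(s) vote_track(s, vote_config())$identity)
  expect_equal(mean(pred1 == sim1$truth), 1)
})

test_that("rendered identities are recovered track-by-track", {
  cfg <- scene_config(n_individuals = 3, image_size = c(320, 240), n_frames = 40,
                      body_size_range = c(30, 40), speed_range = c(2, 4),
                      occlusion_probability = 0, jump_probability = 0,
                      miss_rate = 0, fp_rate = 0, center_noise_sd = 0,
                      size_noise_sd = 0, seed = 12)
  scene <- simulate_scene(cfg)
  frames <- render_frames(scene)
  classifier <- color_classifier(identity_palette(3))
  # use ground truth as the trackset: gt ids are the identities by design
  res <- identify_tracks(scene$gt, frames, classifier,
                         crop_spec(output_side = 64), vote_config())
  expect_equal(nrow(res), 3)
  expect_false(any(res$abstained))
  expect_equal(res$identity, res$track_id)
})

test_that("tracks with only unsure frames abstain", {
  gray <- array(0.5, c(64, 64, 3))
  tt <- data.frame(frame = 0:4, id = 1L, x = 10, y = 10, w = 20, h = 20)
  res <- identify_tracks(tt, replicate(5, gray, simplify = FALSE),
                         color_classifier(identity_palette(3)),
                         crop_spec(output_side = 32), vote_config())
  expect_true(res$abstained)
  expect_true(is.na(res$identity))
})
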