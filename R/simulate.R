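# Seeded synthetic-scene generator. Emulates the hard parts of primate
# field video at toy scale: piecewise-linear motion with sudden jumps whose
# velocity drops to near zero on landing, temporary occlusions across which
# the ground-truth identity persists, detection noise (center/size jitter,
# misses, false positives) and identity-informative appearance embeddings
# with controllable separation.
#
# Jump kinematics: speed ramps linearly from the current locomotion speed
# to jump_magnitude times that speed over jump_duration frames (take-off
# acceleration a frame-to-frame tracker can follow), aimed roughly toward
# the image center so jumps stay in frame, and then drops instantly to zero
# on landing (the overshoot that defeats a pure constant-velocity
# predictor).

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Scene configuration
#'
#' @param n_individuals number of animals.
#' @param image_size `c(width, height)` px.
#' @param n_frames sequence length.
#' @param speed_range px/frame range of normal locomotion speed.
#' @param body_size_range px range of box side lengths.
#' @param segment_length_range frames between direction changes.
#' @param jump_probability per-frame chance (outside a jump) of starting a
#'   jump: one segment at `jump_magnitude` times the current speed, after
#'   which velocity drops to zero for `rest_duration` frames (the landing).
#' @param jump_magnitude speed multiplier during a jump.
#' @param jump_duration,rest_duration frames spent jumping / resting.
#' @param occlusion_probability per-frame chance of disappearing behind
#'   cover; the identity is kept across the gap.
#' @param occlusion_mean_duration mean occlusion length (frames).
#' @param center_noise_sd,size_noise_sd detection noise: Gaussian center
#'   jitter (px) and multiplicative size jitter.
#' @param miss_rate chance a visible animal yields no detection.
#' @param fp_rate expected spurious detections per frame (Poisson).
#' @param embed_dim embedding dimensionality.
#' @param embedding_noise_sd Gaussian noise added to the identity prototype
#'   before renormalization.
#' @param identity_angle angular separation (radians) of identity prototypes
#'   on the unit circle; `NULL` spaces them equally.
#' @param seed RNG seed; the whole scene is a pure function of the config.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(n_individuals = 3L, image_size = c(640L, 480L),
                         n_frames = 300L, speed_range = c(8, 14),
                         body_size_range = c(50, 70),
                         segment_length_range = c(30L, 60L),
                         jump_probability = 0.01, jump_magnitude = 4,
                         jump_duration = 3L, rest_duration = 6L,
                         occlusion_probability = 0.003,
                         occlusion_mean_duration = 6,
                         center_noise_sd = 1.0, size_noise_sd = 0.02,
                         miss_rate = 0.05, fp_rate = 0.05,
                         embed_dim = 8L, embedding_noise_sd = 0.3,
                         identity_angle = NULL, seed = 1L) {
  stopifnot(n_frames >= 1, n_individuals >= 1,
            jump_probability >= 0, jump_probability <= 1,
            occlusion_probability >= 0, occlusion_probability <= 1,
            miss_rate >= 0, miss_rate <= 1)
  structure(as.list(environment()), class = "scene_config")
}

identity_prototypes <- function(k, dim, angle = NULL) {
  if (is.null(angle)) angle <- 2 * pi / k
  proto <- matrix(0, k, dim)
  th <- (seq_len(k) - 1) * angle
  proto[, 1] <- cos(th)
  proto[, 2] <- sin(th)
  proto
}

#' Simulate a multi-animal scene
#'
#' Individuals follow piecewise-constant-velocity motion with reflecting
#' boundaries; jumps multiply the speed for a short segment and end in a
#' resting phase with near-zero velocity; occluded frames emit neither a
#' ground-truth row nor a detection, but the identity persists. Detections
#' derive from the ground truth through the configured noise model and carry
#' unit-norm embeddings drawn around per-identity prototypes.
#'
#' @param cfg a [scene_config()].
#' @return List with `gt` (track table), `detections` (per-frame detection
#'   lists), `events` (jump/occlusion log), `sizes`, `prototypes`, `cfg`.
#' @export
simulate_scene <- function(cfg) {
  with_seed(cfg$seed, {
    K <- cfg$n_individuals
    W <- cfg$image_size[1]; H <- cfg$image_size[2]
    proto <- identity_prototypes(K, cfg$embed_dim, cfg$identity_angle)
    sizes <- cbind(w = stats::runif(K, cfg$body_size_range[1], cfg$body_size_range[2]),
                   h = stats::runif(K, cfg$body_size_range[1], cfg$body_size_range[2]))
    margin <- apply(sizes, 1, max) / 2 + 10
    pos <- cbind(stats::runif(K, margin, W - margin),
                 stats::runif(K, margin, H - margin))
    new_heading <- function() {
      th <- stats::runif(1, 0, 2 * pi)
      c(cos(th), sin(th))
    }
    speed <- stats::runif(K, cfg$speed_range[1], cfg$speed_range[2])
    heading <- t(vapply(seq_len(K), function(i) new_heading(), numeric(2)))
    vel <- heading * speed
    seg_left <- round(stats::runif(K, cfg$segment_length_range[1],
                                   cfg$segment_length_range[2]))
    mode <- rep("normal", K)
    mode_left <- rep(0L, K)
    jump_t <- rep(0L, K)
    occl_left <- rep(0L, K)

    gt_rows <- vector("list", cfg$n_frames * K)
    det_stream <- vector("list", cfg$n_frames)
    events <- list()
    ri <- 0L
    for (f in seq_len(cfg$n_frames) - 1L) {
      dets <- list()
      for (i in seq_len(K)) {
        # motion state machine
        if (mode[i] == "normal") {
          if (seg_left[i] <= 0L) {
            heading[i, ] <- new_heading()
            speed[i] <- stats::runif(1, cfg$speed_range[1], cfg$speed_range[2])
            vel[i, ] <- heading[i, ] * speed[i]
            seg_left[i] <- round(stats::runif(1, cfg$segment_length_range[1],
                                              cfg$segment_length_range[2]))
          }
          if (stats::runif(1) < cfg$jump_probability) {
            mode[i] <- "jumping"
            mode_left[i] <- cfg$jump_duration
            jump_t[i] <- 0L
            # jump aimed toward the image center (+/- 45 deg) so the leap
            # stays inside the frame
            to_ctr <- atan2(H / 2 - pos[i, 2], W / 2 - pos[i, 1]) +
              stats::runif(1, -pi / 4, pi / 4)
            heading[i, ] <- c(cos(to_ctr), sin(to_ctr))
            events[[length(events) + 1L]] <-
              data.frame(type = "jump", id = i, frame = f,
                         duration = cfg$jump_duration)
          }
        }
        if (mode[i] == "jumping") {
          if (mode_left[i] <= 0L) {
            mode[i] <- "resting"
            mode_left[i] <- cfg$rest_duration
            vel[i, ] <- c(0, 0) # landing: velocity drops to (near) zero
          } else {
            jump_t[i] <- jump_t[i] + 1L
            ramp <- speed[i] +
              (cfg$jump_magnitude - 1) * speed[i] * jump_t[i] / cfg$jump_duration
            vel[i, ] <- heading[i, ] * ramp
          }
        } else if (mode[i] == "resting" && mode_left[i] <= 0L) {
          mode[i] <- "normal"
          heading[i, ] <- new_heading()
          speed[i] <- stats::runif(1, cfg$speed_range[1], cfg$speed_range[2])
          vel[i, ] <- heading[i, ] * speed[i]
          seg_left[i] <- round(stats::runif(1, cfg$segment_length_range[1],
                                            cfg$segment_length_range[2]))
        }
        pos[i, ] <- pos[i, ] + vel[i, ]
        # reflecting boundaries
        for (ax in 1:2) {
          lim <- c(W, H)[ax]
          if (pos[i, ax] < margin[i]) {
            pos[i, ax] <- 2 * margin[i] - pos[i, ax]; vel[i, ax] <- -vel[i, ax]
          } else if (pos[i, ax] > lim - margin[i]) {
            pos[i, ax] <- 2 * (lim - margin[i]) - pos[i, ax]
            vel[i, ax] <- -vel[i, ax]
          }
        }
        if (mode[i] != "normal") mode_left[i] <- mode_left[i] - 1L
        seg_left[i] <- seg_left[i] - 1L

        # occlusion state
        if (occl_left[i] > 0L) {
          occl_left[i] <- occl_left[i] - 1L
          next # occluded: no GT row, no detection, identity persists
        } else if (stats::runif(1) < cfg$occlusion_probability) {
          dur <- 1L + stats::rpois(1, max(cfg$occlusion_mean_duration - 1, 0))
          occl_left[i] <- dur
          events[[length(events) + 1L]] <-
            data.frame(type = "occlusion", id = i, frame = f, duration = dur)
          next
        }

        b <- box_from_center(pos[i, 1], pos[i, 2], sizes[i, 1], sizes[i, 2])
        ri <- ri + 1L
        gt_rows[[ri]] <- data.frame(frame = f, id = i, x = b[1], y = b[2],
                                    w = b[3], h = b[4], class_id = 0L)
        # detection noise model
        if (stats::runif(1) < cfg$miss_rate) next
        ctr <- pos[i, ] + stats::rnorm(2, 0, cfg$center_noise_sd)
        sz <- sizes[i, ] * pmax(0.2, 1 + stats::rnorm(2, 0, cfg$size_noise_sd))
        emb <- proto[i, ] + stats::rnorm(cfg$embed_dim, 0, cfg$embedding_noise_sd)
        score <- min(max(stats::rnorm(1, 0.85, 0.05), 0.3), 0.99)
        dets[[length(dets) + 1L]] <- detection(
          box_from_center(ctr[1], ctr[2], sz[1], sz[2]),
          score = score, class_id = 0L, embedding = emb)
      }
      # spurious detections
      nfp <- stats::rpois(1, cfg$fp_rate)
      for (k in seq_len(nfp)) {
        w <- stats::runif(1, 30, 80); h <- stats::runif(1, 30, 80)
        cx <- stats::runif(1, w / 2 + 6, W - w / 2 - 6)
        cy <- stats::runif(1, h / 2 + 6, H - h / 2 - 6)
        emb <- stats::rnorm(cfg$embed_dim)
        score <- min(max(stats::rnorm(1, 0.3, 0.1), 0.12), 0.6)
        dets[[length(dets) + 1L]] <- detection(
          box_from_center(cx, cy, w, h), score = score, class_id = 0L,
          embedding = emb)
      }
      det_stream[[f + 1L]] <- dets
    }
    gt <- do.call(rbind, gt_rows[seq_len(ri)])
    rownames(gt) <- NULL
    list(gt = gt, detections = det_stream,
         events = if (length(events)) do.call(rbind, events) else
           data.frame(type = character(0), id = integer(0),
                      frame = integer(0), duration = integer(0)),
         sizes = sizes, prototypes = proto, cfg = cfg)
  })
}

#' Scene preset isolating the jump-landing failure mode
#'
#' One animal, a large frame, noiseless and complete detections, no
#' occlusions, and frequent jumps: locomotion speed ramps up five-fold over
#' seven frames and drops to zero on landing, which makes a pure
#' constant-velocity predictor overshoot at the landing frame while the
#' location of the last detection still overlaps the animal.
#'
#' @param seed RNG seed.
#' @return A [scene_config()].
#' @export
jump_scene_config <- function(seed = 1L) {
  scene_config(n_individuals = 1L, image_size = c(1280L, 960L),
               n_frames = 100L, speed_range = c(10, 14),
               body_size_range = c(40, 50),
               segment_length_range = c(30L, 50L),
               jump_probability = 0.05, jump_magnitude = 5,
               jump_duration = 7L, rest_duration = 8L,
               occlusion_probability = 0, center_noise_sd = 0,
               size_noise_sd = 0, miss_rate = 0, fp_rate = 0,
               embedding_noise_sd = 0.1, seed = seed)
}

#' Identity switches with and without second-stage association
#'
#' Runs the tracker twice on the same simulated jump scene — once with the
#' conditional second association stage at the last detection, once with the
#' Kalman prediction only — and counts identity switches against ground
#' truth. Association is location-only (`appearance_weight = 0`) so the
#' experiment isolates the motion pathway.
#'
#' @param seed scene seed (see [jump_scene_config()]).
#' @return List with `switches_second_stage`, `switches_kf_only`.
#' @export
jump_ab_experiment <- function(seed) {
  scene <- simulate_scene(jump_scene_config(seed))
  base <- tracker_config(appearance_weight = 0)
  noss <- tracker_config(appearance_weight = 0, second_stage_enabled = FALSE)
  with_ss <- track_video(scene$detections, scene$cfg$image_size, base)
  without <- track_video(scene$detections, scene$cfg$image_size, noss)
  list(switches_second_stage = mota(scene$gt, with_ss)$IDSW,
       switches_kf_only = mota(scene$gt, without)$IDSW)
}

#' Color palette used for rendered identities
#'
#' Fully saturated, equally spaced hues; pairwise well separated in RGB for
#' any realistic group size.
#'
#' @param k number of identities.
#' @return k x 3 matrix of RGB values in `[0, 1]`.
#' @export
identity_palette <- function(k) {
  cols <- grDevices::hsv((seq_len(k) - 1) / k, 1, 1)
  t(grDevices::col2rgb(cols)) / 255
}

#' Render a simulated scene to RGB frames
#'
#' Each visible individual is drawn as a filled ellipse in its unique
#' identity color inside its ground-truth box, over a fixed grayscale noise
#' texture. The companion [blob_detector()] recovers these blobs.
#'
#' @param scene output of [simulate_scene()].
#' @return List of H x W x 3 arrays in `[0, 1]`, one per frame.
#' @export
render_frames <- function(scene) {
  cfg <- scene$cfg
  W <- cfg$image_size[1]; H <- cfg$image_size[2]
  pal <- identity_palette(cfg$n_individuals)
  texture <- with_seed(cfg$seed + 7919L,
                       matrix(stats::runif(H * W, 0.2, 0.45), H, W))
  frames <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames) - 1L) {
    img <- array(texture, c(H, W, 3))
    g <- scene$gt[scene$gt$frame == f, , drop = FALSE]
    for (r in seq_len(nrow(g))) {
      cx <- g$x[r] + g$w[r] / 2; cy <- g$y[r] + g$h[r] / 2
      rx <- g$w[r] / 2; ry <- g$h[r] / 2
      xs <- max(1, floor(g$x[r] + 1)):min(W, ceiling(g$x[r] + g$w[r]))
      ys <- max(1, floor(g$y[r] + 1)):min(H, ceiling(g$y[r] + g$h[r]))
      # pixel centers: column c covers x in [c-1, c], center c - 0.5
      dx2 <- ((xs - 0.5 - cx) / rx)^2
      dy2 <- ((ys - 0.5 - cy) / ry)^2
      inside <- outer(dy2, dx2, "+") <= 1
      col <- pal[g$id[r], ]
      for (ch in 1:3) {
        plane <- img[ys, xs, ch]
        plane[inside] <- col[ch]
        img[ys, xs, ch] <- plane
      }
    }
    frames[[f + 1L]] <- img
  }
  frames
}

#' Synthetic per-frame classifier confidence streams
#'
#' Test harness for the track-level identity vote: on each frame the true
#' identity receives the top confidence with probability `accuracy`,
#' otherwise a uniformly drawn imposter does; the winner's confidence is
#' drawn around `calibration` and the remainder is spread over the other
#' identities. A fraction of frames is flagged unsure.
#'
#' @param n_tracks number of tracks to synthesize.
#' @param n_identities size of the closed identity set.
#' @param frames_per_track frames per track.
#' @param accuracy per-frame probability the true identity wins.
#' @param calibration mean confidence of the per-frame winner.
#' @param unsure_fraction fraction of frames flagged unsure.
#' @param seed RNG seed.
#' @return List with `streams` (each a list `frames`, `conf`, `unsure`) and
#'   `truth` (true identity index per track, 1-based).
#' @export
make_confidence_streams <- function(n_tracks, n_identities, frames_per_track,
                                    accuracy, calibration = 0.7,
                                    unsure_fraction = 0, seed = 1L) {
  stopifnot(accuracy >= 0, accuracy <= 1, n_identities >= 2)
  with_seed(seed, {
    truth <- sample.int(n_identities, n_tracks, replace = TRUE)
    streams <- lapply(seq_len(n_tracks), function(t) {
      conf <- matrix(0, frames_per_track, n_identities)
      for (f in seq_len(frames_per_track)) {
        winner <- if (stats::runif(1) < accuracy) truth[t] else {
          sample(setdiff(seq_len(n_identities), truth[t]), 1)
        }
        c_w <- min(max(stats::rnorm(1, calibration, 0.08),
                       1 / n_identities + 0.05), 0.98)
        conf[f, ] <- (1 - c_w) / (n_identities - 1)
        conf[f, winner] <- c_w
      }
      list(frames = seq_len(frames_per_track) - 1L, conf = conf,
           unsure = stats::runif(frames_per_track) < unsure_fraction)
    })
    list(streams = streams, truth = truth)
  })
}
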