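# Two-stage multi-animal tracker. Per frame: low-threshold detection
# filtering, image-border suppression, Kalman prediction, Hungarian
# association on a single linear combination of appearance and location
# similarity, a conditional second association pass at the location of each
# track's last detection (rescues fast stop-after-jump motion the
# constant-velocity filter overshoots), overlap-gated track birth, and an
# age-based track death rule.

#' Tracker configuration
#'
#' All thresholds the tracker uses. Defaults reflect primate-adapted
#' tracking: a deliberately low detection threshold keeps tracks alive
#' through motion blur, and the false positives that invites are controlled
#' by the border filter and the new-track overlap gate rather than by a high
#' score cut.
#'
#' @param det_threshold minimum detection score (default 0.1, intentionally
#'   low).
#' @param appearance_weight weight `lambda` of the appearance term in the
#'   association cost; `1 - lambda` weighs location. Primates show little
#'   inter-individual appearance variation, so location and appearance are
#'   balanced by default.
#' @param match_threshold association cost ceiling above which a pair is left
#'   unmatched.
#' @param second_stage_enabled if `TRUE`, tracks and detections left over
#'   from the Kalman-predicted association get a second chance at the
#'   location of the track's last detection.
#' @param new_track_overlap_max an unmatched detection starts a new track
#'   only if its IoU with every surviving track is at most this.
#' @param border_margin detections whose box center lies strictly closer
#'   than this many pixels to an image border are discarded.
#' @param max_age frames a track survives without a match before removal.
#' @param embedding_momentum EMA factor for smoothing track appearance
#'   embeddings.
#' @return List of class `tracker_config`.
#' @export
tracker_config <- function(det_threshold = 0.1,
                           appearance_weight = 0.5,
                           match_threshold = 0.8,
                           second_stage_enabled = TRUE,
                           new_track_overlap_max = 0.5,
                           border_margin = 5,
                           max_age = 30L,
                           embedding_momentum = 0.9) {
  unit <- c(det_threshold = det_threshold, appearance_weight = appearance_weight,
            match_threshold = match_threshold,
            new_track_overlap_max = new_track_overlap_max,
            embedding_momentum = embedding_momentum)
  if (any(unit < 0 | unit > 1)) {
    stop("tracker_config: ", paste(names(unit)[unit < 0 | unit > 1], collapse = ", "),
         " must lie in [0, 1]")
  }
  if (border_margin < 0) stop("border_margin must be >= 0")
  if (max_age < 1) stop("max_age must be >= 1")
  structure(list(det_threshold = det_threshold,
                 appearance_weight = appearance_weight,
                 match_threshold = match_threshold,
                 second_stage_enabled = isTRUE(second_stage_enabled),
                 new_track_overlap_max = new_track_overlap_max,
                 border_margin = border_margin,
                 max_age = as.integer(max_age),
                 embedding_momentum = embedding_momentum),
            class = "tracker_config")
}

#' Joint appearance/location association cost
#'
#' `cost[i, j] = lambda * (1 - <e_i, e_j>) / 2 + (1 - lambda) * (1 - IoU)`,
#' a single linear combination of cosine distance (halved so it shares the
#' `[0, 1]` range of the IoU term) and location dissimilarity. Pairs with
#' mismatched classes are unmatchable (`Inf`): a lemur is never associated
#' with a feeding box.
#'
#' @param tracks list of track records (need `$embedding`, `$class_id`).
#' @param dets list of detections.
#' @param location_boxes one box per track: the Kalman-predicted box in
#'   stage 1, the last detection box in stage 2.
#' @param lambda appearance weight in `[0, 1]`.
#' @return `length(tracks)` x `length(dets)` cost matrix in `[0, 1]`
#'   (or `Inf`).
#' @export
association_cost <- function(tracks, dets, location_boxes, lambda) {
  n <- length(tracks); m <- length(dets)
  cost <- matrix(Inf, n, m)
  if (n == 0L || m == 0L) return(cost)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (tracks[[i]]$class_id != dets[[j]]$class_id) next
      loc <- 1 - iou(location_boxes[[i]], dets[[j]]$box)
      if (lambda > 0) {
        ei <- tracks[[i]]$embedding; ej <- dets[[j]]$embedding
        if (is.null(ei) || is.null(ej)) {
          stop("appearance_weight > 0 but embeddings are missing")
        }
        app <- (1 - sum(ei * ej)) / 2
      } else {
        app <- 0
      }
      cost[i, j] <- lambda * app + (1 - lambda) * loc
    }
  }
  cost
}

#' Create an empty tracker state
#'
#' @return List with `tracks` (all tracks ever created, including removed
#'   ones so ids are never reused), `next_id` and `last_frame`.
#' @export
tracker_init <- function() {
  list(tracks = list(), next_id = 1L, last_frame = -1L)
}

new_track <- function(id, d, frame_index) {
  list(track_id = id, class_id = d$class_id, status = "active",
       kf = kf_init(d), last_box = d$box, embedding = d$embedding,
       frames_since_update = 0L, start_frame = frame_index,
       end_frame = frame_index, last_score = d$score)
}

apply_match <- function(tr, d, frame_index, cfg) {
  tr$kf <- kf_update(tr$kf, d)
  if (!is.null(tr$embedding) && !is.null(d$embedding)) {
    e <- cfg$embedding_momentum * tr$embedding +
      (1 - cfg$embedding_momentum) * d$embedding
    tr$embedding <- e / sqrt(sum(e^2))
  } else if (is.null(tr$embedding)) {
    tr$embedding <- d$embedding
  }
  tr$status <- "active"
  tr$frames_since_update <- 0L
  tr$last_box <- d$box
  tr$last_score <- d$score
  tr$end_frame <- frame_index
  tr
}

#' Advance the tracker by one frame
#'
#' Runs the full per-frame pipeline: score filter, border filter, Kalman
#' prediction, stage-1 association at the predicted boxes, optional stage-2
#' association at the last detection boxes, lifecycle bookkeeping and
#' overlap-gated track creation.
#'
#' @param state tracker state from [tracker_init()] or a previous step.
#' @param dets list of detections for this frame.
#' @param frame_index 0-based frame index, strictly increasing across calls.
#' @param image_size `c(width, height)` in pixels.
#' @param cfg a [tracker_config()].
#' @return Updated state, with `state$records` holding this frame's output
#'   rows (frame, id, box, score, class).
#' @export
tracker_step <- function(state, dets, frame_index, image_size, cfg) {
  if (frame_index <= state$last_frame) {
    stop("frame_index must be strictly increasing across tracker_step calls")
  }
  state$last_frame <- frame_index

  # (1) score filter, (2) border filter on the box center
  keep <- vapply(dets, function(d) d$score >= cfg$det_threshold, TRUE)
  dets <- dets[keep]
  if (cfg$border_margin > 0 && length(dets) > 0) {
    keep <- vapply(dets, function(d) {
      ctr <- box_center(d$box)
      min(ctr[1], image_size[1] - ctr[1], ctr[2], image_size[2] - ctr[2]) >=
        cfg$border_margin
    }, TRUE)
    dets <- dets[keep]
  }

  live <- which(vapply(state$tracks, function(t) t$status != "removed", TRUE))
  # (3) predict
  for (i in live) state$tracks[[i]]$kf <- kf_predict(state$tracks[[i]]$kf)

  matched_tracks <- integer(0)
  det_matched <- rep(FALSE, length(dets))
  lam <- cfg$appearance_weight

  run_stage <- function(track_idx, det_idx, boxes) {
    cost <- association_cost(state$tracks[track_idx], dets[det_idx], boxes, lam)
    hungarian_match(cost, cfg$match_threshold)
  }

  # (4) stage 1: association at the Kalman-predicted boxes
  if (length(live) > 0 && length(dets) > 0) {
    pred_boxes <- lapply(state$tracks[live], function(t) kf_box(t$kf))
    res <- run_stage(live, seq_along(dets), pred_boxes)
    for (k in seq_len(nrow(res$matches))) {
      ti <- live[res$matches[k, 1]]; dj <- res$matches[k, 2]
      state$tracks[[ti]] <- apply_match(state$tracks[[ti]], dets[[dj]],
                                        frame_index, cfg)
      matched_tracks <- c(matched_tracks, ti)
      det_matched[dj] <- TRUE
    }
    left_tracks <- live[res$unmatched_rows]
    left_dets <- res$unmatched_cols
  } else {
    left_tracks <- live
    left_dets <- seq_along(dets)
  }

  # (5) stage 2: leftovers retried at the last detection box
  if (cfg$second_stage_enabled && length(left_tracks) > 0 && length(left_dets) > 0) {
    last_boxes <- lapply(state$tracks[left_tracks], function(t) t$last_box)
    res2 <- run_stage(left_tracks, left_dets, last_boxes)
    for (k in seq_len(nrow(res2$matches))) {
      ti <- left_tracks[res2$matches[k, 1]]
      dj <- left_dets[res2$matches[k, 2]]
      state$tracks[[ti]] <- apply_match(state$tracks[[ti]], dets[[dj]],
                                        frame_index, cfg)
      matched_tracks <- c(matched_tracks, ti)
      det_matched[dj] <- TRUE
    }
    left_tracks <- left_tracks[res2$unmatched_rows]
  }

  # (6) unmatched tracks age and eventually die
  for (i in left_tracks) {
    tr <- state$tracks[[i]]
    tr$frames_since_update <- tr$frames_since_update + 1L
    tr$status <- if (tr$frames_since_update > cfg$max_age) "removed" else "lost"
    state$tracks[[i]] <- tr
  }

  # (7) overlap-gated track birth from unmatched detections
  survivors <- which(vapply(state$tracks, function(t) t$status != "removed", TRUE))
  survivor_boxes <- lapply(survivors, function(i) {
    tr <- state$tracks[[i]]
    if (tr$frames_since_update == 0L) tr$last_box else kf_box(tr$kf)
  })
  new_rows <- list()
  for (j in which(!det_matched)) {
    d <- dets[[j]]
    blocked <- FALSE
    for (bx in survivor_boxes) {
      if (iou(bx, d$box) > cfg$new_track_overlap_max) { blocked <- TRUE; break }
    }
    if (blocked) next
    tr <- new_track(state$next_id, d, frame_index)
    state$tracks[[length(state$tracks) + 1L]] <- tr
    state$next_id <- state$next_id + 1L
    matched_tracks <- c(matched_tracks, length(state$tracks))
  }

  # output rows for every track updated or created this frame
  recs <- lapply(sort(matched_tracks), function(i) {
    tr <- state$tracks[[i]]
    data.frame(frame = frame_index, id = tr$track_id,
               x = tr$last_box[1], y = tr$last_box[2],
               w = tr$last_box[3], h = tr$last_box[4],
               score = tr$last_score, class_id = tr$class_id)
  })
  state$records <- if (length(recs)) do.call(rbind, recs) else empty_trackset()
  state
}

empty_trackset <- function() {
  data.frame(frame = integer(0), id = integer(0), x = numeric(0),
             y = numeric(0), w = numeric(0), h = numeric(0),
             score = numeric(0), class_id = integer(0))
}

#' Track a whole detection stream
#'
#' Folds [tracker_step()] over per-frame detection lists and collects the
#' resulting track table. Deterministic: identical inputs and configuration
#' give an identical table.
#'
#' @param det_stream list of per-frame detection lists, frame 0 first.
#' @param image_size `c(width, height)` in pixels.
#' @param cfg a [tracker_config()].
#' @return Track table (`data.frame`) with columns
#'   `frame, id, x, y, w, h, score, class_id`, one row per track per frame
#'   in which it was matched (0-based frames).
#' @export
track_video <- function(det_stream, image_size, cfg = tracker_config()) {
  state <- tracker_init()
  out <- vector("list", length(det_stream))
  for (f in seq_along(det_stream)) {
    state <- tracker_step(state, det_stream[[f]], f - 1L, image_size, cfg)
    out[[f]] <- state$records
  }
  res <- do.call(rbind, c(out, list(empty_trackset())))
  rownames(res) <- NULL
  res
}
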