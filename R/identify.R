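# Track-level individual identification: square-crop preparation with the
# training-time jitter/zoom augmentation contract, a pluggable per-frame
# classifier, and the exponentially weighted confidence majority vote that
# turns noisy per-frame identifications into a single track-level decision.

#' Crop specification
#'
#' @param output_side output crop side length (px).
#' @param jitter_max training-time uniform integer box translation, per axis
#'   (px).
#' @param zoom_max training-time maximum relative enlargement of width and
#'   height (e.g. 0.20 = up to 20%); enlargement only.
#' @return List of class `crop_spec`.
#' @export
crop_spec <- function(output_side = 224L, jitter_max = 5L, zoom_max = 0.20) {
  stopifnot(output_side > 0, jitter_max >= 0, zoom_max >= 0)
  structure(list(output_side = as.integer(output_side),
                 jitter_max = as.integer(jitter_max), zoom_max = zoom_max),
            class = "crop_spec")
}

#' Square crop of a box region
#'
#' The box is squared with [square_box()] (shorter side grown to the longer,
#' so the animal is never squeezed) and the region resampled to
#' `output_side` x `output_side` by nearest neighbor; parts outside the
#' image are zero-padded. With `training = TRUE` the box is first jittered
#' by up to `jitter_max` px per axis and enlarged by independent factors up
#' to `1 + zoom_max`, then re-squared — the augmentation applied when
#' training an identification network on annotated boxes; inference crops
#' (`training = FALSE`) are deterministic.
#'
#' @param image H x W x 3 numeric array.
#' @param b a [box()] intersecting the image.
#' @param spec a [crop_spec()].
#' @param training apply jitter/zoom augmentation.
#' @return `output_side` x `output_side` x 3 array.
#' @export
crop_square <- function(image, b, spec = crop_spec(), training = FALSE) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (b[1] + b[3] <= 0 || b[1] >= W || b[2] + b[4] <= 0 || b[2] >= H) {
    stop("empty crop: box lies fully outside the image")
  }
  if (training) {
    jx <- sample(-spec$jitter_max:spec$jitter_max, 1)
    jy <- sample(-spec$jitter_max:spec$jitter_max, 1)
    zx <- stats::runif(1, 1, 1 + spec$zoom_max)
    zy <- stats::runif(1, 1, 1 + spec$zoom_max)
    cx <- b[1] + b[3] / 2 + jx
    cy <- b[2] + b[4] / 2 + jy
    b <- box_from_center(cx, cy, b[3] * zx, b[4] * zy)
  }
  s <- square_box(b)
  side <- spec$output_side
  # nearest-neighbor sample of the square region, zero-padded off-image
  sx <- s[1] + (seq_len(side) - 0.5) * s[3] / side
  sy <- s[2] + (seq_len(side) - 0.5) * s[4] / side
  ci <- floor(sx) + 1
  ri <- floor(sy) + 1
  cv <- ci >= 1 & ci <= W
  rv <- ri >= 1 & ri <= H
  out <- array(0, c(side, side, 3))
  if (any(rv) && any(cv)) {
    out[rv, cv, ] <- image[ri[rv], ci[cv], , drop = FALSE]
  }
  out
}

#' Toy color-histogram identity classifier
#'
#' Reference classifier for tests and demos: the mean RGB of the crop's
#' saturated foreground pixels is compared to per-identity prototype colors
#' and converted to confidences by a softmax over negative distances. Crops
#' without enough foreground are flagged unsure with a near-uniform vector.
#'
#' @param prototypes K x 3 matrix of identity RGB prototypes in `[0, 1]`
#'   (e.g. [identity_palette()]).
#' @param sat_threshold minimum (max - min) channel difference for a
#'   foreground pixel.
#' @param temperature softmax sharpness.
#' @param min_pixels fewer foreground pixels than this flags the frame
#'   unsure.
#' @return A classifier function `crop -> confidence vector` (attribute
#'   `unsure` set when identification was impossible).
#' @export
color_classifier <- function(prototypes, sat_threshold = 0.25,
                             temperature = 12, min_pixels = 20L) {
  k <- nrow(prototypes)
  function(crop) {
    r <- crop[, , 1]; g <- crop[, , 2]; b <- crop[, , 3]
    fg <- (pmax(r, g, b) - pmin(r, g, b)) > sat_threshold
    if (sum(fg) < min_pixels) {
      conf <- rep(1 / k, k)
      attr(conf, "unsure") <- TRUE
      return(conf)
    }
    mu <- c(mean(r[fg]), mean(g[fg]), mean(b[fg]))
    d <- sqrt(rowSums((prototypes - matrix(mu, k, 3, byrow = TRUE))^2))
    e <- exp(-temperature * d)
    conf <- e / sum(e)
    attr(conf, "unsure") <- FALSE
    conf
  }
}

#' Vote configuration
#'
#' @param beta exponential sharpening of the per-frame weight
#'   `exp(beta * max confidence)`; `beta = 0` recovers plain confidence
#'   summation.
#' @param exclude_unsure drop frames flagged unsure from the vote.
#' @return List of class `vote_config`.
#' @export
vote_config <- function(beta = 4, exclude_unsure = TRUE) {
  stopifnot(beta >= 0)
  structure(list(beta = beta, exclude_unsure = isTRUE(exclude_unsure)),
            class = "vote_config")
}

#' Exponentially weighted confidence majority vote over a track
#'
#' With `c_t` the frame-`t` confidence vector and `m_t = max_k c_t[k]`, the
#' per-identity score is `s_k = sum_t exp(beta * m_t) * c_t[k]` over
#' non-excluded frames and the track identity is `argmax_k s_k`. Confident
#' frames dominate the vote; frames where no decision was possible barely
#' contribute. Ties break to the lowest index and are flagged.
#'
#' @param stream list with `conf` (frames x K confidence matrix, rows
#'   summing to at most 1) and optional `unsure` logical vector.
#' @param cfg a [vote_config()].
#' @return List with `identity` (1-based index), `scores` (length K) and
#'   `tie`.
#' @export
vote_track <- function(stream, cfg = vote_config()) {
  conf <- stream$conf
  if (is.null(dim(conf))) conf <- matrix(conf, nrow = 1)
  keep <- rep(TRUE, nrow(conf))
  if (cfg$exclude_unsure && !is.null(stream$unsure)) keep <- !stream$unsure
  if (!any(keep)) stop("no frames left to vote on: all frames excluded")
  conf <- conf[keep, , drop = FALSE]
  m <- apply(conf, 1, max)
  w <- exp(cfg$beta * m)
  scores <- colSums(conf * w)
  best <- max(scores)
  winners <- which(scores >= best - 1e-12)
  list(identity = winners[1], scores = scores, tie = length(winners) > 1)
}

#' Identify all tracks of a video
#'
#' Runs the classifier on a deterministic square crop of every track frame,
#' assembles the per-track confidence streams and applies [vote_track()].
#' Tracks whose frames are all flagged unsure abstain (identity `NA`).
#'
#' @param trackset track table (`frame, id, x, y, w, h, ...`), 0-based
#'   frames.
#' @param frames list of H x W x 3 arrays, frame 0 first.
#' @param classifier function `crop -> confidence vector` (optionally with
#'   an `unsure` attribute), e.g. [color_classifier()].
#' @param spec a [crop_spec()].
#' @param cfg a [vote_config()].
#' @return data.frame with one row per track: `track_id`, `identity`
#'   (1-based, `NA` when abstained), `n_frames_voted`, `abstained`, and the
#'   per-identity vote scores `score.1..score.K`.
#' @export
identify_tracks <- function(trackset, frames, classifier,
                            spec = crop_spec(), cfg = vote_config()) {
  ids <- sort(unique(trackset$id))
  rows <- lapply(ids, function(tid) {
    tt <- trackset[trackset$id == tid, , drop = FALSE]
    confs <- list(); unsure <- logical(0)
    for (r in seq_len(nrow(tt))) {
      img <- frames[[tt$frame[r] + 1L]]
      crop <- crop_square(img, box(tt$x[r], tt$y[r], tt$w[r], tt$h[r]),
                          spec, training = FALSE)
      cf <- classifier(crop)
      confs[[length(confs) + 1L]] <- as.numeric(cf)
      unsure <- c(unsure, isTRUE(attr(cf, "unsure")))
    }
    conf <- do.call(rbind, confs)
    stream <- list(frames = tt$frame, conf = conf, unsure = unsure)
    voted <- if (cfg$exclude_unsure && all(unsure)) NULL else vote_track(stream, cfg)
    k <- ncol(conf)
    scores <- if (is.null(voted)) rep(NA_real_, k) else voted$scores
    data.frame(track_id = tid,
               identity = if (is.null(voted)) NA_integer_ else voted$identity,
               n_frames_voted = if (is.null(voted)) 0L else sum(!unsure | !cfg$exclude_unsure),
               abstained = is.null(voted),
               t(stats::setNames(scores, paste0("score.", seq_len(k)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
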