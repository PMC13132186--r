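# Detection records and the detector seam: a "detector" is any function
# (frame, frame_index) -> list of detections, so a CNN wrapper, a file-backed
# playback and the synthetic blob detector are interchangeable. The decoding
# of center-point head outputs (heatmap / size / offset / embedding) into
# detections lives here too.

#' Construct a detection
#'
#' @param box box `c(x, y, w, h)`.
#' @param score confidence in `[0, 1]`.
#' @param class_id small non-negative integer class label (e.g. 0 = primate,
#'   1 = feeding box).
#' @param embedding optional appearance vector; stored L2-normalized.
#' @return A `list` with elements `box`, `score`, `class_id`, `embedding`.
#' @export
detection <- function(box, score, class_id = 0L, embedding = NULL) {
  if (score < 0 || score > 1) stop("detection score must lie in [0, 1]")
  if (box[3] < 0 || box[4] < 0) stop("detection box must have non-negative size")
  if (!is.null(embedding)) {
    nrm <- sqrt(sum(embedding^2))
    if (nrm == 0) stop("detection embedding must be non-zero")
    embedding <- embedding / nrm
  }
  list(box = box, score = as.numeric(score), class_id = as.integer(class_id),
       embedding = embedding)
}

#' Decode center-point head outputs into detections
#'
#' Detections are placed at strict local maxima of the per-class heatmap
#' (a cell must dominate its 8 neighbors; on exact ties the lexicographically
#' smallest (row, column) cell of the plateau wins, for determinism). The
#' box center is `(cell + offset) * stride`, the box size is read from the
#' size map at the peak cell, and the appearance embedding is the
#' L2-normalized embedding-map column there.
#'
#' @param heads list with `heatmap` (H x W x C array, values in `[0, 1]`;
#'   an H x W matrix is treated as C = 1), `size_map` (H x W x 2: width,
#'   height in input pixels), `offset_map` (H x W x 2: sub-cell x/y center
#'   correction; optional, defaults to 0), `embed_map` (H x W x D, optional)
#'   and `stride` (output-to-input scale).
#' @param det_threshold minimum heatmap score to keep a peak.
#' @param max_per_frame cap on detections per class, highest scores first.
#' @return List of detections ordered by decreasing score.
#' @export
decode_detections <- function(heads, det_threshold, max_per_frame = 100L) {
  hm <- heads$heatmap
  if (length(dim(hm)) == 2L) hm <- array(hm, c(dim(hm), 1L))
  hdim <- dim(hm)[1:2]
  check_map <- function(m, d3, name) {
    if (!is.null(m) && !identical(dim(m)[1:2], hdim)) {
      stop(sprintf("%s shape does not match heatmap", name))
    }
    if (!is.null(m) && dim(m)[3] != d3) stop(sprintf("%s has wrong depth", name))
  }
  check_map(heads$size_map, 2L, "size_map")
  check_map(heads$offset_map, 2L, "offset_map")
  if (!is.null(heads$embed_map) &&
      !identical(dim(heads$embed_map)[1:2], hdim)) {
    stop("embed_map shape does not match heatmap")
  }
  stride <- heads$stride
  H <- hdim[1]; W <- hdim[2]
  dets <- list()
  for (cls in seq_len(dim(hm)[3])) {
    plane <- hm[, , cls, drop = TRUE]
    if (!is.matrix(plane)) plane <- matrix(plane, H, W)
    cand <- which(plane >= det_threshold, arr.ind = TRUE)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; ci <- cand[k, 2]
      v <- plane[r, ci]
      ok <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- ci + dc
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        vn <- plane[rr, cc]
        if (vn > v || (vn == v && (rr < r || (rr == r && cc < ci)))) {
          ok <- FALSE
        }
      }
      keep[k] <- ok
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) next
    scores <- plane[cand]
    ord <- order(-scores, cand[, 1], cand[, 2])
    ord <- ord[seq_len(min(length(ord), max_per_frame))]
    for (k in ord) {
      r <- cand[k, 1]; ci <- cand[k, 2]
      off <- if (is.null(heads$offset_map)) c(0, 0) else heads$offset_map[r, ci, ]
      cx <- (ci - 1 + off[1]) * stride
      cy <- (r - 1 + off[2]) * stride
      sz <- heads$size_map[r, ci, ]
      emb <- if (is.null(heads$embed_map)) NULL else as.numeric(heads$embed_map[r, ci, ])
      dets[[length(dets) + 1L]] <- detection(
        box_from_center(cx, cy, sz[1], sz[2]),
        score = plane[r, ci], class_id = cls - 1L, embedding = emb)
    }
  }
  if (length(dets) > 1L) dets <- dets[order(-vapply(dets, `[[`, 0, "score"))]
  dets
}

#' File-backed playback detector
#'
#' Wraps a pre-computed per-frame detection stream as a detector function, so
#' saved detections can be replayed through the tracking pipeline exactly.
#'
#' @param det_stream list of per-frame detection lists (frame 0 first).
#' @return A function `(frame, frame_index)` returning the stored detections
#'   for `frame_index` (0-based).
#' @export
playback_detector <- function(det_stream) {
  function(frame, frame_index) {
    if (frame_index + 1L > length(det_stream)) return(list())
    det_stream[[frame_index + 1L]]
  }
}

#' Synthetic color-blob detector
#'
#' Companion to [render_frames()]: finds saturated color blobs on a grayscale
#' textured background by grouping foreground pixels (saturation above
#' `sat_threshold`) into hue bins and taking the bounding box of each group.
#' Rendered individuals have flat, fully saturated, well-separated hues, so
#' each blob maps to exactly one bin.
#'
#' @param sat_threshold minimum (max - min) channel difference for a pixel to
#'   count as foreground.
#' @param min_pixels discard hue groups smaller than this.
#' @param n_bins number of hue bins.
#' @return A detector function `(frame, frame_index) -> list of detections`.
#' @export
blob_detector <- function(sat_threshold = 0.25, min_pixels = 30L, n_bins = 24L) {
  function(frame, frame_index = 0L) {
    r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
    mx <- pmax(r, g, b); mn <- pmin(r, g, b)
    fg <- which(mx - mn > sat_threshold)
    if (length(fg) == 0L) return(list())
    # hue in [0,1) from the RGB max channel
    d <- (mx - mn)[fg]
    hue <- numeric(length(fg))
    rm <- r[fg] == mx[fg]; gm <- !rm & g[fg] == mx[fg]; bm <- !rm & !gm
    hue[rm] <- ((g[fg][rm] - b[fg][rm]) / d[rm]) %% 6
    hue[gm] <- (b[fg][gm] - r[fg][gm]) / d[gm] + 2
    hue[bm] <- (r[fg][bm] - g[fg][bm]) / d[bm] + 4
    hue <- hue / 6
    bin <- pmin(floor(hue * n_bins + 1e-9), n_bins - 1)
    rows <- ((fg - 1) %% nrow(frame)) + 1
    cols <- ((fg - 1) %/% nrow(frame)) + 1
    dets <- list()
    for (bb in sort(unique(bin))) {
      sel <- bin == bb
      if (sum(sel) < min_pixels) next
      x0 <- min(cols[sel]) - 1; x1 <- max(cols[sel])
      y0 <- min(rows[sel]) - 1; y1 <- max(rows[sel])
      dets[[length(dets) + 1L]] <- detection(
        box(x0, y0, x1 - x0, y1 - y0), score = 0.9, class_id = 0L)
    }
    dets
  }
}
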