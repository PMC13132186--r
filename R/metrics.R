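# Evaluation suite: Hungarian frame matching, MOTA, IDF1, HOTA (reference
# definition averaged over 19 IoU thresholds), COCO-style mAP/AP50, the
# box-versus-keypoint detection comparison, keypoint RMSE and
# inter-annotator consistency QC.
#
# Ground truth and predictions are data.frames with columns
# frame (0-based), id, x, y, w, h, class_id (predictions also carry score).
# Occluded individuals simply have no row for the occluded frames and keep
# their id when they reappear.

boxes_of <- function(df) {
  m <- as.matrix(df[, c("x", "y", "w", "h"), drop = FALSE])
  dimnames(m) <- NULL
  m
}

class_of <- function(df) {
  if ("class_id" %in% names(df)) df$class_id else rep(0L, nrow(df))
}

# IoU gated to 0 across classes: boxes of different classes never match.
class_gated_iou <- function(gt, pr) {
  sim <- iou_matrix(boxes_of(gt), boxes_of(pr))
  cg <- class_of(gt); cp <- class_of(pr)
  if (length(cg) && length(cp)) {
    sim[outer(cg, cp, "!=")] <- 0
  }
  sim
}

#' Hungarian matching of one frame's boxes
#'
#' Maximizes total IoU over pairs whose IoU reaches `iou_threshold` (and
#' whose classes agree).
#'
#' @param gt,pred data.frames with columns `x, y, w, h` (optional
#'   `class_id`) for a single frame.
#' @param iou_threshold minimum IoU for a pair to be matchable.
#' @return List with `matches` (columns gt, pred, iou), `unmatched_gt`,
#'   `unmatched_pred` (row indices).
#' @export
frame_match <- function(gt, pred, iou_threshold = 0.5) {
  sim <- class_gated_iou(gt, pred)
  cost <- 1 - sim
  cost[sim < iou_threshold] <- Inf
  res <- hungarian_match(cost, match_threshold = Inf)
  mm <- res$matches
  ious <- if (nrow(mm)) sim[mm] else numeric(0)
  list(matches = cbind(gt = mm[, 1], pred = mm[, 2], iou = ious),
       unmatched_gt = res$unmatched_rows,
       unmatched_pred = res$unmatched_cols)
}

split_frames <- function(df, frames) {
  lapply(frames, function(f) df[df$frame == f, , drop = FALSE])
}

seq_frames <- function(gt, pred) sort(unique(c(gt$frame, pred$frame)))

#' Multi-Object Tracking Accuracy
#'
#' `MOTA = 100 * (1 - (FN + FP + IDSW) / |GT|)`. Matching is per-frame
#' Hungarian at `iou_threshold`; an identity switch is counted when a ground
#' truth id's matched track id changes between its consecutive matched
#' frames (occlusion gaps are skipped, per the MOTChallenge convention).
#' MOTA can be negative.
#'
#' @param gt,pred track tables (see module header).
#' @param iou_threshold match threshold (default 0.5).
#' @return List with `MOTA` (0-100 scale) and the counts `TP, FN, FP, IDSW`.
#' @export
mota <- function(gt, pred, iou_threshold = 0.5) {
  if (nrow(gt) == 0) stop("MOTA undefined: no ground truth boxes")
  frames <- seq_frames(gt, pred)
  tp <- 0L; fn <- 0L; fp <- 0L; idsw <- 0L
  last_match <- list() # gt id -> last matched pred id
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    fm <- frame_match(g, p, iou_threshold)
    tp <- tp + nrow(fm$matches)
    fn <- fn + length(fm$unmatched_gt)
    fp <- fp + length(fm$unmatched_pred)
    for (k in seq_len(nrow(fm$matches))) {
      gid <- as.character(g$id[fm$matches[k, "gt"]])
      pid <- p$id[fm$matches[k, "pred"]]
      if (!is.null(last_match[[gid]]) && last_match[[gid]] != pid) {
        idsw <- idsw + 1L
      }
      last_match[[gid]] <- pid
    }
  }
  list(MOTA = 100 * (1 - (fn + fp + idsw) / nrow(gt)),
       TP = tp, FN = fn, FP = fp, IDSW = idsw)
}

#' IDF1 identity metric
#'
#' F1 of identity-consistent matching under the optimal global bijection
#' between ground-truth and predicted ids: per id pair, the overlap count is
#' the number of frames where their boxes reach `iou_threshold`; the
#' bijection maximizing total overlap (Hungarian on the padded cost matrix)
#' yields IDTP, and `IDF1 = 100 * IDTP / (IDTP + 0.5 IDFP + 0.5 IDFN)`.
#'
#' @inheritParams mota
#' @return List with `IDF1` (0-100) and counts `IDTP, IDFP, IDFN`.
#' @export
idf1 <- function(gt, pred, iou_threshold = 0.5) {
  if (nrow(gt) == 0) stop("IDF1 undefined: no ground truth boxes")
  gids <- unique(gt$id); pids <- unique(pred$id)
  n <- length(gids); m <- length(pids)
  overlap <- matrix(0L, n, m)
  for (f in seq_frames(gt, pred)) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    if (nrow(g) == 0 || nrow(p) == 0) next
    sim <- class_gated_iou(g, p)
    hit <- which(sim >= iou_threshold, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      i <- match(g$id[hit[k, 1]], gids)
      j <- match(p$id[hit[k, 2]], pids)
      overlap[i, j] <- overlap[i, j] + 1L
    }
  }
  len_g <- as.numeric(table(factor(gt$id, levels = gids)))
  len_p <- as.numeric(table(factor(pred$id, levels = pids)))
  # padded assignment: dummy columns/rows carry the cost of leaving an id
  # unmatched (all its frames become IDFN or IDFP)
  size <- n + m
  cost <- matrix(Inf, size, size)
  if (n && m) cost[1:n, 1:m] <- outer(len_g, len_p, "+") - 2 * overlap
  for (i in seq_len(n)) cost[i, m + i] <- len_g[i]
  for (j in seq_len(m)) cost[n + j, j] <- len_p[j]
  if (n && m) cost[(n + 1):size, (m + 1):size] <- 0
  res <- hungarian_match(cost, Inf)
  idtp <- 0L
  for (k in seq_len(nrow(res$matches))) {
    i <- res$matches[k, 1]; j <- res$matches[k, 2]
    if (i <= n && j <= m) idtp <- idtp + overlap[i, j]
  }
  idfn <- sum(len_g) - idtp
  idfp <- sum(len_p) - idtp
  list(IDF1 = 100 * idtp / (idtp + 0.5 * idfp + 0.5 * idfn),
       IDTP = idtp, IDFP = idfp, IDFN = idfn)
}

HOTA_ALPHAS <- seq(0.05, 0.95, by = 0.05)

#' Higher Order Tracking Accuracy
#'
#' Reference HOTA: per frame, boxes are matched by Hungarian assignment on
#' the product of a global id-pair alignment score and the frame IoU; for
#' each threshold `alpha` in 0.05..0.95, matches with IoU >= alpha give
#' `DetA(alpha) = TP / (TP + FN + FP)` and
#' `AssA(alpha) = mean over TPs of TPA / (TPA + FNA + FPA)`;
#' `HOTA(alpha) = sqrt(DetA * AssA)` and the reported scores are means over
#' the 19 alphas, on the 0-100 scale.
#'
#' @inheritParams mota
#' @return List with `HOTA`, `DetA`, `AssA` (0-100) and per-alpha vectors.
#' @export
hota <- function(gt, pred) {
  if (nrow(gt) == 0) stop("HOTA undefined: no ground truth boxes")
  gids <- unique(gt$id); pids <- unique(pred$id)
  n <- length(gids); m <- length(pids)
  frames <- seq_frames(gt, pred)
  if (m == 0L) {
    z <- rep(0, length(HOTA_ALPHAS))
    return(list(HOTA = 0, DetA = 0, AssA = 0,
                DetA_alpha = z, AssA_alpha = z, HOTA_alpha = z))
  }
  gcount <- as.numeric(table(factor(gt$id, levels = gids)))
  pcount <- as.numeric(table(factor(pred$id, levels = pids)))

  per_frame <- lapply(frames, function(f) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    list(gi = match(g$id, gids), pj = match(p$id, pids),
         sim = class_gated_iou(g, p))
  })

  # global alignment score between id pairs, from IoU-normalized potential
  # matches accumulated over all frames
  pot <- matrix(0, n, m)
  for (fr in per_frame) {
    if (length(fr$gi) == 0 || length(fr$pj) == 0) next
    sim <- fr$sim
    denom <- outer(rowSums(sim), colSums(sim), "+") - sim
    norm <- ifelse(denom > 0, sim / denom, 0)
    pot[fr$gi, fr$pj] <- pot[fr$gi, fr$pj] + norm
  }
  galign <- pot / (outer(gcount, pcount, "+") - pot)

  na <- length(HOTA_ALPHAS)
  tp <- numeric(na); fn <- numeric(na); fp <- numeric(na)
  mcount <- lapply(seq_len(na), function(i) matrix(0, n, m))
  eps <- sqrt(.Machine$double.eps)
  for (fr in per_frame) {
    ng <- length(fr$gi); np <- length(fr$pj)
    fn <- fn + ng; fp <- fp + np
    if (ng == 0 || np == 0) next
    score <- galign[fr$gi, fr$pj, drop = FALSE] * fr$sim
    assigned <- solve_assignment(-score)
    for (i in seq_len(ng)) {
      j <- assigned[i]
      if (is.na(j)) next
      s <- fr$sim[i, j]
      hit <- which(s >= HOTA_ALPHAS - eps)
      for (a in hit) {
        mcount[[a]][fr$gi[i], fr$pj[j]] <- mcount[[a]][fr$gi[i], fr$pj[j]] + 1
        tp[a] <- tp[a] + 1
      }
    }
  }
  fn <- fn - tp; fp <- fp - tp
  det_a <- tp / pmax(tp + fn + fp, 1)
  ass_a <- vapply(seq_len(na), function(a) {
    mc <- mcount[[a]]
    av <- mc / (outer(gcount, pcount, "+") - mc)
    sum(mc * av) / max(tp[a], 1)
  }, 0)
  hota_a <- sqrt(det_a * ass_a)
  list(HOTA = 100 * mean(hota_a), DetA = 100 * mean(det_a),
       AssA = 100 * mean(ass_a), DetA_alpha = 100 * det_a,
       AssA_alpha = 100 * ass_a, HOTA_alpha = 100 * hota_a)
}

#' Combined tracking metric report
#'
#' @inheritParams mota
#' @return List with HOTA/DetA/AssA, MOTA, IDF1 (0-100) and all counts.
#' @export
metric_report <- function(gt, pred, iou_threshold = 0.5) {
  h <- hota(gt, pred)
  m <- mota(gt, pred, iou_threshold)
  i <- idf1(gt, pred, iou_threshold)
  list(HOTA = h$HOTA, DetA = h$DetA, AssA = h$AssA,
       MOTA = m$MOTA, IDF1 = i$IDF1,
       TP = m$TP, FN = m$FN, FP = m$FP, IDSW = m$IDSW,
       IDTP = i$IDTP, IDFP = i$IDFP, IDFN = i$IDFN)
}

#' COCO-style average precision
#'
#' Greedy score-ordered matching per image, 101-point interpolated
#' precision-recall area, averaged over IoU thresholds 0.50:0.05:0.95
#' (`mAP`); `AP50` is the 0.50 term alone. Multi-class inputs are averaged
#' over the classes present in the ground truth.
#'
#' @param gt data.frame with `image_id, x, y, w, h` (optional `class_id`).
#' @param pred data.frame with `image_id, x, y, w, h, score` (optional
#'   `class_id`).
#' @param iou_thresholds thresholds to average over.
#' @return List with `mAP` and `AP50`, both in `[0, 1]`.
#' @export
average_precision <- function(gt, pred,
                              iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (nrow(gt) == 0) stop("average precision undefined: no ground truth")
  classes <- sort(unique(class_of(gt)))
  ap_one <- function(g, p, thr) {
    if (nrow(p) == 0) return(0)
    ord <- order(-p$score)
    p <- p[ord, , drop = FALSE]
    tp_flag <- logical(nrow(p))
    used <- list()
    for (k in seq_len(nrow(p))) {
      img <- p$image_id[k]
      gi <- which(g$image_id == img)
      if (length(gi) == 0) next
      ious <- iou_matrix(boxes_of(p[k, , drop = FALSE]),
                         boxes_of(g[gi, , drop = FALSE]))[1, ]
      taken <- used[[as.character(img)]]
      ious[gi %in% taken] <- -1
      best <- which.max(ious)
      if (length(best) && ious[best] >= thr) {
        tp_flag[k] <- TRUE
        used[[as.character(img)]] <- c(taken, gi[best])
      }
    }
    tp_cum <- cumsum(tp_flag)
    fp_cum <- cumsum(!tp_flag)
    recall <- tp_cum / nrow(g)
    precision <- tp_cum / (tp_cum + fp_cum)
    # 101-point interpolation with a monotone precision envelope
    penv <- rev(cummax(rev(precision)))
    rgrid <- seq(0, 1, by = 0.01)
    pi <- vapply(rgrid, function(r) {
      ix <- which(recall >= r - 1e-12)
      if (length(ix)) penv[ix[1]] else 0
    }, 0)
    mean(pi)
  }
  aps <- sapply(iou_thresholds, function(thr) {
    mean(sapply(classes, function(cl) {
      g <- gt[class_of(gt) == cl, , drop = FALSE]
      p <- pred[class_of(pred) == cl, , drop = FALSE]
      ap_one(g, p, thr)
    }))
  })
  list(mAP = mean(aps), AP50 = aps[which.min(abs(iou_thresholds - 0.5))])
}

#' Box-based versus keypoint-based detection comparison
#'
#' Box mode: a ground-truth box counts as detected if some predicted box
#' reaches IoU 0.5 with it, and a predicted box is correct if it reaches IoU
#' 0.5 with some ground-truth box. Keypoint mode: each predicted skeleton
#' yields a box (its tight point extent, optionally buffered by
#' `buffer_factor`, e.g. 1.5); the box is correct if at least two keypoints
#' of a single ground-truth individual fall inside it, and a ground-truth
#' individual is detected if at least two of its keypoints fall inside some
#' predicted box. Reports recall, precision and F1 (0 when P + R = 0).
#'
#' @param gt_boxes per-frame list of ground-truth box matrices (n x 4).
#' @param pred_boxes per-frame list of predicted box matrices (box mode).
#' @param pred_skeletons per-frame list of lists of keypoint matrices
#'   (n_kp x 2; keypoint mode).
#' @param gt_keypoints per-frame list of lists of per-individual keypoint
#'   matrices (keypoint mode).
#' @param buffer_factor box scale applied to skeleton-derived boxes.
#' @return List with `recall`, `precision`, `F1`.
#' @export
detection_compare <- function(gt_boxes, pred_boxes = NULL,
                              pred_skeletons = NULL, gt_keypoints = NULL,
                              buffer_factor = 1) {
  box_mode <- !is.null(pred_boxes)
  if (box_mode == !is.null(pred_skeletons)) {
    stop("provide exactly one of pred_boxes or pred_skeletons")
  }
  n_gt <- 0L; n_pred <- 0L; gt_hit <- 0L; pred_hit <- 0L
  for (f in seq_along(gt_boxes)) {
    g <- as_box_matrix(gt_boxes[[f]])
    n_gt_f <- nrow(g)
    n_gt <- n_gt + n_gt_f
    if (box_mode) {
      p <- as_box_matrix(pred_boxes[[f]])
      n_pred <- n_pred + nrow(p)
      if (n_gt_f && nrow(p)) {
        sim <- iou_matrix(g, p)
        gt_hit <- gt_hit + sum(apply(sim, 1, max) >= 0.5)
        pred_hit <- pred_hit + sum(apply(sim, 2, max) >= 0.5)
      }
    } else {
      skel <- pred_skeletons[[f]]
      kps <- gt_keypoints[[f]]
      pboxes <- lapply(skel, function(s) {
        b <- box(min(s[, 1]), min(s[, 2]),
                 max(s[, 1]) - min(s[, 1]), max(s[, 2]) - min(s[, 2]))
        buffer_box(b, buffer_factor)
      })
      n_pred <- n_pred + length(pboxes)
      inside_count <- function(kp, b) {
        sum(vapply(seq_len(nrow(kp)),
                   function(r) point_in_box(kp[r, ], b), TRUE))
      }
      for (b in pboxes) {
        if (any(vapply(kps, function(kp) inside_count(kp, b) >= 2, TRUE))) {
          pred_hit <- pred_hit + 1L
        }
      }
      for (kp in kps) {
        if (any(vapply(pboxes, function(b) inside_count(kp, b) >= 2, TRUE))) {
          gt_hit <- gt_hit + 1L
        }
      }
      if (!box_mode) n_gt <- n_gt - n_gt_f + length(kps)
    }
  }
  recall <- if (n_gt > 0) gt_hit / n_gt else 0
  precision <- if (n_pred > 0) pred_hit / n_pred else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(recall = recall, precision = precision, F1 = f1)
}

#' Keypoint error to the closest ground truth
#'
#' Each predicted keypoint's Euclidean distance to the nearest ground-truth
#' keypoint of the same type; the summary is the median over all predicted
#' keypoints.
#'
#' @param pred,gt data.frames with columns `x, y, type` (optional `frame`,
#'   compared within frame).
#' @return List with `errors` (per predicted keypoint) and `median`.
#' @export
keypoint_rmse <- function(pred, gt) {
  if (nrow(gt) == 0) stop("keypoint error undefined: no ground truth keypoints")
  if (nrow(pred) == 0) stop("keypoint error undefined: no predicted keypoints")
  key <- function(df) {
    if ("frame" %in% names(df)) paste(df$frame, df$type) else as.character(df$type)
  }
  gk <- key(gt); pk <- key(pred)
  errors <- vapply(seq_len(nrow(pred)), function(i) {
    cand <- which(gk == pk[i])
    if (length(cand) == 0) return(NA_real_)
    min(sqrt((gt$x[cand] - pred$x[i])^2 + (gt$y[cand] - pred$y[i])^2))
  }, 0)
  list(errors = errors, median = stats::median(errors, na.rm = TRUE))
}

#' Inter-annotator box consistency
#'
#' Per frame, boxes from the two annotators are matched by Hungarian
#' assignment maximizing IoU; the score is the average IoU over all boxes,
#' with unmatched boxes contributing zero terms.
#'
#' @param a,b per-frame lists of box matrices from two annotators.
#' @return Average IoU in `[0, 1]`.
#' @export
annotation_consistency <- function(a, b) {
  total <- 0; terms <- 0L
  for (f in seq_along(a)) {
    A <- as_box_matrix(a[[f]]); B <- as_box_matrix(b[[f]])
    if (nrow(A) == 0 && nrow(B) == 0) next
    if (nrow(A) && nrow(B)) {
      sim <- iou_matrix(A, B)
      res <- hungarian_match(1 - sim, Inf)
      total <- total + sum(sim[res$matches])
      terms <- terms + nrow(res$matches) +
        length(res$unmatched_rows) + length(res$unmatched_cols)
    } else {
      terms <- terms + nrow(A) + nrow(B)
    }
  }
  if (terms == 0L) stop("annotation consistency undefined: no boxes")
  total / terms
}
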