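# Independent oracles used to check the package implementations. Everything
# here is deliberately naive -- enumeration, unit-cell counting, plain loops
# -- and shares no code with the package internals (in particular, no
# Hungarian solver and no reuse of the package IoU).

# plain-arithmetic IoU, independent of primatrack::iou
iou_simple <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  uni <- a[3] * a[4] + b[3] * b[4] - inter
  if (uni <= 0) 0 else inter / uni
}

# rasterization oracle for integer-coordinate boxes: count occupied unit
# cells on the pixel grid (exact for integer boxes, so equivalent to any
# upsampled sub-pixel count)
raster_iou <- function(a, b) {
  x0 <- min(a[1], b[1]); y0 <- min(a[2], b[2])
  x1 <- max(a[1] + a[3], b[1] + b[3]); y1 <- max(a[2] + a[4], b[2] + b[4])
  W <- x1 - x0; H <- y1 - y0
  grid_of <- function(bb) {
    g <- matrix(FALSE, H, W)
    if (bb[3] > 0 && bb[4] > 0) {
      g[(bb[2] - y0 + 1):(bb[2] - y0 + bb[4]),
        (bb[1] - x0 + 1):(bb[1] - x0 + bb[3])] <- TRUE
    }
    g
  }
  ga <- grid_of(a); gb <- grid_of(b)
  sum(ga & gb) / sum(ga | gb)
}

# all permutations of a vector, as a list
perm_list <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# brute-force minimum assignment total (Inf treated as the same large
# penalty the solver uses)
brute_min_total <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) return(brute_min_total(t(cost)))
  cost[!is.finite(cost)] <- 1e8
  best <- Inf
  sets <- utils::combn(m, n, simplify = FALSE)
  for (s in sets) {
    for (p in perm_list(s)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best) best <- tot
    }
  }
  best
}

# all injective partial matchings between row and column indices; returns the
# one maximizing (number of pairs, total weight) over pairs allowed[i, j]
best_partial_matching <- function(weight, allowed) {
  n <- nrow(weight); m <- ncol(weight)
  best <- list(count = -1L, total = -Inf, pairs = NULL)
  recurse <- function(i, used, pairs, total) {
    if (i > n) {
      cnt <- if (is.null(pairs)) 0L else nrow(pairs)
      if (cnt > best$count || (cnt == best$count && total > best$total)) {
        best <<- list(count = cnt, total = total, pairs = pairs)
      }
      return()
    }
    recurse(i + 1L, used, pairs, total) # leave row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(i, j)), total + weight[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), NULL, 0)
  best
}

frame_sim <- function(g, p) {
  sim <- matrix(0, nrow(g), nrow(p))
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(p))) {
      if (g$class_id[i] == p$class_id[j]) {
        sim[i, j] <- iou_simple(c(g$x[i], g$y[i], g$w[i], g$h[i]),
                                c(p$x[j], p$y[j], p$w[j], p$h[j]))
      }
    }
  }
  sim
}

# MOTA by enumeration-based per-frame matching
oracle_mota <- function(gt, pred, thr = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  fn <- 0L; fp <- 0L; idsw <- 0L
  last <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    sim <- frame_sim(g, p)
    bm <- best_partial_matching(sim, sim >= thr)
    nmatch <- bm$count
    fn <- fn + nrow(g) - nmatch
    fp <- fp + nrow(p) - nmatch
    for (k in seq_len(nmatch)) {
      gid <- as.character(g$id[bm$pairs[k, 1]])
      pid <- p$id[bm$pairs[k, 2]]
      if (!is.null(last[[gid]]) && last[[gid]] != pid) idsw <- idsw + 1L
      last[[gid]] <- pid
    }
  }
  100 * (1 - (fn + fp + idsw) / nrow(gt))
}

# IDF1 by enumeration over injective id bijections
oracle_idf1 <- function(gt, pred, thr = 0.5) {
  gids <- unique(gt$id); pids <- unique(pred$id)
  ov <- matrix(0, length(gids), length(pids))
  for (f in sort(unique(c(gt$frame, pred$frame)))) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    if (!nrow(g) || !nrow(p)) next
    sim <- frame_sim(g, p)
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
      if (sim[i, j] >= thr) {
        ov[match(g$id[i], gids), match(p$id[j], pids)] <-
          ov[match(g$id[i], gids), match(p$id[j], pids)] + 1
      }
    }
  }
  bm <- best_partial_matching(ov, ov > -1) # all pairs allowed
  idtp <- bm$total
  idfn <- nrow(gt) - idtp
  idfp <- nrow(pred) - idtp
  100 * idtp / (idtp + 0.5 * idfp + 0.5 * idfn)
}

# HOTA by the reference recipe with enumeration replacing the Hungarian step
oracle_hota <- function(gt, pred) {
  gids <- unique(gt$id); pids <- unique(pred$id)
  n <- length(gids); m <- length(pids)
  frames <- sort(unique(c(gt$frame, pred$frame)))
  if (m == 0) return(0)
  alphas <- seq(0.05, 0.95, by = 0.05)
  gcount <- sapply(gids, function(i) sum(gt$id == i))
  pcount <- sapply(pids, function(j) sum(pred$id == j))
  pot <- matrix(0, n, m)
  fr <- lapply(frames, function(f) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    sim <- frame_sim(g, p)
    list(g = g, p = p, sim = sim)
  })
  for (x in fr) {
    if (!nrow(x$g) || !nrow(x$p)) next
    for (i in seq_len(nrow(x$g))) for (j in seq_len(nrow(x$p))) {
      den <- sum(x$sim[i, ]) + sum(x$sim[, j]) - x$sim[i, j]
      if (den > 0) {
        gi <- match(x$g$id[i], gids); pj <- match(x$p$id[j], pids)
        pot[gi, pj] <- pot[gi, pj] + x$sim[i, j] / den
      }
    }
  }
  galign <- pot / (outer(gcount, pcount, "+") - pot)
  tp <- numeric(length(alphas))
  totg <- 0L; totp <- 0L
  mc <- lapply(alphas, function(a) matrix(0, n, m))
  eps <- sqrt(.Machine$double.eps)
  for (x in fr) {
    ng <- nrow(x$g); np <- nrow(x$p)
    totg <- totg + ng; totp <- totp + np
    if (!ng || !np) next
    score <- matrix(0, ng, np)
    for (i in seq_len(ng)) for (j in seq_len(np)) {
      score[i, j] <- galign[match(x$g$id[i], gids), match(x$p$id[j], pids)] *
        x$sim[i, j]
    }
    # full assignment of the smaller side maximizing total score
    k <- min(ng, np)
    best <- NULL; bestv <- -Inf
    if (ng <= np) {
      for (s in utils::combn(np, ng, simplify = FALSE)) {
        for (p2 in perm_list(s)) {
          v <- sum(score[cbind(seq_len(ng), p2)])
          if (v > bestv) { bestv <- v; best <- cbind(seq_len(ng), p2) }
        }
      }
    } else {
      for (s in utils::combn(ng, np, simplify = FALSE)) {
        for (p2 in perm_list(s)) {
          v <- sum(score[cbind(p2, seq_len(np))])
          if (v > bestv) { bestv <- v; best <- cbind(p2, seq_len(np)) }
        }
      }
    }
    for (r in seq_len(nrow(best))) {
      i <- best[r, 1]; j <- best[r, 2]
      s <- x$sim[i, j]
      for (a in seq_along(alphas)) {
        if (s >= alphas[a] - eps) {
          gi <- match(x$g$id[i], gids); pj <- match(x$p$id[j], pids)
          mc[[a]][gi, pj] <- mc[[a]][gi, pj] + 1
          tp[a] <- tp[a] + 1
        }
      }
    }
  }
  hsum <- 0
  for (a in seq_along(alphas)) {
    fn <- totg - tp[a]; fp <- totp - tp[a]
    deta <- tp[a] / max(tp[a] + fn + fp, 1)
    av <- mc[[a]] / (outer(gcount, pcount, "+") - mc[[a]])
    assa <- sum(mc[[a]] * av) / max(tp[a], 1)
    hsum <- hsum + sqrt(deta * assa)
  }
  100 * hsum / length(alphas)
}

# seeded random tracking sequence with id corruption, misses and clutter
random_tracking_sequence <- function(seed, max_ids = 5, n_frames = 50,
                                     swap_prob = 0.5) {
  set.seed(seed)
  n_ids <- sample.int(max_ids, 1)
  W <- 400; H <- 300
  gt_rows <- list(); pred_rows <- list()
  next_pid <- 100L
  for (i in seq_len(n_ids)) {
    cx <- runif(1, 40, W - 40); cy <- runif(1, 40, H - 40)
    vx <- runif(1, -3, 3); vy <- runif(1, -3, 3)
    sz <- runif(1, 25, 45)
    pid <- next_pid; next_pid <- next_pid + 1L
    swap_at <- if (runif(1) < swap_prob) sample.int(n_frames, 1) else Inf
    for (f in seq_len(n_frames) - 1) {
      cx <- cx + vx; cy <- cy + vy
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        frame = f, id = i, x = cx - sz / 2, y = cy - sz / 2, w = sz, h = sz,
        class_id = 0L)
      if (f == swap_at) { pid <- next_pid; next_pid <- next_pid + 1L }
      if (runif(1) < 0.1) next # missed detection
      jx <- rnorm(1, 0, 2); jy <- rnorm(1, 0, 2)
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        frame = f, id = pid, x = cx - sz / 2 + jx, y = cy - sz / 2 + jy,
        w = sz, h = sz, class_id = 0L)
    }
  }
  for (f in seq_len(n_frames) - 1) {
    if (runif(1) < 0.15) {
      sz <- runif(1, 20, 40)
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        frame = f, id = 999L, x = runif(1, 0, W - sz), y = runif(1, 0, H - sz),
        w = sz, h = sz, class_id = 0L)
    }
  }
  list(gt = do.call(rbind, gt_rows), pred = do.call(rbind, pred_rows))
}

boxes_of_df <- function(df) {
  m <- as.matrix(df[, c("x", "y", "w", "h"), drop = FALSE])
  dimnames(m) <- NULL
  m
}
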