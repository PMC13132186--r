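# Copy-paste training-data synthesis: masked animal instances are pasted
# onto arbitrary backgrounds with hard mask edges (no blending), and
# detection labels are recomputed from each instance's visible pixels, so
# occluded or clipped instances get tight, learnable boxes.
#
# Images are H x W x 3 integer arrays with values 0..255; masks are H x W
# 0/1 matrices aligned to their patch. Integer pixel operations keep
# composites bit-reproducible across platforms.

#' Instance cutout
#'
#' @param patch H x W x 3 integer RGB array (0..255).
#' @param mask H x W 0/1 matrix, 1 = animal pixel; at least one foreground
#'   pixel.
#' @return List of class `instance_cutout`.
#' @export
instance_cutout <- function(patch, mask) {
  stopifnot(length(dim(patch)) == 3, dim(patch)[3] == 3,
            identical(dim(patch)[1:2], dim(mask)))
  if (sum(mask) < 1) stop("instance mask has no foreground pixel")
  structure(list(patch = patch, mask = mask), class = "instance_cutout")
}

#' Bounding box from mask extreme points
#'
#' The tightest pixel-inclusive box over the foreground: width is
#' `max col - min col + 1` (0-based pixel coordinates), analogously for
#' height, translated by `origin`.
#'
#' @param mask 0/1 matrix.
#' @param origin `c(x, y)` offset of the mask's top-left pixel in the image.
#' @return A [box()].
#' @export
#' @examples
#' m <- matrix(0, 10, 10); m[8, 4] <- 1
#' mask_to_box(m) # pixel at x=3, y=7 -> c(3, 7, 1, 1)
mask_to_box <- function(mask, origin = c(0, 0)) {
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask: no foreground pixels")
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
  box(origin[1] + c0 - 1, origin[2] + r0 - 1, c1 - c0 + 1, r1 - r0 + 1)
}

# nearest-neighbor resize of a matrix/array to n rows x m cols
nn_resize <- function(img, nr, nc) {
  sr <- dim(img)[1]; sc <- dim(img)[2]
  ri <- pmin(pmax(floor(((seq_len(nr) - 0.5) * sr) / nr) + 1, 1), sr)
  ci <- pmin(pmax(floor(((seq_len(nc) - 0.5) * sc) / nc) + 1, 1), sc)
  if (length(dim(img)) == 3) img[ri, ci, , drop = FALSE] else img[ri, ci, drop = FALSE]
}

#' Composite instances onto a background
#'
#' Instances are pasted in list order, later ones occluding earlier ones.
#' Each label box is recomputed from the instance's visible (un-occluded,
#' in-bounds) pixels via [mask_to_box()]; an instance left with zero visible
#' pixels is dropped and recorded in `dropped`, not an error. Background
#' pixels outside all pasted masks are bit-identical to the input.
#'
#' @param background H x W x 3 integer array.
#' @param instances list of [instance_cutout()]s.
#' @param placements list of `list(position = c(x, y), scale, flip)`:
#'   0-based top-left paste position of the scaled patch, isotropic scale
#'   factor, and horizontal flip flag.
#' @param class_ids class label per instance (default all 0).
#' @return List with `image`, `labels` (data.frame x, y, w, h, class_id,
#'   instance), `dropped` (instance indices) and `provenance`.
#' @export
compose <- function(background, instances, placements,
                    class_ids = rep(0L, length(instances))) {
  H <- dim(background)[1]; W <- dim(background)[2]
  out <- background
  owner <- matrix(0L, H, W)
  prov <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    pl <- placements[[i]]
    sc <- if (is.null(pl$scale)) 1 else pl$scale
    nr <- max(1L, round(dim(inst$mask)[1] * sc))
    nc <- max(1L, round(dim(inst$mask)[2] * sc))
    patch <- nn_resize(inst$patch, nr, nc)
    mask <- nn_resize(inst$mask, nr, nc)
    if (isTRUE(pl$flip)) {
      patch <- patch[, rev(seq_len(nc)), , drop = FALSE]
      mask <- mask[, rev(seq_len(nc)), drop = FALSE]
    }
    x0 <- round(pl$position[1]); y0 <- round(pl$position[2])
    # in-bounds overlap between the scaled patch and the background
    rows <- max(1L, y0 + 1L):min(H, y0 + nr)
    cols <- max(1L, x0 + 1L):min(W, x0 + nc)
    if (y0 + 1L > H || y0 + nr < 1L || x0 + 1L > W || x0 + nc < 1L) {
      prov[[i]] <- list(instance = i, position = c(x0, y0), scale = sc,
                        flip = isTRUE(pl$flip))
      next
    }
    prow <- rows - y0; pcol <- cols - x0
    sub_mask <- mask[prow, pcol, drop = FALSE] != 0
    if (any(sub_mask)) {
      own <- owner[rows, cols, drop = FALSE]
      own[sub_mask] <- i
      owner[rows, cols] <- own
      for (ch in 1:3) {
        dst <- out[rows, cols, ch]
        src <- patch[prow, pcol, ch]
        dst[sub_mask] <- src[sub_mask]
        out[rows, cols, ch] <- dst
      }
    }
    prov[[i]] <- list(instance = i, position = c(x0, y0), scale = sc,
                      flip = isTRUE(pl$flip))
  }
  labels <- list(); dropped <- integer(0)
  for (i in seq_along(instances)) {
    vis <- owner == i
    if (!any(vis)) {
      dropped <- c(dropped, i)
      next
    }
    b <- mask_to_box(vis)
    labels[[length(labels) + 1L]] <-
      data.frame(x = b[1], y = b[2], w = b[3], h = b[4],
                 class_id = class_ids[i], instance = i)
  }
  if (length(dropped)) {
    warning(sprintf("%d instance(s) fully occluded or out of frame, dropped from labels",
                    length(dropped)))
  }
  list(image = out,
       labels = if (length(labels)) do.call(rbind, labels) else
         data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                    h = numeric(0), class_id = integer(0), instance = integer(0)),
       dropped = dropped, provenance = prov)
}

#' Build a seeded copy-paste dataset with a train/test split
#'
#' Draws instances, backgrounds and placements from the pools under a fixed
#' seed, composes `n_images` samples, and splits them at the image level by
#' a seeded shuffle (default 80/20).
#'
#' @param instance_pool list of [instance_cutout()]s.
#' @param background_pool list of H x W x 3 integer arrays.
#' @param n_images number of composites.
#' @param instances_per_image_range inclusive `c(min, max)` instances per
#'   composite.
#' @param split_fraction training fraction in `(0, 1)`.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @param scale_range instance scale jitter range.
#' @param flip_prob horizontal flip probability.
#' @return List with `train` and `test`, each a list of [compose()] outputs.
#' @export
build_dataset <- function(instance_pool, background_pool, n_images,
                          instances_per_image_range = c(1L, 3L),
                          split_fraction = 0.8, seed = 1L,
                          scale_range = c(0.5, 1.5), flip_prob = 0.5) {
  stopifnot(length(instance_pool) > 0, length(background_pool) > 0,
            split_fraction > 0, split_fraction < 1)
  with_seed(seed, {
    samples <- lapply(seq_len(n_images), function(s) {
      bg <- background_pool[[sample.int(length(background_pool), 1)]]
      H <- dim(bg)[1]; W <- dim(bg)[2]
      k <- sample(instances_per_image_range[1]:instances_per_image_range[2], 1)
      idx <- sample.int(length(instance_pool), k, replace = TRUE)
      placements <- lapply(idx, function(i) {
        sc <- stats::runif(1, scale_range[1], scale_range[2])
        nr <- max(1, round(dim(instance_pool[[i]]$mask)[1] * sc))
        nc <- max(1, round(dim(instance_pool[[i]]$mask)[2] * sc))
        list(position = c(round(stats::runif(1, -nc / 4, W - 3 * nc / 4)),
                          round(stats::runif(1, -nr / 4, H - 3 * nr / 4))),
             scale = sc, flip = stats::runif(1) < flip_prob)
      })
      suppressWarnings(compose(bg, instance_pool[idx], placements))
    })
    n_train <- round(split_fraction * n_images)
    perm <- sample.int(n_images)
    list(train = samples[perm[seq_len(n_train)]],
         test = samples[perm[-seq_len(n_train)]])
  })
}
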