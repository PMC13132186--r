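# Readers/writers for the interchange formats: MOTChallenge track text,
# a COCO JSON subset (detections + instance segmentations), YAML run
# configuration. Writers are deterministic (fixed field order and float
# formatting) so fixture hashes are stable; external files are 1-based,
# internal coordinates 0-based, and the conversion happens only here.

#' Read MOTChallenge track file
#'
#' Rows are `frame,id,bb_left,bb_top,bb_width,bb_height,conf,class,vis` with
#' 1-based frame and pixel coordinates; internally frames and coordinates
#' are 0-based.
#'
#' @param path file path.
#' @return data.frame `frame, id, x, y, w, h, score, class_id, visibility`.
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 9) {
      stop(sprintf("malformed MOT row at line %d: expected 9 fields, got %d",
                   i, length(parts)))
    }
    v <- suppressWarnings(as.numeric(parts))
    if (any(is.na(v))) stop(sprintf("malformed MOT row at line %d: non-numeric field", i))
    if (v[5] < 0 || v[6] < 0) {
      stop(sprintf("malformed MOT row at line %d: negative box size", i))
    }
    v
  })
  m <- do.call(rbind, rows)
  data.frame(frame = as.integer(m[, 1]) - 1L, id = as.integer(m[, 2]),
             x = m[, 3] - 1, y = m[, 4] - 1, w = m[, 5], h = m[, 6],
             score = m[, 7], class_id = as.integer(m[, 8]),
             visibility = m[, 9])
}

#' Write MOTChallenge track file
#'
#' Inverse of [read_mot()]: frames and coordinates are written 1-based,
#' coordinates and scores with 4 decimals, rows sorted by frame then id.
#'
#' @param df track table with at least `frame, id, x, y, w, h` (optional
#'   `score`, `class_id`, `visibility`).
#' @param path output path.
#' @export
write_mot <- function(df, path) {
  score <- if ("score" %in% names(df)) df$score else rep(1, nrow(df))
  cls <- if ("class_id" %in% names(df)) df$class_id else rep(0L, nrow(df))
  vis <- if ("visibility" %in% names(df)) df$visibility else rep(1, nrow(df))
  ord <- order(df$frame, df$id)
  lines <- sprintf("%d,%d,%.4f,%.4f,%.4f,%.4f,%.4f,%d,%.4f",
                   df$frame[ord] + 1L, df$id[ord],
                   df$x[ord] + 1, df$y[ord] + 1, df$w[ord], df$h[ord],
                   score[ord], cls[ord], vis[ord])
  writeLines(lines, path)
  invisible(path)
}

#' Write detections / instances as COCO JSON
#'
#' Emits the COCO subset this package consumes: `images`, `annotations`
#' (bbox, score, optional polygon segmentation) and `categories`, with
#' fixed key order.
#'
#' @param annotations data.frame with `image_id, x, y, w, h` and optionally
#'   `score`, `class_id`, `segmentation` (list column of polygon vectors).
#' @param images data.frame with `id, width, height`.
#' @param categories data.frame with `id, name`.
#' @param path output path.
#' @export
write_coco <- function(annotations, images, categories, path) {
  anns <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- list(id = i, image_id = annotations$image_id[i],
              category_id = if ("class_id" %in% names(annotations))
                annotations$class_id[i] else 0L,
              bbox = c(annotations$x[i], annotations$y[i],
                       annotations$w[i], annotations$h[i]))
    if ("score" %in% names(annotations)) a$score <- annotations$score[i]
    if ("segmentation" %in% names(annotations)) {
      a$segmentation <- list(annotations$segmentation[[i]])
    }
    a
  })
  doc <- list(
    images = lapply(seq_len(nrow(images)), function(i) {
      im <- list(id = images$id[i], width = images$width[i],
                 height = images$height[i])
      if ("file_name" %in% names(images)) im$file_name <- images$file_name[i]
      im
    }),
    annotations = anns,
    categories = lapply(seq_len(nrow(categories)), function(i) {
      list(id = categories$id[i], name = categories$name[i])
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the COCO JSON subset
#'
#' @param path file path.
#' @return List with `annotations` (data.frame, `segmentation` as a list
#'   column when present), `images`, `categories`.
#' @export
read_coco <- function(path) {
  doc <- jsonlite::read_json(path)
  for (key in c("images", "annotations", "categories")) {
    if (is.null(doc[[key]])) stop(sprintf("COCO schema error: missing '%s'", key))
  }
  anns <- lapply(doc$annotations, function(a) {
    if (is.null(a$bbox) || is.null(a$image_id)) {
      stop("COCO schema error: annotation missing bbox or image_id")
    }
    bb <- unlist(a$bbox)
    data.frame(image_id = a$image_id,
               x = bb[1], y = bb[2], w = bb[3], h = bb[4],
               class_id = if (is.null(a$category_id)) 0L else a$category_id,
               score = if (is.null(a$score)) NA_real_ else a$score)
  })
  ann_df <- do.call(rbind, anns)
  segs <- lapply(doc$annotations, function(a) {
    if (is.null(a$segmentation)) NULL else a$segmentation
  })
  if (any(!vapply(segs, is.null, TRUE))) ann_df$segmentation <- I(segs)
  imgs <- do.call(rbind, lapply(doc$images, function(im) {
    data.frame(id = im$id,
               width = if (is.null(im$width)) NA_integer_ else im$width,
               height = if (is.null(im$height)) NA_integer_ else im$height,
               file_name = if (is.null(im$file_name)) NA_character_ else im$file_name)
  }))
  cats <- do.call(rbind, lapply(doc$categories, function(ct) {
    data.frame(id = ct$id, name = ct$name)
  }))
  list(annotations = ann_df, images = imgs, categories = cats)
}

#' Decode a COCO segmentation to a binary mask
#'
#' Supports polygons (`[x1, y1, x2, y2, ...]`, even-odd fill over pixel
#' centers) and uncompressed RLE (`list(counts, size)`, column-major,
#' starting with background).
#'
#' @param seg one segmentation entry: a list of polygon vectors, or a list
#'   with `counts` and `size`.
#' @param height,width mask dimensions (polygons only).
#' @return H x W 0/1 matrix.
#' @export
decode_segmentation <- function(seg, height = NULL, width = NULL) {
  if (!is.null(seg$counts)) {
    size <- unlist(seg$size)
    counts <- unlist(seg$counts)
    vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
    if (length(vals) != prod(size)) stop("RLE counts do not fill the mask")
    return(matrix(vals, size[1], size[2]))
  }
  if (is.null(height) || is.null(width)) {
    stop("polygon decoding needs explicit mask height and width")
  }
  mask <- matrix(0L, height, width)
  for (poly in seg) {
    p <- unlist(poly)
    px <- p[seq(1, length(p), by = 2)]
    py <- p[seq(2, length(p), by = 2)]
    xs <- seq_len(width) - 0.5
    ys <- seq_len(height) - 0.5
    # even-odd rule on pixel centers, vectorized over columns per row
    n <- length(px)
    for (r in seq_len(height)) {
      ycr <- ys[r]
      inside <- rep(FALSE, width)
      j <- n
      for (i in seq_len(n)) {
        if ((py[i] > ycr) != (py[j] > ycr)) {
          xint <- px[i] + (ycr - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
          inside <- xor(inside, xs < xint)
        }
        j <- i
      }
      mask[r, inside] <- 1L
    }
  }
  mask
}

#' Write a composed copy-paste dataset as COCO JSON + PNG images
#'
#' @param samples list of [compose()] outputs.
#' @param dir output directory (created if needed); images go to
#'   `dir/images`, labels to `dir/annotations.json`.
#' @return Invisibly, the annotation file path.
#' @export
write_composite_dataset <- function(samples, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  anns <- list(); imgs <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    png::writePNG(s$image / 255, file.path(img_dir, sprintf("%06d.png", i)))
    imgs[[i]] <- data.frame(id = i, width = dim(s$image)[2],
                            height = dim(s$image)[1])
    if (nrow(s$labels)) {
      lab <- s$labels
      lab$image_id <- i
      anns[[length(anns) + 1L]] <- lab[, c("image_id", "x", "y", "w", "h", "class_id")]
    }
  }
  out <- file.path(dir, "annotations.json")
  write_coco(do.call(rbind, anns), do.call(rbind, imgs),
             data.frame(id = 0L, name = "primate"), out)
  invisible(out)
}

RUN_CONFIG_DEFAULTS <- function() {
  list(tracker = unclass(tracker_config()),
       crop = unclass(crop_spec()),
       vote = unclass(vote_config()),
       scene = unclass(scene_config()))
}

#' Read a YAML run configuration
#'
#' The document has four optional sections (`tracker`, `crop`, `vote`,
#' `scene`); every field has a documented default and unknown keys are
#' rejected.
#'
#' @param path YAML file path (`NULL` for pure defaults).
#' @return Nested list with all defaults filled in.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- RUN_CONFIG_DEFAULTS()
  if (is.null(path)) return(cfg)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) return(cfg)
  for (section in names(doc)) {
    if (!section %in% names(cfg)) {
      stop(sprintf("unknown config section '%s'", section))
    }
    for (key in names(doc[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        stop(sprintf("unknown config key '%s.%s'", section, key))
      }
      # [key] <- list(...) keeps keys whose configured value is NULL
      cfg[[section]][key] <- list(doc[[section]][[key]])
    }
  }
  cfg
}

#' Write a run configuration as YAML
#'
#' @param cfg nested list as returned by [read_run_config()].
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
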