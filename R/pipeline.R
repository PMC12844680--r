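# Dataset-construction pipeline: sliding-window tiling with overlap,
# polygon-annotation rasterization, crown-containing screening,
# training-only augmentation, and the random train/validation split.
# Pixel indexing is 0-based (row, col); windows are half-open
# [start, start + window).

#' Plan a sliding-window tile grid
#'
#' Stride is `round(window_px * (1 - overlap_frac))`; start positions
#' run 0, stride, 2*stride, ... while start + window fits, and when the
#' last such window stops short of the image edge one final origin is
#' clamped to `dim - window` per axis, so every pixel is covered.
#'
#' @param width,height source raster size in pixels.
#' @param window_px square window size (default 640).
#' @param overlap_frac fractional overlap between adjacent windows
#'   (default 0.25, i.e. stride = 75% of the window).
#' @return a `tile_grid`: `window_px`, `stride_px`, `origins` (matrix
#'   of 0-based (x0, y0)), `source_size` (width, height).
#' @export
plan_tiles <- function(width, height, window_px = 640L,
                       overlap_frac = 0.25) {
  width <- as.integer(width); height <- as.integer(height)
  window_px <- as.integer(window_px)
  if (window_px > min(width, height))
    stop("window (", window_px, ") larger than source (", width, "x",
         height, ")")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must lie in [0, 1)")
  stride <- as.integer(round(window_px * (1 - overlap_frac)))
  axis_starts <- function(dim) {
    s <- seq.int(0L, dim - window_px, by = stride)
    if (s[length(s)] + window_px < dim) s <- c(s, dim - window_px)
    s
  }
  xs <- axis_starts(width)
  ys <- axis_starts(height)
  origins <- cbind(x0 = rep(xs, times = length(ys)),
                   y0 = rep(ys, each = length(xs)))
  structure(list(window_px = window_px, stride_px = stride,
                 origins = origins, source_size = c(width, height)),
            class = "tile_grid")
}

#' Extract window crops from a multiband raster
#'
#' @param stack array (H, W, C) or matrix (H, W).
#' @param grid a `tile_grid` from [plan_tiles()].
#' @return list of (window, window, C) arrays, grid order (row-major).
#' @export
extract_tiles <- function(stack, grid) {
  d <- dim(stack)
  if (is.null(d) || length(d) < 2L) stop("stack must be a matrix or array")
  if (d[2] != grid$source_size[1] || d[1] != grid$source_size[2])
    stop("raster size ", d[2], "x", d[1], " does not match grid source ",
         grid$source_size[1], "x", grid$source_size[2])
  w <- grid$window_px
  lapply(seq_len(nrow(grid$origins)), function(i) {
    x0 <- grid$origins[i, 1]; y0 <- grid$origins[i, 2]
    if (length(d) == 2L)
      stack[y0 + seq_len(w), x0 + seq_len(w), drop = FALSE]
    else
      stack[y0 + seq_len(w), x0 + seq_len(w), , drop = FALSE]
  })
}

#' Create a polygon annotation set
#'
#' @param polygons list of entries, each `list(label =, points =)` with
#'   `points` an n x 2 matrix of (x, y) float pixel coordinates.
#' @param image_size (width, height).
#' @export
annotation_set <- function(polygons, image_size) {
  for (p in polygons) {
    if (is.null(p$points) || nrow(p$points) < 3L)
      stop("each polygon needs at least 3 vertices")
  }
  structure(list(polygons = polygons,
                 image_size = as.integer(image_size)),
            class = "annotation_set")
}

#' Read a LabelMe-style JSON annotation file
#'
#' Expects the usual structure: `shapes` entries with `label` and
#' `points`, plus `imageWidth`/`imageHeight`.
#'
#' @param path JSON file path.
#' @export
read_labelme <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- lapply(j$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    list(label = s$label, points = pts)
  })
  annotation_set(polys, c(j$imageWidth, j$imageHeight))
}

#' Rasterize target polygons to a binary mask
#'
#' A pixel is positive iff its center lies inside at least one polygon
#' carrying a target label (even-odd fill rule; overlapping polygons
#' union). Pixel (row i, col j), 0-based, has center (j + 0.5, i + 0.5).
#'
#' @param ann an [annotation_set()].
#' @param height,width output mask size.
#' @param target_labels labels counted as crown (default: all).
#' @return (height, width) matrix over \{0, 1\}.
#' @export
rasterize_polygons <- function(ann, height, width, target_labels = NULL) {
  polys <- ann$polygons
  if (!is.null(target_labels))
    polys <- Filter(function(p) p$label %in% target_labels, polys)
  if (length(polys) == 0L) return(matrix(0, height, width))
  for (p in polys)
    if (nrow(p$points) < 3L) stop("degenerate polygon (<3 vertices)")
  m <- cpp_rasterize_polys(lapply(polys, `[[`, "points"),
                           as.integer(height), as.integer(width))
  matrix(as.numeric(m), height, width)
}

#' Screen tiles by crown content
#'
#' Keeps tile i iff its positive mask fraction strictly exceeds
#' `min_positive_frac` (default 0: at least one crown pixel) — a
#' reproducible proxy for manual "discernible crown" screening.
#'
#' @param masks list of binary masks.
#' @param min_positive_frac threshold in \[0, 1\].
#' @return integer vector of kept indices.
#' @export
screen_tiles <- function(masks, min_positive_frac = 0) {
  if (min_positive_frac < 0 || min_positive_frac > 1)
    stop("min_positive_frac must lie in [0, 1]")
  fr <- vapply(masks, function(m) mean(m), 1)
  which(fr > min_positive_frac)
}

rot90_arr <- function(x, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) {
    if (length(dim(x)) == 2L) x <- t(x[nrow(x):1, , drop = FALSE])
    else x <- aperm(x[dim(x)[1]:1, , , drop = FALSE], c(2, 1, 3))
  }
  x
}

flip_arr <- function(x, axis) {
  if (length(dim(x)) == 2L) {
    if (axis == "h") x[, ncol(x):1, drop = FALSE]
    else x[nrow(x):1, , drop = FALSE]
  } else {
    if (axis == "h") x[, dim(x)[2]:1, , drop = FALSE]
    else x[dim(x)[1]:1, , , drop = FALSE]
  }
}

resize_img <- function(x, H, W) {
  d2 <- length(dim(x)) == 2L
  xa <- if (d2) array(x, c(dim(x), 1L, 1L)) else
    array(x, c(dim(x), 1L))
  y <- cpp_resize_bilinear(xa, as.integer(H), as.integer(W))
  if (d2) matrix(y, H, W) else array(y, c(H, W, dim(x)[3]))
}

resize_mask <- function(x, H, W) {
  xa <- array(x, c(dim(x), 1L, 1L))
  matrix(cpp_resize_nearest(xa, as.integer(H), as.integer(W)), H, W)
}

center_crop <- function(x, H, W) {
  d <- dim(x)
  r0 <- (d[1] - H) %/% 2L
  c0 <- (d[2] - W) %/% 2L
  if (length(d) == 2L) x[r0 + seq_len(H), c0 + seq_len(W), drop = FALSE]
  else x[r0 + seq_len(H), c0 + seq_len(W), , drop = FALSE]
}

pad_center <- function(x, H, W) {
  d <- dim(x)
  r0 <- (H - d[1]) %/% 2L
  c0 <- (W - d[2]) %/% 2L
  if (length(d) == 2L) {
    out <- matrix(0, H, W)
    out[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- x
  } else {
    out <- array(0, c(H, W, d[3]))
    out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- x
  }
  out
}

#' Apply one geometric augmentation jointly to a multimodal sample
#'
#' The identical geometric transform is applied to the RGB array, the
#' MS array, and the mask; images are interpolated bilinearly, masks
#' nearest-neighbour (so they stay binary), and output size equals
#' input size. Supported ops:
#' \describe{
#'   \item{rot90}{`params$k` quarter-turns (default random).}
#'   \item{hflip, vflip}{horizontal / vertical mirror.}
#'   \item{scale_crop}{scale by `params$factor` (default random in
#'     \[0.8, 1.3\]) then center-crop (or center-pad when < 1).}
#'   \item{crop_resize}{random crop of fraction `params$frac` (default
#'     random in \[0.7, 1\]) then resize back.}
#' }
#'
#' @param sample a `multimodal_sample`.
#' @param op_spec op name, or `list(name =, ...params)`.
#' @param seed seed controlling any randomness in the op.
#' @return the augmented `multimodal_sample`.
#' @export
augment_sample <- function(sample, op_spec, seed = 1L) {
  if (is.character(op_spec)) op_spec <- list(name = op_spec)
  name <- op_spec$name
  known <- c("rot90", "hflip", "vflip", "scale_crop", "crop_resize")
  if (is.null(name) || !name %in% known)
    stop("unknown augmentation op '", name, "'; available: ",
         paste(known, collapse = ", "))
  H <- dim(sample$rgb)[1]; W <- dim(sample$rgb)[2]
  with_seed(seed, {
    app <- switch(
      name,
      rot90 = {
        k <- if (!is.null(op_spec$k)) op_spec$k else sample(0:3, 1)
        list(img = function(x) rot90_arr(x, k),
             msk = function(x) rot90_arr(x, k))
      },
      hflip = list(img = function(x) flip_arr(x, "h"),
                   msk = function(x) flip_arr(x, "h")),
      vflip = list(img = function(x) flip_arr(x, "v"),
                   msk = function(x) flip_arr(x, "v")),
      scale_crop = {
        f <- if (!is.null(op_spec$factor)) op_spec$factor else
          runif(1, 0.8, 1.3)
        H2 <- max(1L, as.integer(round(H * f)))
        W2 <- max(1L, as.integer(round(W * f)))
        fit <- function(x) {
          if (H2 >= H && W2 >= W) center_crop(x, H, W) else
            pad_center(center_crop(x, min(H2, H), min(W2, W)), H, W)
        }
        list(img = function(x) fit(resize_img(x, H2, W2)),
             msk = function(x) fit(resize_mask(x, H2, W2)))
      },
      crop_resize = {
        f <- if (!is.null(op_spec$frac)) op_spec$frac else runif(1, 0.7, 1)
        h2 <- max(2L, as.integer(round(H * f)))
        w2 <- max(2L, as.integer(round(W * f)))
        r0 <- sample.int(H - h2 + 1L, 1L) - 1L
        c0 <- sample.int(W - w2 + 1L, 1L) - 1L
        crop <- function(x) {
          if (length(dim(x)) == 2L)
            x[r0 + seq_len(h2), c0 + seq_len(w2), drop = FALSE]
          else x[r0 + seq_len(h2), c0 + seq_len(w2), , drop = FALSE]
        }
        list(img = function(x) resize_img(crop(x), H, W),
             msk = function(x) resize_mask(crop(x), H, W))
      })
    out <- sample
    out$rgb <- app$img(sample$rgb)
    out$ms <- app$img(sample$ms)
    out$mask <- app$msk(sample$mask)
    out$mask[out$mask > 0.5] <- 1
    out$mask[out$mask <= 0.5] <- 0
    # region indices refer to the pre-transform geometry
    out$meta$regions <- NULL
    out
  })
}

#' Randomly split sample ids into train and validation sets
#'
#' Deterministic shuffle by seed; the train count is round-half-up of
#' `train_frac * n`; the split is an exact disjoint partition. Test
#' data are expected to come from a separate source and never pass
#' through this split.
#'
#' @param ids vector of ids.
#' @param train_frac fraction assigned to training (0 < f < 1).
#' @param seed shuffle seed.
#' @return list with `train` and `val` id vectors.
#' @export
split_samples <- function(ids, train_frac = 0.8, seed = 1L) {
  if (length(ids) == 0L) stop("empty id list")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly in (0, 1)")
  n <- length(ids)
  n_train <- as.integer(floor(train_frac * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  list(train = ids[sort(perm[seq_len(n_train)])],
       val = ids[sort(perm[n_train + seq_len(n - n_train)])])
}
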