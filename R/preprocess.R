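# Preprocessing: remove device-annotation and background regions by
# thresholding plus largest-connected-component cropping, then sample the
# model's input frames from a window around the reader-selected keyframe.

#' Threshold an 8-bit grayscale image to a binary mask
#'
#' Pixels strictly greater than `threshold` become foreground. The strict
#' inequality is a fixed convention: a uniform image at exactly the threshold
#' value yields an all-background mask.
#'
#' @param image Numeric or integer matrix of intensities in 0..255.
#' @param threshold Intensity threshold (default 50).
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(image, threshold = 50) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty single-channel matrix")
  image > threshold
}

# Connected-component labelling with 8-connectivity, two-pass union-find.
# EBImage's labeller uses 4-connectivity, which merges fewer diagonal
# touches than the pinned convention, so this is implemented directly.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1L && labels[i - 1L, j] > 0L) nb <- c(nb, labels[i - 1L, j])
      if (j > 1L) {
        if (labels[i, j - 1L] > 0L) nb <- c(nb, labels[i, j - 1L])
        if (i > 1L && labels[i - 1L, j - 1L] > 0L) nb <- c(nb, labels[i - 1L, j - 1L])
        if (i < h && labels[i + 1L, j - 1L] > 0L) nb <- c(nb, labels[i + 1L, j - 1L])
      }
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        m <- min(roots)
        labels[i, j] <- m
        for (r in roots) parent[r] <- m
      }
    }
  }
  if (nxt > 0L) {
    # resolve to root labels and renumber densely
    roots <- vapply(seq_len(nxt), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    pos <- which(labels > 0L)
    labels[pos] <- dense[labels[pos]]
  }
  labels
}

#' Bounding box of the largest 8-connected foreground component
#'
#' Components use 8-connectivity; ties in pixel count are broken by the
#' smallest top-left corner (first by `y0`, then `x0`). Coordinates are
#' 0-based and half-open: the box covers columns `[x0, x1)` and rows
#' `[y0, y1)`.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return A `crop_region` list with fields `x0`, `y0`, `x1`, `y1`.
#' @export
largest_component_bbox <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stop("no foreground pixels in mask")
  labels <- label_components(mask)
  counts <- tabulate(labels[labels > 0L])
  boxes <- lapply(seq_along(counts), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    list(count = counts[k],
         y0 = min(idx[, 1]) - 1L, y1 = max(idx[, 1]),
         x0 = min(idx[, 2]) - 1L, x1 = max(idx[, 2]))
  })
  ord <- order(-vapply(boxes, `[[`, numeric(1), "count"),
               vapply(boxes, `[[`, numeric(1), "y0"),
               vapply(boxes, `[[`, numeric(1), "x0"))
  b <- boxes[[ord[1]]]
  structure(list(x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1),
            class = "crop_region")
}

# Bilinear resize of a single matrix to (h, w), via EBImage.
resize_bilinear <- function(m, h, w) {
  if (nrow(m) == h && ncol(m) == w) return(m)
  # EBImage's first image dimension is x; our matrices use rows = y, so the
  # matrix row count maps onto EBImage's `w` argument.
  out <- EBImage::resize(EBImage::Image(m), w = h, h = w)
  as.matrix(EBImage::imageData(out))
}

#' Crop a frame sequence to a region and resize
#'
#' The crop region is computed once (typically from the keyframe) and applied
#' identically to every frame, then each crop is resized to `out_size` with
#' bilinear interpolation.
#'
#' @param frames List of numeric matrices, all the same size.
#' @param region A `crop_region` from [largest_component_bbox()].
#' @param out_size Integer vector `c(height, width)`; `NULL` keeps the crop
#'   size.
#' @return List of matrices of size `out_size`.
#' @export
crop_frames <- function(frames, region, out_size = NULL) {
  stopifnot(length(frames) >= 1L)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  if (region$x0 < 0 || region$y0 < 0 || region$x1 > w || region$y1 > h ||
      region$x1 <= region$x0 || region$y1 <= region$y0)
    stop("crop region lies outside frame bounds")
  rows <- (region$y0 + 1L):region$y1
  cols <- (region$x0 + 1L):region$x1
  lapply(frames, function(f) {
    cr <- f[rows, cols, drop = FALSE]
    if (is.null(out_size)) cr else resize_bilinear(cr, out_size[1], out_size[2])
  })
}

#' Compute the crop region of a CEUS sample from its keyframe
#'
#' Applies [binarize()] at the given threshold to the keyframe and takes the
#' bounding box of the largest 8-connected component, which excludes the
#' annotation band and black margins when they are disconnected from the
#' imaging content.
#'
#' @param sample A `ceus_sample`.
#' @param threshold Binarization threshold (default 50).
#' @return A `crop_region`.
#' @export
sample_crop_region <- function(sample, threshold = 50) {
  key <- sample$frames[[sample$keyframe_index + 1L]]
  largest_component_bbox(binarize(key, threshold))
}

#' Sample input frame indices from the keyframe window
#'
#' Takes `n_out` strictly increasing indices from the window
#' `[keyframe - half_window, keyframe + half_window]`, shifted (never shrunk)
#' to stay inside `[0, n_total)`, chosen as the floor of `n_out` evenly
#' spaced real positions spanning the window inclusive.
#'
#' @param n_total Total number of frames in the video.
#' @param keyframe 0-based keyframe index.
#' @param half_window Half width of the sampling window (default 5).
#' @param n_out Number of frames to sample (default 10).
#' @return Integer vector of `n_out` 0-based frame indices.
#' @examples
#' sample_frames(120, 50) # ten indices within [45, 55]
#' @export
sample_frames <- function(n_total, keyframe, half_window = 5, n_out = 10) {
  if (keyframe < 0 || keyframe >= n_total) stop("`keyframe` out of range")
  win <- 2L * as.integer(half_window) + 1L
  if (n_total < n_out) stop("video shorter than requested frame count")
  if (win < n_out) stop("keyframe window shorter than `n_out`")
  lo <- keyframe - half_window
  hi <- keyframe + half_window
  if (lo < 0) { hi <- hi - lo; lo <- 0 }
  if (hi > n_total - 1) { lo <- lo - (hi - (n_total - 1)); hi <- n_total - 1 }
  if (lo < 0) stop("keyframe window shorter than `n_out` after clamping")
  pos <- seq(lo, hi, length.out = n_out)
  idx <- unique(as.integer(floor(pos)))
  stopifnot(length(idx) == n_out)
  idx
}

#' Preprocess a CEUS sample into model-ready frames
#'
#' Computes the keyframe crop region, samples `n_out` frames from the
#' keyframe window, crops and resizes them, and scales intensities to [0, 1].
#'
#' @param sample A `ceus_sample`.
#' @param out_size Model input size `c(height, width)`.
#' @param threshold Binarization threshold.
#' @param half_window,n_out Frame-window sampling parameters.
#' @return List with `frames` (list of `n_out` matrices in [0,1]), `region`,
#'   `frame_indices`, and the sample's label fields.
#' @export
preprocess_sample <- function(sample, out_size = c(64, 64), threshold = 50,
                              half_window = 5, n_out = 10) {
  region <- sample_crop_region(sample, threshold)
  idx <- sample_frames(length(sample$frames), sample$keyframe_index,
                       half_window, n_out)
  frames <- crop_frames(sample$frames[idx + 1L], region, out_size)
  frames <- lapply(frames, function(f) pmin(pmax(f / 255, 0), 1))
  list(frames = frames, region = region, frame_indices = idx,
       patient_id = sample$patient_id, class_label = sample$class_label,
       clinical_attributes = sample$clinical_attributes)
}
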