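#' Flatten large-scale illumination gradients
#'
#' Estimates the slowly varying illumination field by heavy smoothing
#' (box-filter cascade approximating a Gaussian whose standard deviation
#' is several times the largest expected nucleus radius), divides the
#' image by it, and rescales the result to \[0, 1\]. Structures much
#' smaller than the smoothing scale keep their local contrast; shading
#' across the field is removed.
#'
#' @param channel 2-D intensity matrix in \[0, 1\].
#' @param sigma Smoothing scale in pixels of the background estimate;
#'   defaults to 4 x the default upper nuclear radius bound (4 x 40).
#' @return Intensity matrix in \[0, 1\], same shape. An all-zero input is
#'   returned unchanged.
#' @export
normalize_illumination <- function(channel, sigma = 160) {
  if (max(channel) <= 0) return(channel)
  bg <- blur_background(channel, sigma)
  bg <- pmax(bg, max(bg) * 1e-3)
  out <- channel / bg
  # near-constant ratio (e.g. uniform input): rescaling would only
  # amplify numerical dust, so return the plainly rescaled channel
  if (diff(range(out)) < 1e-8 * max(out))
    return(channel / max(channel))
  out <- out - min(out)
  out / max(out)
}

#' Threshold the cytoskeletal channel into a binary tube image
#'
#' The cut is `tube_thresh` times an automatic global threshold chosen by
#' maximising between-class variance (Otsu) on 256 intensity bins of the
#' normalised raster; pixels strictly above the cut are foreground.
#' Lowering `tube_thresh` therefore always yields a superset of the
#' foreground (it detects fainter staining).
#'
#' @param channel Normalised 2-D intensity matrix in \[0, 1\].
#' @param tube_thresh Positive multiplicative scale on the automatic
#'   threshold (default 1).
#' @return Logical matrix, `TRUE` = tube foreground. A flat raster gives
#'   an empty mask.
#' @export
binarize_tubes <- function(channel, tube_thresh = 1) {
  stopifnot(tube_thresh > 0)
  channel > tube_thresh * auto_threshold(channel)
}

#' Fill holes and smooth the borders of a binary mask
#'
#' Interior holes are filled, then the border is smoothed by a
#' morphological closing followed by an opening, both with a disc-shaped
#' structuring element of radius `fill_size`.
#'
#' @param mask Logical/binary matrix.
#' @param fill_size Disc radius in pixels.
#' @return Logical matrix, same shape.
#' @export
fill_and_smooth <- function(mask, fill_size = 10) {
  m <- mask != 0
  if (!any(m)) return(m)
  b <- disc_brush(fill_size)
  m <- em(EBImage::fillHull(m)) != 0
  m <- em(EBImage::opening(EBImage::closing(m, b), b)) != 0
  m
}

#' Delete connected components below a size floor
#'
#' Components (8-connectivity) whose pixel area is strictly below
#' `min_size` are removed; survivors are relabelled with contiguous
#' positive integers and their areas recorded. A component of exactly
#' `min_size` pixels survives.
#'
#' @param mask Logical/binary matrix.
#' @param min_size Minimum component area in pixels.
#' @return A `tube_mask`: list with `mask` (logical), `labels` (integer
#'   matrix, 0 = background) and `areas` (named integer vector, per
#'   retained label).
#' @export
remove_small_objects <- function(mask, min_size = 500) {
  L <- label8(mask)
  ar <- label_areas(L)
  keep <- as.integer(names(ar)[ar >= min_size])
  out <- matrix(0L, nrow(L), ncol(L))
  if (length(keep)) {
    sel <- L %in% keep
    out[sel] <- match(L[sel], keep)
  }
  structure(list(mask = out > 0L,
                 labels = out,
                 areas = label_areas(out)),
            class = "tube_mask")
}

#' Segment myotubes from the cytoskeletal channel
#'
#' Full tube pipeline: illumination normalisation, automatic
#' thresholding scaled by `tube_thresh`, hole filling and border
#' smoothing (disc radius `fill_size`), then removal of components
#' smaller than `smallest_myotube_pixel_count` pixels. Deterministic for
#' fixed input and parameters.
#'
#' @param channel 2-D intensity matrix of the myotube channel.
#' @param params A [myofuse_params()] object.
#' @return A `tube_mask` (see [remove_small_objects()]).
#' @export
segment_myotubes <- function(channel, params = myofuse_params()) {
  norm <- normalize_illumination(channel, sigma = 4 * params$max_circle_rad)
  bin <- binarize_tubes(norm, params$tube_thresh)
  sm <- fill_and_smooth(bin, params$fill_size)
  remove_small_objects(sm, params$smallest_myotube_pixel_count)
}

#' @export
print.tube_mask <- function(x, ...) {
  cat(sprintf("Myotube mask: %d component(s), %d foreground px\n",
              length(x$areas), sum(x$mask)))
  if (length(x$areas))
    cat("  areas (px):", paste(sort(as.integer(x$areas), decreasing = TRUE),
                               collapse = ", "), "\n")
  invisible(x)
}
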