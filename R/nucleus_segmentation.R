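#' Adaptive (Wiener-type) denoising of the nuclear channel
#'
#' Pixel-wise adaptive filter driven by local statistics in a square
#' window: where the local variance is close to the estimated noise
#' floor (the mean of all local variances) the local mean is returned,
#' and where the local variance is large the pixel is left nearly
#' untouched. This attenuates additive noise while preserving nuclear
#' edges.
#'
#' @param channel 2-D intensity matrix in \[0, 1\].
#' @param window Odd window size in pixels (default 5).
#' @return Denoised matrix in \[0, 1\]. A constant image is returned
#'   unchanged.
#' @export
denoise_nuclei <- function(channel, window = 5L) {
  stopifnot(window >= 1)
  h <- as.integer(window) %/% 2L
  mu <- box_mean(channel, h)
  v <- pmax(box_mean(channel^2, h) - mu^2, 0)
  noise <- mean(v)
  if (noise == 0) return(channel)
  gain <- pmax(v - noise, 0) / pmax(v, noise)
  out <- mu + gain * (channel - mu)
  pmin(pmax(out, 0), 1)
}

#' Threshold and clean the nuclear channel
#'
#' Automatic global threshold (between-class variance), hole filling,
#' closing/opening with a disc of radius `nuc_fill_size`, then removal of
#' components (8-connectivity) with area strictly below
#' `smallest_nucleus_pixel_count` or strictly above
#' `height x width / max_nuc_size_divisor` pixels (at defaults, blobs
#' larger than 1\% of the image are discarded; exactly 1\% survives).
#'
#' @param channel Denoised 2-D intensity matrix of the nuclear channel.
#' @param params A [myofuse_params()] object.
#' @return Logical matrix of accepted nuclear pixels.
#' @export
binarize_and_clean_nuclei <- function(channel, params = myofuse_params()) {
  mask <- channel > auto_threshold(channel)
  if (!any(mask)) return(mask)
  mask <- fill_and_smooth(mask, params$nuc_fill_size)
  L <- label8(mask)
  ar <- label_areas(L)
  max_area <- nrow(channel) * ncol(channel) / params$max_nuc_size_divisor
  keep <- as.integer(names(ar)[ar >= params$smallest_nucleus_pixel_count &
                                 ar <= max_area])
  L %in% keep & matrix(TRUE, nrow(L), ncol(L))
}

# annulus kernel for one Hough radius (capture band +-1 px, absorbing
# rasterisation of the mask boundary) and the matching full-perimeter
# vote: the boundary pixel count of an ideal rasterised disc of that
# radius
.hough_ring <- function(r) {
  n <- 2L * as.integer(ceiling(r)) + 5L
  c0 <- (n + 1L) / 2
  d <- sqrt((row(matrix(0, n, n)) - c0)^2 + (col(matrix(0, n, n)) - c0)^2)
  list(ring = (abs(d - r) <= 1) * 1,
       perimeter = sum(mask_boundary(d <= r)))
}

#' Detect rounded nuclei by a circle Hough transform
#'
#' Votes are accumulated on the boundary (edge map) of the cleaned
#' nuclear mask over integer radii in `[min_rad, max_rad]`. A
#' centre/radius candidate requires at least half of the theoretical
#' perimeter vote for its radius; candidates are reduced by greedy
#' non-maximum suppression so that no two accepted centres are closer
#' than `min_rad`. A candidate is finally accepted only if its circle
#' explains its connected component: at least 70\% of the component's
#' pixels must fall inside the circle, so single rounded nuclei are
#' claimed here while clusters of overlapping nuclei are left for the
#' watershed stage. Deterministic.
#'
#' @param mask Logical matrix of cleaned nuclear pixels.
#' @param min_rad,max_rad Radius bounds in pixels, `min_rad < max_rad`.
#' @param coverage_min Minimum fraction of the component's area the
#'   accepted circle must cover (default 0.7).
#' @return Data frame with columns `row`, `col`, `radius`, `score`
#'   (vote fraction), one row per detected nucleus, sorted row-major.
#' @export
hough_round_nuclei <- function(mask, min_rad = 15, max_rad = 40,
                               coverage_min = 0.7) {
  if (!(min_rad < max_rad) || min_rad <= 0)
    stop("parameter error: need 0 < min_rad < max_rad", call. = FALSE)
  empty <- data.frame(row = integer(0), col = integer(0),
                      radius = numeric(0), score = numeric(0))
  m <- mask != 0
  if (!any(m)) return(empty)
  edges <- mask_boundary(m) * 1
  radii <- seq(ceiling(min_rad), floor(max_rad))
  best_score <- matrix(0, nrow(m), ncol(m))
  best_rad <- matrix(0, nrow(m), ncol(m))
  for (r in radii) {
    rk <- .hough_ring(r)
    votes <- filter2_safe(edges, rk$ring)
    frac <- votes / rk$perimeter
    upd <- frac > best_score
    best_score[upd] <- frac[upd]
    best_rad[upd] <- r
  }
  cand <- which(best_score >= 0.5 & m, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  sc <- best_score[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  # greedy non-maximum suppression at min_rad
  acc <- matrix(0, 0, 2)
  acc_i <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (!nrow(acc) ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_rad^2) {
      acc <- rbind(acc, p)
      acc_i <- c(acc_i, i)
    }
  }
  # component-roundness gate
  L <- label8(m)
  ar <- label_areas(L)
  keep <- logical(length(acc_i))
  for (k in seq_along(acc_i)) {
    ri <- best_rad[cand[acc_i[k], , drop = FALSE]]
    p <- acc[k, ]
    lab <- L[p[1], p[2]]
    if (lab == 0L) next
    comp_area <- ar[[as.character(lab)]]
    ys <- max(1, p[1] - ri):min(nrow(m), p[1] + ri)
    xs <- max(1, p[2] - ri):min(ncol(m), p[2] + ri)
    sub <- L[ys, xs, drop = FALSE]
    dd <- outer((ys - p[1])^2, (xs - p[2])^2, "+")
    covered <- sum(sub == lab & dd <= ri^2)
    keep[k] <- covered / comp_area >= coverage_min
  }
  if (!any(keep)) return(empty)
  out <- data.frame(row = acc[keep, 1], col = acc[keep, 2],
                    radius = best_rad[cand[acc_i[keep], , drop = FALSE]],
                    score = sc[acc_i[keep]])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Erase Hough-detected circles from the nuclear mask
#'
#' @param mask Logical matrix.
#' @param detections Data frame from [hough_round_nuclei()].
#' @return The mask with all pixels inside each detected circle (radius
#'   + 0.5 px) set to `FALSE`.
#' @export
remove_round_nuclei <- function(mask, detections) {
  m <- mask != 0
  if (is.null(detections) || nrow(detections) == 0L) return(m)
  for (i in seq_len(nrow(detections))) {
    p <- detections[i, ]
    r <- p$radius + 0.5
    ys <- max(1, floor(p$row - r)):min(nrow(m), ceiling(p$row + r))
    xs <- max(1, floor(p$col - r)):min(ncol(m), ceiling(p$col + r))
    dd <- outer((ys - p$row)^2, (xs - p$col)^2, "+")
    m[ys, xs][dd <= r^2] <- FALSE
  }
  m
}

#' Split remaining nuclear clusters by watershed
#'
#' Watershed of the distance transform of the remaining nuclear regions,
#' with marker merging in place of raw regional maxima: fragments whose
#' distance-map peaks are closer than `min_circle_rad` are merged
#' (single linkage), which suppresses the over-segmentation that spurious
#' nearby maxima would otherwise cause. Fragments smaller than
#' `smallest_nucleus_pixel_count` pixels are discarded. Each surviving
#' fragment contributes one nucleus at its centroid (snapped to the
#' nearest fragment pixel if the centroid falls outside the fragment).
#'
#' @param remainder Logical matrix of nuclear pixels not claimed by the
#'   Hough stage.
#' @param params A [myofuse_params()] object.
#' @return Data frame with columns `row`, `col`, `area`, one row per
#'   fragment, sorted row-major; plus attribute `labels` (integer matrix
#'   of the merged fragments).
#' @export
watershed_split_remaining <- function(remainder, params = myofuse_params()) {
  empty <- data.frame(row = numeric(0), col = numeric(0), area = numeric(0))
  m <- remainder != 0
  hw <- dim(m)
  if (!any(m)) {
    attr(empty, "labels") <- matrix(0L, hw[1], hw[2])
    return(empty)
  }
  dm <- em(EBImage::distmap(m))
  ws <- em(EBImage::watershed(EBImage::Image(dm), tolerance = 0.1, ext = 1))
  storage.mode(ws) <- "integer"
  n <- max(ws)
  if (n == 0L) {
    attr(empty, "labels") <- matrix(0L, hw[1], hw[2])
    return(empty)
  }
  # distance-map peak of each watershed fragment
  peaks <- t(vapply(seq_len(n), function(l) {
    idx <- which(ws == l)
    p <- idx[which.max(dm[idx])]
    c((p - 1L) %% hw[1] + 1L, (p - 1L) %/% hw[1] + 1L)
  }, numeric(2)))
  # single-linkage merge of fragments with peaks closer than min_circle_rad
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1L) {
    d2 <- as.matrix(stats::dist(peaks))^2
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (d2[i, j] < params$min_circle_rad^2) {
        ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <- ri
      }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  merged <- ws
  merged[ws > 0L] <- relab[ws[ws > 0L]]
  ar <- label_areas(merged)
  keep <- as.integer(names(ar)[ar >= params$smallest_nucleus_pixel_count])
  rows <- numeric(0); cols <- numeric(0); areas <- numeric(0)
  out_lab <- matrix(0L, hw[1], hw[2])
  for (k in seq_along(keep)) {
    idx <- which(merged == keep[k], arr.ind = TRUE)
    ctr <- colMeans(idx)
    ci <- round(ctr)
    if (ci[1] < 1 || ci[1] > hw[1] || ci[2] < 1 || ci[2] > hw[2] ||
        merged[ci[1], ci[2]] != keep[k]) {
      j <- which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
      ci <- idx[j, ]
    }
    rows <- c(rows, ci[1]); cols <- c(cols, ci[2]); areas <- c(areas, nrow(idx))
    out_lab[merged == keep[k]] <- k
  }
  out <- data.frame(row = rows, col = cols, area = areas)
  out <- out[order(out$row, out$col), , drop = FALSE]
  attr(out, "labels") <- out_lab
  out
}

#' Detect individual nuclei in the DAPI channel
#'
#' Full nuclear pipeline: adaptive denoising, automatic thresholding and
#' morphological cleaning with the Table-of-parameters size gates,
#' detection of rounded nuclei by circle Hough transform, removal of the
#' detected circles, and watershed splitting of the remaining clustered
#' regions. The result is the union of both detection routes.
#'
#' @param channel 2-D intensity matrix of the nuclear channel.
#' @param params A [myofuse_params()] object.
#' @return A `nucleus_set`: list with `centres` (n x 2 matrix, row/col),
#'   `size` (radius in px for Hough detections, area in px for watershed
#'   detections), `provenance` (`"hough"` or `"watershed"`), `mask`
#'   (cleaned nuclear mask) and `n` (total count). Centres are sorted
#'   row-major.
#' @export
detect_nuclei <- function(channel, params = myofuse_params()) {
  den <- denoise_nuclei(channel)
  mask <- binarize_and_clean_nuclei(den, params)
  hough <- hough_round_nuclei(mask, params$min_circle_rad,
                              params$max_circle_rad)
  remainder <- remove_round_nuclei(mask, hough)
  ws <- watershed_split_remaining(remainder, params)
  centres <- rbind(as.matrix(hough[, c("row", "col")]),
                   as.matrix(ws[, c("row", "col")]))
  size <- c(hough$radius, ws$area)
  prov <- c(rep("hough", nrow(hough)), rep("watershed", nrow(ws)))
  if (nrow(centres)) {
    o <- order(centres[, 1], centres[, 2])
    dup <- duplicated(centres[o, , drop = FALSE])
    o <- o[!dup]
    centres <- centres[o, , drop = FALSE]
    size <- size[o]
    prov <- prov[o]
  }
  colnames(centres) <- c("row", "col")
  structure(list(centres = centres, size = size, provenance = prov,
                 mask = mask, ws_labels = attr(ws, "labels"),
                 hough = hough, n = nrow(centres)),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("Nucleus set: %d nuclei (%d hough, %d watershed), %d mask px\n",
              x$n, sum(x$provenance == "hough"),
              sum(x$provenance == "watershed"), sum(x$mask)))
  invisible(x)
}
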