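# Rendering of the four diagnostic overlays. All overlays are H x W x 3
# arrays in [0,1], written as 8-bit RGB PNGs by write_outputs().

.paint <- function(rgb, sel, col) {
  for (k in 1:3) { p <- rgb[, , k]; p[sel] <- col[k]; rgb[, , k] <- p }
  rgb
}

.cross_mask <- function(h, w, rows, cols, arm = 4L) {
  m <- matrix(FALSE, h, w)
  for (i in seq_along(rows)) {
    r <- round(rows[i]); c <- round(cols[i])
    rr <- max(1, r - arm):min(h, r + arm)
    cc <- max(1, c - arm):min(w, c + arm)
    m[rr, c] <- TRUE
    m[r, cc] <- TRUE
  }
  m
}

.circle_mask <- function(h, w, rows, cols, radii) {
  m <- matrix(FALSE, h, w)
  for (i in seq_along(rows)) {
    r0 <- rows[i]; c0 <- cols[i]; rad <- radii[i]
    th <- seq(0, 2 * pi, length.out = max(16L, round(2 * pi * rad)))
    rr <- pmin(pmax(round(r0 + rad * sin(th)), 1), h)
    cc <- pmin(pmax(round(c0 + rad * cos(th)), 1), w)
    m[cbind(rr, cc)] <- TRUE
  }
  m
}

.gray_rgb <- function(x) array(rep(pmin(pmax(x, 0), 1), 3), c(dim(x), 3))

render_overlays <- function(img, tubes, nuclei, records, params) {
  h <- nrow(tubes$labels); w <- ncol(tubes$labels)
  tube_ch <- select_channel(img, params$myotube_channel)
  nuc_ch <- select_channel(img, params$nuc_channel)

  # 1. combined: tubes green / nuclei blue composite, retained tube
  #    borders yellow, other tube borders grey, nucleus centres marked
  #    (white = in retained tube, magenta = elsewhere)
  base <- array(0, c(h, w, 3))
  base[, , 2] <- tube_ch
  base[, , 3] <- nuc_ch
  ret_labels <- records$label[which(records$retained)]
  ret_border <- mask_boundary(tubes$labels %in% ret_labels &
                                matrix(TRUE, h, w))
  oth_border <- mask_boundary(tubes$mask) & !ret_border
  combined <- .paint(base, oth_border, c(0.5, 0.5, 0.5))
  combined <- .paint(combined, ret_border, c(1, 1, 0))
  if (nuclei$n > 0) {
    assignment <- attr(records, "assignment")
    in_ret <- assignment %in% ret_labels
    if (any(in_ret))
      combined <- .paint(combined,
                         .cross_mask(h, w, nuclei$centres[in_ret, 1],
                                     nuclei$centres[in_ret, 2]), c(1, 1, 1))
    if (any(!in_ret))
      combined <- .paint(combined,
                         .cross_mask(h, w, nuclei$centres[!in_ret, 1],
                                     nuclei$centres[!in_ret, 2]), c(1, 0, 1))
  }

  # 2. estimated nucleus centroids over the nuclear channel
  centroids <- .gray_rgb(nuc_ch)
  if (nuclei$n > 0)
    centroids <- .paint(centroids,
                        .cross_mask(h, w, nuclei$centres[, 1],
                                    nuclei$centres[, 2]), c(1, 0, 0))

  # 3. approximate nucleus borders over the nuclear channel
  borders <- .gray_rgb(nuc_ch)
  borders <- .paint(borders, mask_boundary(nuclei$mask), c(0, 1, 0))

  # 4. segmentation stages: cleaned mask dim grey, Hough circles cyan,
  #    watershed fragment borders orange
  stages <- .gray_rgb(nuclei$mask * 0.4)
  if (!is.null(nuclei$ws_labels)) {
    wsb <- mask_boundary(nuclei$ws_labels > 0L)
    # internal watershed lines: fragment boundaries against other fragments
    stages <- .paint(stages, wsb, c(1, 0.55, 0))
  }
  if (!is.null(nuclei$hough) && nrow(nuclei$hough) > 0)
    stages <- .paint(stages,
                     .circle_mask(h, w, nuclei$hough$row, nuclei$hough$col,
                                  nuclei$hough$radius), c(0, 1, 1))

  list(combined = combined, centroids = centroids,
       borders = borders, stages = stages)
}
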