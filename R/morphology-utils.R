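# Internal raster helpers shared by the segmentation modules.
# All rasters are plain numeric/logical/integer matrices indexed [row, col];
# EBImage objects are unwrapped immediately after each call.

# EBImage Image -> plain matrix
em <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# disc structuring element of radius r (odd-sized brush)
disc_brush <- function(r) {
  EBImage::makeBrush(2L * as.integer(ceiling(r)) + 1L, shape = "disc")
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged afterwards with union-find.
label8 <- function(mask) {
  L <- em(EBImage::bwlabel(mask != 0))
  storage.mode(L) <- "integer"
  n <- max(L)
  if (n <= 1L) return(L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  h <- nrow(L); w <- ncol(L)
  diag_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    unique(cbind(a[keep], b[keep]))
  }
  prs <- rbind(
    diag_pairs(L[-h, -w], L[-1, -1]),   # shift (+1,+1)
    diag_pairs(L[-h, -1], L[-1, -w])    # shift (+1,-1)
  )
  if (nrow(prs)) for (k in seq_len(nrow(prs))) union2(prs[k, 1], prs[k, 2])
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- L
  out[L > 0L] <- relab[L[L > 0L]]
  out
}

# per-label pixel counts of a label matrix (names = label ids)
label_areas <- function(labels) {
  v <- labels[labels > 0L]
  if (!length(v)) return(integer(0))
  tab <- tabulate(v)
  stats::setNames(tab, seq_along(tab))[tab > 0]
}

# one-pixel-thick boundary of a binary mask (pixels losing a 4-neighbour)
mask_boundary <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  inner <- m
  inner[] <- FALSE
  if (h > 2 && w > 2)
    inner[2:(h - 1), 2:(w - 1)] <-
      m[2:(h - 1), 2:(w - 1)] & m[1:(h - 2), 2:(w - 1)] & m[3:h, 2:(w - 1)] &
      m[2:(h - 1), 1:(w - 2)] & m[2:(h - 1), 3:w]
  m & !inner
}

# running-mean box filter along rows and columns via cumulative sums,
# replicate boundary; h = half-width
box_mean <- function(x, h) {
  if (h < 1) return(x)
  run1 <- function(m) {           # along columns of m
    nr <- nrow(m)
    if (nr == 1L) return(m)
    hh <- min(h, nr - 1L)
    mp <- rbind(m[rep(1L, hh), , drop = FALSE], m, m[rep(nr, hh), , drop = FALSE])
    cs <- apply(mp, 2L, cumsum)
    zeros <- matrix(0, 1L, ncol(m))
    (cs[(2L * hh + 1L):nrow(cs), , drop = FALSE] -
       rbind(zeros, cs[seq_len(nrow(cs) - 2L * hh - 1L), , drop = FALSE])) / (2L * hh + 1L)
  }
  t(run1(t(run1(x))))
}

# large-kernel Gaussian-like smoothing: 3 box-filter passes whose cascade
# approximates a Gaussian of standard deviation sigma (half-width from the
# box-variance identity var = (2h+1)^2/12 per pass)
blur_background <- function(x, sigma) {
  h <- max(1L, as.integer(round(sqrt(sigma^2 * 12 / 3) / 2)))
  for (i in 1:3) x <- box_mean(x, h)
  x
}

# between-class-variance (Otsu) automatic global threshold on 256 bins;
# returns a cut value: pixels strictly above it are foreground
auto_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  if (diff(range(v)) == 0) return(Inf)   # flat image: nothing is foreground
  EBImage::otsu(EBImage::Image(matrix(v, nrow = nrow(x))),
                range = c(0, 1), levels = levels)
}

# crop-safe linear filter: pads x (zeros) when the kernel exceeds its size
filter2_safe <- function(x, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- max(0L, kh - nrow(x)); pw <- max(0L, kw - ncol(x))
  if (ph == 0L && pw == 0L)
    return(em(EBImage::filter2(x, kern, boundary = 0)))
  xp <- matrix(0, nrow(x) + 2L * ph, ncol(x) + 2L * pw)
  xp[ph + seq_len(nrow(x)), pw + seq_len(ncol(x))] <- x
  f <- em(EBImage::filter2(xp, kern, boundary = 0))
  f[ph + seq_len(nrow(x)), pw + seq_len(ncol(x))]
}
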