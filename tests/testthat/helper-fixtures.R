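# Shared fixtures, built once per test run. Small fields keep the suite
# fast; the fuzzing parameter set shrinks the nuclear radius prior so
# that default-size structures fit a 288 px field.

# parameters scaled to small fuzz fields (nuclei r in [10, 13])
fuzz_params <- function(...) {
  myofuse_params(min_circle_rad = 8, max_circle_rad = 20,
                 smallest_nucleus_pixel_count = 250, ...)
}

fuzz_culture <- function(seed, ...) {
  defaults <- list(height = 320, width = 320, n_tubes = 1, n_myoblasts = 1,
                   nuclei_per_tube = 3, n_free_nuclei = 3,
                   nucleus_radius_range = c(10, 13), noise_sigma = 0.02,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(make_culture, args)
}

# hard two-level intensity raster from a binary mask
two_level <- function(mask, lo = 0.1, hi = 0.9) {
  out <- matrix(lo, nrow(mask), ncol(mask))
  out[mask != 0] <- hi
  out
}

draw_disc_mask <- function(h, w, cy, cx, r) {
  m <- matrix(FALSE, h, w)
  m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- TRUE
  m
}

# independent between-class-variance threshold oracle: exhaustive sweep
# over the 256-bin histogram
otsu_oracle <- function(x, levels = 256L) {
  br <- seq(0, 1, length.out = levels + 1L)
  cnt <- tabulate(findInterval(as.numeric(x), br, rightmost.closed = TRUE),
                  nbins = levels)
  mids <- (br[-1] + br[-(levels + 1L)]) / 2
  n <- sum(cnt)
  best <- -Inf; best_t <- NA_real_
  for (k in seq_len(levels - 1L)) {
    w0 <- sum(cnt[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(cnt[1:k] * mids[1:k]) / sum(cnt[1:k])
    mu1 <- sum(cnt[(k + 1):levels] * mids[(k + 1):levels]) /
      sum(cnt[(k + 1):levels])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- br[k + 1L] }
  }
  best_t
}

# brute-force nucleus-to-tube assignment oracle: per-centre component
# lookup by exhaustive point-in-component test
assignment_oracle <- function(centres, labels) {
  vapply(seq_len(nrow(centres)), function(i) {
    r <- round(centres[i, 1]); c <- round(centres[i, 2])
    found <- 0L
    for (l in setdiff(unique(as.integer(labels)), 0L)) {
      idx <- which(labels == l, arr.ind = TRUE)
      if (any(idx[, 1] == r & idx[, 2] == c)) { found <- l; break }
    }
    found
  }, integer(1))
}

write_tmp_tiff <- function(img, name = "img.tif", dir = tempdir()) {
  path <- file.path(dir, name)
  write_culture_tiff(img, path)
  path
}
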