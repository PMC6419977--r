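test_that("illumination normalisation flattens shading but keeps flat fields flat", {
  u <- matrix(0.4, 64, 64)
  nu <- normalize_illumination(u, sigma = 40)
  expect_lt(diff(range(nu)), 1e-9)
  z <- matrix(0, 64, 64)
  expect_identical(normalize_illumination(z, sigma = 40), z)
})

test_that("disc/background contrast varies <= 10% across a shading gradient", {
  # discs near the 4 corners of a field with strong linear shading; the
  # background-estimate scale must sit between the structure size and
  # the field size for flattening to work
  h <- 400; w <- 400
  shade <- matrix(seq(0.45, 1, length.out = w), h, w, byrow = TRUE)
  base <- matrix(0.15, h, w)
  ctrs <- list(c(88, 88), c(88, 312), c(312, 88), c(312, 312))
  for (p in ctrs) base[draw_disc_mask(h, w, p[1], p[2], 18)] <- 0.75
  img <- base * shade
  norm <- normalize_illumination(img, sigma = 60)
  contrast <- vapply(ctrs, function(p) {
    disc <- draw_disc_mask(h, w, p[1], p[2], 12)
    ring <- draw_disc_mask(h, w, p[1], p[2], 40) &
      !draw_disc_mask(h, w, p[1], p[2], 26)
    mean(norm[disc]) - mean(norm[ring])
  }, numeric(1))
  expect_lt((max(contrast) - min(contrast)) / mean(contrast), 0.10)
  # before normalisation the same contrast spread is far larger
  raw <- vapply(ctrs, function(p) {
    disc <- draw_disc_mask(h, w, p[1], p[2], 12)
    ring <- draw_disc_mask(h, w, p[1], p[2], 40) &
      !draw_disc_mask(h, w, p[1], p[2], 26)
    mean(img[disc]) - mean(img[ring])
  }, numeric(1))
  expect_gt((max(raw) - min(raw)) / mean(raw), 0.10)
})

test_that("automatic threshold matches the between-class-variance sweep oracle", {
  set.seed(7)
  for (i in 1:5) {
    mask <- draw_disc_mask(80, 80, 40, 40, 8 + 2 * i)
    x <- two_level(mask, lo = runif(1, 0.05, 0.3), hi = runif(1, 0.6, 0.95))
    x <- pmin(pmax(x + rnorm(length(x), 0, 0.02), 0), 1)
    thr_o <- otsu_oracle(x)
    m_pkg <- binarize_tubes(x, 1)
    expect_identical(m_pkg, x > thr_o)
  }
  # exact two-level image: exactly the bright pixels selected
  mask <- draw_disc_mask(60, 60, 30, 30, 12)
  x <- two_level(mask, 0.2, 0.8)
  expect_identical(binarize_tubes(x, 1), mask)
})

test_that("foreground area is non-increasing in tube_thresh; low limit takes all", {
  set.seed(8)
  x <- matrix(runif(80 * 80), 80, 80)
  x[20:50, 20:50] <- pmin(x[20:50, 20:50] + 0.5, 1)
  areas <- vapply(c(0.5, 0.8, 0.95, 1, 1.2, 2),
                  function(s) sum(binarize_tubes(x, s)), numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_gt(sum(binarize_tubes(x, 0.95)), sum(binarize_tubes(x, 1)))
  expect_identical(sum(binarize_tubes(x, 1e-9)), sum(x > 0))
  # flat raster: empty mask, no error
  expect_false(any(binarize_tubes(matrix(0, 10, 10), 1)))
})

test_that("fill_and_smooth fills holes and removes edge serrations", {
  m <- draw_disc_mask(80, 80, 40, 40, 20)
  hole <- draw_disc_mask(80, 80, 40, 40, 2)
  expect_true(all(fill_and_smooth(m & !hole, 10)[hole]))
  empty <- matrix(FALSE, 30, 30)
  expect_identical(fill_and_smooth(empty, 10), empty)
  # serrated rectangle edge: 1-px notches smoothed away, area change < 5%
  rect <- matrix(FALSE, 90, 90)
  rect[25:65, 25:65] <- TRUE
  serr <- rect
  serr[25, seq(25, 65, by = 2)] <- FALSE   # comb of notches along one edge
  sm <- fill_and_smooth(serr, 10)
  expect_true(all(sm[25, 40:50]))          # notches closed along the flat edge
  # identical to the ideal rectangle after the same smoothing
  expect_lt(sum(abs(sm - fill_and_smooth(rect, 10))) / sum(rect), 0.01)
})

test_that("smoothing never creates foreground far from existing foreground", {
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(70 * 70) > 0.97, 70, 70)
    m <- m | draw_disc_mask(70, 70, 35, 35, 12)
    out <- fill_and_smooth(m, 6)
    filled <- EBImage::imageData(EBImage::fillHull(m)) != 0
    reach <- EBImage::imageData(
      EBImage::dilate(filled, EBImage::makeBrush(15, "disc"))) != 0
    expect_false(any(out & !reach))
  }
})

test_that("small-object removal keeps exactly the components at/above the floor", {
  m <- matrix(FALSE, 120, 200)
  m[10:59, 10:19] <- TRUE              # 50 x 10 = 500 px
  m[70:115, 30:40] <- FALSE
  m[70:112, 100:110] <- TRUE           # 43 x 11 = 473 px
  m[15:40, 150:170] <- TRUE            # 26 x 21 = 546 px
  tm <- remove_small_objects(m, 500)
  expect_s3_class(tm, "tube_mask")
  expect_identical(sort(as.integer(tm$areas)), c(500L, 546L))
  expect_gte(min(tm$areas), 500)
  # 499 vs 500 on direct components
  m2 <- matrix(FALSE, 60, 120)
  m2[6:55, 5:14] <- TRUE               # 50 x 10 = 500 px
  m2[6:55, 60:69] <- TRUE              # 500 px minus one corner = 499 px
  m2[6, 60] <- FALSE
  tm2 <- remove_small_objects(m2, 500)
  expect_identical(as.integer(tm2$areas), 500L)
  # idempotence and no-op floor
  tm3 <- remove_small_objects(tm2$mask, 500)
  expect_identical(tm3$mask, tm2$mask)
  expect_length(remove_small_objects(m, 1)$areas, 3L)
  expect_length(remove_small_objects(matrix(FALSE, 10, 10), 1)$areas, 0L)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one component
  tm <- remove_small_objects(m, 1)
  expect_length(tm$areas, 1L)
  expect_identical(as.integer(tm$areas), 2L)
})

test_that("full tube segmentation keeps large elongated blobs and drops debris", {
  h <- 300; w <- 300
  ch <- matrix(0.08, h, w)
  ch[40:79, 30:79] <- 0.85     # 40 x 50 = 2000 px
  ch[150:177, 40:68] <- 0.85   # 28 x 29 = 812 px
  ch[220:236, 200:217] <- 0.85 # 17 x 18 = 306 px, below floor after smoothing
  tm <- segment_myotubes(ch, myofuse_params())
  expect_length(tm$areas, 2L)
  expect_gte(min(tm$areas), 500)
  # determinism and blank input
  tm2 <- segment_myotubes(ch, myofuse_params())
  expect_identical(tm$labels, tm2$labels)
  blank <- segment_myotubes(matrix(0, 100, 100), myofuse_params())
  expect_length(blank$areas, 0L)
})
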