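# minimal hand-built nucleus_set
mk_nuclei <- function(centres, mask) {
  structure(list(centres = centres, size = rep(20, nrow(centres)),
                 provenance = rep("hough", nrow(centres)),
                 mask = mask, ws_labels = matrix(0L, nrow(mask), ncol(mask)),
                 hough = NULL, n = nrow(centres)),
            class = "nucleus_set")
}

test_that("nuclei are assigned by centre-point containment", {
  m <- matrix(FALSE, 100, 100)
  m[20:60, 20:60] <- TRUE
  tubes <- remove_small_objects(m, 1)
  centres <- rbind(c(30, 30), c(40, 40), c(50, 50), c(20, 20), c(60, 60),
                   c(80, 80), c(5, 5), c(90, 10))
  colnames(centres) <- c("row", "col")
  nmask <- matrix(TRUE, 100, 100)
  rec <- assign_nuclei(mk_nuclei(centres, nmask), tubes)
  expect_identical(rec$nucleus_count, 5L)     # border pixels count as inside
  expect_identical(attr(rec, "unassigned"), 3L)
  # no tubes at all: everyone unassigned
  rec0 <- assign_nuclei(mk_nuclei(centres, nmask),
                        remove_small_objects(matrix(FALSE, 100, 100), 1))
  expect_identical(attr(rec0, "unassigned"), 8L)
  # shape mismatch
  expect_error(assign_nuclei(mk_nuclei(centres, matrix(TRUE, 50, 50)), tubes),
               "consistency")
})

test_that("assignment equals the brute-force point-in-component oracle", {
  set.seed(15)
  for (i in 1:3) {
    m <- matrix(FALSE, 60, 60)
    for (k in 1:3) {
      r0 <- sample(10:45, 1); c0 <- sample(10:45, 1)
      m[r0:(r0 + 9), c0:(c0 + 9)] <- TRUE
    }
    tubes <- remove_small_objects(m, 1)
    centres <- cbind(row = sample(1:60, 12, TRUE), col = sample(1:60, 12, TRUE))
    rec <- assign_nuclei(mk_nuclei(centres, matrix(TRUE, 60, 60)), tubes)
    expect_identical(attr(rec, "assignment"),
                     assignment_oracle(centres, tubes$labels))
  }
})

test_that("myoblast exclusion retains only structures meeting the nucleus floor", {
  rec <- data.frame(label = 1:4, area = c(900, 1200, 2000, 5000),
                    nucleus_count = c(1L, 2L, 3L, 5L), retained = NA)
  out <- filter_myoblasts(rec, 3)
  expect_identical(sum(out$retained), 2L)
  expect_identical(out$retained, c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(filter_myoblasts(rec, 1)$retained))
  rec0 <- data.frame(label = 1:2, area = c(600, 700),
                     nucleus_count = c(0L, 0L), retained = NA)
  expect_identical(sum(filter_myoblasts(rec0, 3)$retained), 0L)
})

test_that("summary metrics follow the fusion-index definitions", {
  m <- matrix(FALSE, 50, 50); m[10:40, 10:40] <- TRUE
  nm <- matrix(TRUE, 50, 50)
  centres <- cbind(row = rep(seq(12, 38, length.out = 10), 10)[1:100],
                   col = rep(seq(12, 38, length.out = 10), each = 10)[1:100])
  # fabricate records directly: 30 of 100 in one retained tube
  rec <- data.frame(label = 1L, area = c(4300L), nucleus_count = 30L,
                    retained = TRUE)
  attr(rec, "assignment") <- c(rep(1L, 30), rep(0L, 70))
  ns <- mk_nuclei(centres, nm)
  s <- summarize_fusion(ns, rec, source = "x.tif")
  expect_equal(s$nfi, 0.30)
  expect_identical(s$nuclei_in_retained_tubes, 30L)
  expect_identical(s$retained_tube_area, 4300L)
  # area sums over retained records only
  rec2 <- data.frame(label = 1:3, area = c(2000L, 1500L, 800L),
                     nucleus_count = c(5L, 4L, 3L), retained = TRUE)
  attr(rec2, "assignment") <- rep(c(1L, 2L, 3L), c(5, 4, 3))
  ns2 <- mk_nuclei(centres[1:12, ], nm)
  expect_identical(summarize_fusion(ns2, rec2)$retained_tube_area, 4300L)
  # no nuclei: all zero by convention
  s0 <- summarize_fusion(mk_nuclei(centres[0, , drop = FALSE], nm), rec[0, ])
  expect_identical(s0$nfi, 0)
  expect_identical(s0$total_nuclei, 0L)
  # optional physical scale
  su <- summarize_fusion(ns, rec, scale_um_per_px = 0.5)
  expect_equal(su$retained_tube_area_um2, 4300 * 0.25)
})

test_that("end-to-end analysis matches generator ground truth", {
  cg <- fuzz_culture(51, n_tubes = 2, nuclei_per_tube = c(4, 3),
                     n_myoblasts = 2, n_free_nuclei = 3)
  gt <- cg$ground_truth
  res <- analyze_image(cg$image, fuzz_params())
  expect_identical(res$summary$total_nuclei, nrow(gt$nuclei))
  tube_ids <- gt$structures$id[gt$structures$kind == "tube"]
  expect_identical(res$summary$nuclei_in_retained_tubes,
                   sum(gt$nuclei$structure %in% tube_ids))
  expect_identical(res$summary$n_retained_tubes, 2L)
  # tube channel blank: nuclei counted, no tubes, nfi 0
  px <- cg$image$pixels
  px[, , 2] <- 0
  img2 <- structure(list(pixels = px, n_channels = 3L, source_path = "b.tif"),
                    class = "myofuse_image")
  res2 <- analyze_image(img2, fuzz_params())
  expect_gt(res2$summary$total_nuclei, 0L)
  expect_identical(res2$summary$retained_tube_area, 0L)
  expect_identical(res2$summary$nfi, 0)
  # determinism
  res3 <- analyze_image(cg$image, fuzz_params())
  expect_identical(res3$summary, res$summary)
})

test_that("raising min_nuclei never increases NFI or retained area", {
  cg <- fuzz_culture(52, n_tubes = 2, nuclei_per_tube = c(5, 3),
                     n_myoblasts = 2, n_free_nuclei = 4)
  base <- analyze_image(cg$image, fuzz_params())
  prev_nfi <- Inf; prev_area <- Inf
  for (mn in 1:6) {
    rec <- filter_myoblasts(base$records, mn)
    s <- summarize_fusion(base$nuclei, rec)
    expect_lte(s$nfi, prev_nfi)
    expect_lte(s$retained_tube_area, prev_area)
    prev_nfi <- s$nfi; prev_area <- s$retained_tube_area
  }
})
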