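# Seeded synthetic culture images with exact ground truth. The generator
# emulates the input domain of the tool: a cytoskeletal channel with
# elongated bright myotubes and small compact myoblasts on a dark
# background, and a nuclear channel with bright round (sometimes
# overlapping) discs, plus additive Gaussian noise and optional linear
# shading.

# -- low-level drawing --------------------------------------------------------

# anti-aliased disc: coverage ramp of width 1 px at the rim
.draw_disc <- function(field, cy, cx, r, value, aa = TRUE) {
  h <- nrow(field); w <- ncol(field)
  ys <- max(1, floor(cy - r - 2)):min(h, ceiling(cy + r + 2))
  xs <- max(1, floor(cx - r - 2)):min(w, ceiling(cx + r + 2))
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- if (aa) pmin(pmax(r + 0.5 - d, 0), 1) else (d <= r) * 1
  field[ys, xs] <- pmax(field[ys, xs], value * cov)
  field
}

# capsule (thick segment) from p1 to p2 with half-width hw
.draw_capsule <- function(field, p1, p2, hw, value, aa = TRUE) {
  h <- nrow(field); w <- ncol(field)
  ys <- max(1, floor(min(p1[1], p2[1]) - hw - 2)):min(h, ceiling(max(p1[1], p2[1]) + hw + 2))
  xs <- max(1, floor(min(p1[2], p2[2]) - hw - 2)):min(w, ceiling(max(p1[2], p2[2]) + hw + 2))
  v <- p2 - p1
  len2 <- sum(v^2)
  Y <- matrix(ys, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  tt <- if (len2 == 0) 0 else pmin(pmax(((Y - p1[1]) * v[1] + (X - p1[2]) * v[2]) / len2, 0), 1)
  d <- sqrt((Y - (p1[1] + tt * v[1]))^2 + (X - (p1[2] + tt * v[2]))^2)
  cov <- if (aa) pmin(pmax(hw + 0.5 - d, 0), 1) else (d <= hw) * 1
  field[ys, xs] <- pmax(field[ys, xs], value * cov)
  field
}

# filled ellipse, rotated by theta
.draw_ellipse <- function(field, cy, cx, a, b, theta, value, aa = TRUE) {
  h <- nrow(field); w <- ncol(field)
  r <- max(a, b)
  ys <- max(1, floor(cy - r - 2)):min(h, ceiling(cy + r + 2))
  xs <- max(1, floor(cx - r - 2)):min(w, ceiling(cx + r + 2))
  Y <- matrix(ys - cy, length(ys), length(xs))
  X <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  q <- sqrt((u / a)^2 + (v / b)^2)
  # approximate edge ramp in pixel units
  grad <- pmax(1 / a, 1 / b)
  cov <- if (aa) pmin(pmax((1 + grad / 2 - q) / grad, 0), 1) else (q <= 1) * 1
  field[ys, xs] <- pmax(field[ys, xs], value * cov)
  field
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# -- culture generator --------------------------------------------------------

#' Generate a seeded synthetic myotube culture with ground truth
#'
#' Builds a three-channel image (channel 2 = cytoskeletal/myotube,
#' channel 3 = nuclear, channel 1 empty) containing elongated capsule
#' myotubes, small ellipse myoblasts holding 1-2 nuclei, free background
#' nuclei, and optionally pairs of deliberately touching nuclei, with
#' additive Gaussian noise and optional linear shading. Fully
#' reproducible from `seed`; the exact ground truth (every structure and
#' every nucleus centre/radius with its structure membership) is
#' returned alongside the image.
#'
#' @param height,width Field size in pixels.
#' @param n_tubes Number of myotubes.
#' @param n_myoblasts Number of myoblasts (each holds 1 or 2 nuclei).
#' @param nuclei_per_tube Integer vector (recycled to `n_tubes`) of
#'   nucleus counts per myotube.
#' @param n_free_nuclei Nuclei on background, outside all structures.
#' @param n_touching_pairs Pairs of overlapping nuclei on background
#'   (centre distance 0.9 x the radius sum), exercising the watershed
#'   splitting route.
#' @param nucleus_radius_range Range the nuclear radii are drawn from.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param shading If `TRUE`, multiply both channels by a linear
#'   left-to-right illumination gradient (0.65 to 1).
#' @param seed Integer RNG seed.
#' @return List with `image` (a `myofuse_image`) and `ground_truth`
#'   (class `myofuse_ground_truth`): `structures` data frame (id, kind,
#'   drawn pixel area, nucleus count), `nuclei` data frame (id, row,
#'   col, radius, structure id or 0, touching flag) and `seed`.
#' @export
make_culture <- function(height = 640, width = 640,
                         n_tubes = 2, n_myoblasts = 3,
                         nuclei_per_tube = c(8, 5),
                         n_free_nuclei = 20,
                         n_touching_pairs = 0,
                         nucleus_radius_range = c(15, 25),
                         noise_sigma = 0.02,
                         shading = FALSE,
                         seed = 1) {
  .with_seed(seed, {
    rmin <- nucleus_radius_range[1]; rmax <- nucleus_radius_range[2]
    stopifnot(rmin > 0, rmin <= rmax)
    if (n_tubes > 0) nuclei_per_tube <- rep_len(nuclei_per_tube, n_tubes)
    tube_ch <- matrix(0.08, height, width)
    nuc_ch <- matrix(0.05, height, width)
    occupied <- matrix(FALSE, height, width)   # structure occupancy + margin
    structures <- data.frame(id = integer(0), kind = character(0),
                             area_px = integer(0), n_nuclei = integer(0))
    nuclei <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                         radius = numeric(0), structure = integer(0),
                         touching = logical(0))
    sid <- 0L; nid <- 0L
    fail <- function() stop("generation error: could not place all structures; ",
                            "use a larger field", call. = FALSE)
    claim <- function(mask_sel) occupied[mask_sel] <<- TRUE

    region_free <- function(ys, xs) !any(occupied[ys, xs])

    add_nucleus <- function(r, c, rad, structure, touching = FALSE) {
      nid <<- nid + 1L
      nuclei[nrow(nuclei) + 1L, ] <<- list(nid, r, c, rad, structure, touching)
      nuc_ch <<- .draw_disc(nuc_ch, r, c, rad, 0.9)
    }

    # ---- myotubes: capsules, axial nuclei ----
    for (i in seq_len(n_tubes)) {
      k <- nuclei_per_tube[i]
      spacing <- 2 * rmax + 8
      len <- max(150, k * spacing + 30)
      hw <- stats::runif(1, 20, 28)
      placed <- FALSE
      for (att in 1:300) {
        theta <- stats::runif(1, 0, pi)
        margin <- hw + 12
        dy <- len * sin(theta); dx <- len * cos(theta)
        r1 <- suppressWarnings(
          stats::runif(1, margin + max(0, -dy), height - margin - max(0, dy)))
        c1 <- suppressWarnings(
          stats::runif(1, margin + max(0, -dx), width - margin - max(0, dx)))
        if (is.na(r1) || is.na(c1)) next
        p1 <- c(r1, c1); p2 <- p1 + c(dy, dx)
        probe <- matrix(0, height, width)
        probe <- .draw_capsule(probe, p1, p2, hw + 10, 1, aa = FALSE)
        if (any(occupied & probe > 0)) next
        tube_ch <- .draw_capsule(tube_ch, p1, p2, hw, 0.85)
        drawn <- .draw_capsule(matrix(0, height, width), p1, p2, hw, 1, aa = FALSE)
        claim(probe > 0)
        sid <- sid + 1L
        structures[nrow(structures) + 1L, ] <- list(sid, "tube",
                                                    as.integer(sum(drawn > 0)), k)
        # nuclei along the axis
        if (k > 0) {
          dirv <- (p2 - p1) / len
          perp <- c(-dirv[2], dirv[1])
          t0 <- (len - (k - 1) * spacing) / 2
          for (j in seq_len(k)) {
            rad <- stats::runif(1, rmin, min(rmax, hw * 0.85))
            off <- stats::runif(1, -1, 1) * max(0, hw - rad * 0.4 - 6)
            ctr <- p1 + dirv * (t0 + (j - 1) * spacing) + perp * off
            add_nucleus(ctr[1], ctr[2], rad, sid)
          }
        }
        placed <- TRUE
        break
      }
      if (!placed) fail()
    }

    # ---- myoblasts: small ellipses with 1-2 nuclei ----
    for (i in seq_len(n_myoblasts)) {
      kn <- sample(1:2, 1)
      a <- stats::runif(1, max(24, rmin * 1.6), 34)
      b <- stats::runif(1, 14, 18)
      placed <- FALSE
      for (att in 1:300) {
        theta <- stats::runif(1, 0, pi)
        margin <- a + 14
        cy <- stats::runif(1, margin, height - margin)
        cx <- stats::runif(1, margin, width - margin)
        probe <- .draw_ellipse(matrix(0, height, width), cy, cx,
                               a + 10, b + 10, theta, 1, aa = FALSE)
        if (any(occupied & probe > 0)) next
        tube_ch <- .draw_ellipse(tube_ch, cy, cx, a, b, theta, 0.85)
        drawn <- .draw_ellipse(matrix(0, height, width), cy, cx, a, b, theta,
                               1, aa = FALSE)
        claim(probe > 0)
        sid <- sid + 1L
        structures[nrow(structures) + 1L, ] <- list(sid, "myoblast",
                                                    as.integer(sum(drawn > 0)), kn)
        dirv <- c(sin(theta), cos(theta))
        rad <- stats::runif(kn, rmin, rmin + 3)
        if (kn == 1L) {
          add_nucleus(cy, cx, rad[1], sid)
        } else {
          d <- 0.45 * sum(rad) # overlapping pair inside the myoblast
          add_nucleus(cy - dirv[1] * d, cx - dirv[2] * d, rad[1], sid, TRUE)
          add_nucleus(cy + dirv[1] * d, cx + dirv[2] * d, rad[2], sid, TRUE)
        }
        placed <- TRUE
        break
      }
      if (!placed) fail()
    }

    # ---- free nuclei and touching pairs on background ----
    place_free <- function(rad_tot) {
      for (att in 1:400) {
        m <- rad_tot + 8
        cy <- stats::runif(1, m, height - m)
        cx <- stats::runif(1, m, width - m)
        ys <- max(1, floor(cy - m)):min(height, ceiling(cy + m))
        xs <- max(1, floor(cx - m)):min(width, ceiling(cx + m))
        if (!region_free(ys, xs)) next
        if (nrow(nuclei)) {
          d2 <- (nuclei$row - cy)^2 + (nuclei$col - cx)^2
          if (min(d2) < (rad_tot + rmax + 6)^2) next
        }
        return(c(cy, cx))
      }
      fail()
    }
    for (i in seq_len(n_free_nuclei)) {
      rad <- stats::runif(1, rmin, rmax)
      ctr <- place_free(rad)
      add_nucleus(ctr[1], ctr[2], rad, 0L)
    }
    for (i in seq_len(n_touching_pairs)) {
      rad <- stats::runif(2, rmin, rmin + 6)
      d <- 0.9 * sum(rad) / 2
      theta <- stats::runif(1, 0, pi)
      ctr <- place_free(d + max(rad))
      dv <- c(sin(theta), cos(theta))
      add_nucleus(ctr[1] - dv[1] * d, ctr[2] - dv[2] * d, rad[1], 0L, TRUE)
      add_nucleus(ctr[1] + dv[1] * d, ctr[2] + dv[2] * d, rad[2], 0L, TRUE)
    }

    # ---- shading, noise, assembly ----
    if (shading) {
      g <- matrix(seq(0.65, 1, length.out = width), height, width, byrow = TRUE)
      tube_ch <- tube_ch * g
      nuc_ch <- nuc_ch * g
    }
    if (noise_sigma > 0) {
      tube_ch <- tube_ch + stats::rnorm(length(tube_ch), 0, noise_sigma)
      nuc_ch <- nuc_ch + stats::rnorm(length(nuc_ch), 0, noise_sigma)
    }
    px <- array(0, c(height, width, 3))
    px[, , 2] <- pmin(pmax(tube_ch, 0), 1)
    px[, , 3] <- pmin(pmax(nuc_ch, 0), 1)
    img <- structure(list(pixels = px, n_channels = 3L,
                          source_path = sprintf("synthetic_seed%d.tif", seed)),
                     class = "myofuse_image")
    for (fld in c("id", "area_px", "n_nuclei"))
      structures[[fld]] <- as.integer(structures[[fld]])
    nuclei$id <- as.integer(nuclei$id)
    nuclei$structure <- as.integer(nuclei$structure)
    gt <- structure(list(structures = structures, nuclei = nuclei, seed = seed),
                    class = "myofuse_ground_truth")
    list(image = img, ground_truth = gt)
  })
}

#' @export
print.myofuse_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth (seed %d): %d structure(s), %d nuclei\n",
              x$seed, nrow(x$structures), nrow(x$nuclei)))
  invisible(x)
}

# -- pixel-exact boundary fixtures -------------------------------------------

# measure functions return per-component areas of the processing prefix
# that precedes the size filter under test
.measure_tube_prefix <- function(ch, params) {
  norm <- normalize_illumination(ch, sigma = 4 * params$max_circle_rad)
  sm <- fill_and_smooth(binarize_tubes(norm, params$tube_thresh),
                        params$fill_size)
  L <- label8(sm)
  list(labels = L, areas = label_areas(L))
}

.measure_nuc_prefix <- function(ch, params) {
  mask <- ch > auto_threshold(ch)
  sm <- fill_and_smooth(mask, params$nuc_fill_size)
  L <- label8(sm)
  list(labels = L, areas = label_areas(L))
}

# area of the component whose centroid is nearest (cy, cx)
.area_near <- function(meas, cy, cx) {
  if (!length(meas$areas)) return(0L)
  labs <- as.integer(names(meas$areas))
  d <- vapply(labs, function(l) {
    idx <- which(meas$labels == l, arr.ind = TRUE)
    sum((colMeans(idx) - c(cy, cx))^2)
  }, numeric(1))
  as.integer(meas$areas[[which.min(d)]])
}

# engineer a blob whose post-prefix component area equals `target`
# exactly. Stage 1 binary-searches the (real-valued) radius of a single
# disc at an off-lattice centre (areas step in small increments as
# lattice points cross the rim). Morphological smoothing can make those
# steps skip the target, so stage 2 backs the main disc off below the
# target and slides a secondary disc (just larger than the smoothing
# brush, so it survives the opening) outward, which grows the component
# in ~1 px steps until the target is hit.
.tune_disc <- function(base_ch, cy, cx, target, measure, fg = 0.9,
                       slider_rad = 11.5) {
  r0 <- sqrt(target / pi)
  offsets <- list(c(0.31, 0.17), c(0.13, 0.43), c(0.47, 0.29),
                  c(0.05, 0.37), c(0.23, 0.11), c(0.41, 0.47))
  for (off in offsets) {
    yy <- cy + off[1]; xx <- cx + off[2]
    f <- function(r) .area_near(measure(.draw_disc(base_ch, yy, xx, r, fg,
                                                   aa = FALSE)),
                                yy, xx)
    lo <- r0 - 4; hi <- r0 + 4
    if (f(lo) > target || f(hi) < target) next
    while (hi - lo > 0.001) {
      mid <- (lo + hi) / 2
      if (f(mid) >= target) hi <- mid else lo <- mid
    }
    if (f(hi) == target)
      return(list(channel = .draw_disc(base_ch, yy, xx, hi, fg, aa = FALSE),
                  radius = hi, centre = c(yy, xx), area = target))
    # stage 2: back the main disc off below the target and slide a
    # secondary disc outward as a fine-grained area knob
    for (back in c(0.02, 0.25, 0.5, 0.8, 1.2)) {
      r_main <- lo - back
      ch_main <- .draw_disc(base_ch, yy, xx, r_main, fg, aa = FALSE)
      if (.area_near(measure(ch_main), yy, xx) >= target) next
      for (ang in c(0, pi / 2, pi / 4, 3 * pi / 4)) {
        dv <- c(sin(ang), cos(ang))
        g <- function(d) .area_near(measure(
          .draw_disc(ch_main, yy + dv[1] * d, xx + dv[2] * d,
                     slider_rad, fg, aa = FALSE)), yy, xx)
        ds <- seq(max(0.5, r_main - slider_rad - 0.5),
                  r_main + slider_rad - 1, by = 0.1)
        prev_d <- ds[1]; prev_a <- g(prev_d)
        hit <- NA_real_
        for (d in ds[-1]) {
          a <- g(d)
          if (a == target) { hit <- d; break }
          if (prev_a < target && a > target) {
            for (dd in seq(prev_d, d, by = 0.005)) {
              if (g(dd) == target) { hit <- dd; break }
            }
            if (!is.na(hit)) break
          }
          prev_d <- d; prev_a <- a
        }
        if (!is.na(hit))
          return(list(channel = .draw_disc(ch_main, yy + dv[1] * hit,
                                           xx + dv[2] * hit, slider_rad, fg,
                                           aa = FALSE),
                      radius = r_main, centre = c(yy, xx), area = target))
      }
    }
  }
  stop("generation error: could not engineer a component of exactly ",
       target, " px", call. = FALSE)
}

.boundary_kinds <- c("tube_area_499", "tube_area_500",
                     "nucleus_area_299", "nucleus_area_300",
                     "oversize_nucleus",
                     "two_nuclei_tube", "three_nuclei_tube")

#' Build a field of pixel-exact boundary structures
#'
#' Engineers one or more structures whose connected-component area,
#' measured after the pipeline stages that precede the size filter
#' under test, is controlled exactly to the pixel: tube components of
#' 499/500 px (around the default myotube floor), nuclear components of
#' 299/300 px (around the default nucleus floor), or an arbitrary
#' nuclear blob area via `kind = "nucleus_area"` with `target`. All
#' kinds in one call must address the same channel. Structures are
#' placed left to right and each is tuned on the growing composite
#' field, so areas remain exact in the final image.
#'
#' @param kinds Character vector of kinds: `"tube_area_<n>"`,
#'   `"nucleus_area_<n>"`, or `"oversize_nucleus"`.
#' @param height,width Field size; defaults accommodate the structures
#'   (`oversize_nucleus` uses 1000 x 1000).
#' @param targets Optional numeric vector overriding the per-kind target
#'   areas parsed from the kind names.
#' @param params Parameter set the measurement prefix uses.
#' @return List with `image` (a `myofuse_image`) and `ground_truth`
#'   (per-structure kind, centre, tuned radius and exact achieved area).
#' @export
make_boundary_field <- function(kinds, height = NULL, width = NULL,
                                targets = NULL,
                                params = myofuse_params()) {
  parse_kind <- function(k) {
    if (k == "oversize_nucleus") return(list(chan = "nuc", target = 11000))
    mt <- regmatches(k, regexec("^(tube|nucleus)_area_([0-9]+)$", k))[[1]]
    if (length(mt) != 3)
      stop("parameter error: unknown boundary kind '", k, "'", call. = FALSE)
    list(chan = if (mt[2] == "tube") "tube" else "nuc",
         target = as.numeric(mt[3]))
  }
  specs <- lapply(kinds, parse_kind)
  if (!is.null(targets)) for (i in seq_along(specs)) specs[[i]]$target <- targets[i]
  chans <- vapply(specs, `[[`, "", "chan")
  if (length(unique(chans)) != 1)
    stop("parameter error: boundary kinds must share one channel", call. = FALSE)
  oversize <- any(kinds == "oversize_nucleus")
  rmax <- max(vapply(specs, function(s) sqrt(s$target / pi), numeric(1)))
  cell <- max(160, ceiling(2 * rmax + 120))
  if (is.null(height)) height <- if (oversize) 1000 else cell
  if (is.null(width)) width <- if (oversize) 1000 else cell * length(specs)
  bg <- if (chans[1] == "tube") 0.08 else 0.05
  ch <- matrix(bg, height, width)
  measure <- if (chans[1] == "tube")
    function(x) .measure_tube_prefix(x, params)
  else
    function(x) .measure_nuc_prefix(x, params)
  gt <- data.frame(kind = character(0), row = numeric(0), col = numeric(0),
                   radius = numeric(0), area = numeric(0))
  step <- width / length(specs)
  for (i in seq_along(specs)) {
    cy <- height / 2
    cx <- step * (i - 0.5)
    slider <- if (chans[1] == "tube") params$fill_size + 1.5 else
      params$nuc_fill_size + 1.5
    tuned <- .tune_disc(ch, cy, cx, specs[[i]]$target, measure,
                        slider_rad = slider)
    ch <- tuned$channel
    gt[nrow(gt) + 1L, ] <- list(kinds[i], tuned$centre[1], tuned$centre[2],
                                tuned$radius, tuned$area)
  }
  px <- array(0, c(height, width, 3))
  if (chans[1] == "tube") { px[, , 2] <- ch; px[, , 3] <- 0.05 }
  else { px[, , 3] <- ch; px[, , 2] <- 0.08 }
  img <- structure(list(pixels = px, n_channels = 3L,
                        source_path = paste0("synthetic_boundary_",
                                             paste(kinds, collapse = "_"),
                                             ".tif")),
                   class = "myofuse_image")
  list(image = img, ground_truth = gt)
}

#' Generate a single boundary-case image
#'
#' Minimal images exercising the exact size and count boundaries of the
#' default parameters: tube components of exactly 499 or 500 px after
#' smoothing, nuclear components of exactly 299 or 300 px after
#' cleaning, a nuclear blob of 11,000 px on a 1000 x 1000 field (above
#' the 1\%-of-image ceiling), and capsule structures containing exactly
#' 2 or 3 nuclei.
#'
#' @param kind One of `"tube_area_499"`, `"tube_area_500"`,
#'   `"nucleus_area_299"`, `"nucleus_area_300"`, `"oversize_nucleus"`,
#'   `"two_nuclei_tube"`, `"three_nuclei_tube"`.
#' @param params Parameter set used when tuning exact areas.
#' @return List with `image` and `ground_truth` (format depends on
#'   kind: tuned-area table or full culture ground truth).
#' @export
make_boundary_case <- function(kind, params = myofuse_params()) {
  kind <- match.arg(kind, .boundary_kinds)
  if (kind %in% c("two_nuclei_tube", "three_nuclei_tube")) {
    k <- if (kind == "two_nuclei_tube") 2L else 3L
    return(make_culture(height = 420, width = 420, n_tubes = 1,
                        n_myoblasts = 0, nuclei_per_tube = k,
                        n_free_nuclei = 0, noise_sigma = 0,
                        seed = 1000L + k))
  }
  make_boundary_field(kind, params = params)
}
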