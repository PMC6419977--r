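#' Analysis parameters
#'
#' Constructs the set of ten user-tunable analysis parameters with their
#' default values. All sizes are in pixels of the input image; channel
#' indices are 1-based (1 = red, 2 = green, 3 = blue for an RGB TIFF).
#'
#' @param smallest_myotube_pixel_count Smallest allowed myotube, by the
#'   number of pixels it covers. Tube components strictly smaller are
#'   discarded. Default 500.
#' @param smallest_nucleus_pixel_count Smallest allowed nucleus, by the
#'   number of pixels it covers. Nuclear components strictly smaller are
#'   discarded. Default 300.
#' @param myotube_channel 1-based index of the cytoskeletal-marker
#'   channel. Default 2 (green).
#' @param nuc_channel 1-based index of the DAPI/nuclear channel.
#'   Default 3 (blue).
#' @param fill_size Radius, in pixels, of the disc structuring element
#'   used to smooth myotube borders (closing then opening). Default 10.
#' @param nuc_fill_size Radius of the disc used to smooth nuclear
#'   borders. Default 5.
#' @param min_circle_rad Lower bound for nuclear radii considered by the
#'   circle Hough transform, and the minimum separation of watershed
#'   markers. Adjust for magnification. Default 15.
#' @param max_circle_rad Upper bound for nuclear radii. Default 40.
#' @param tube_thresh Multiplicative scale on the automatically computed
#'   (between-class-variance) tube threshold. Lower values detect fainter
#'   cytoskeletal staining. Default 1.
#' @param min_nuclei Discard any myotube with fewer than this many
#'   recognised nuclei inside its borders. Default 3.
#' @param max_nuc_size_divisor Discard nuclei larger than 1/n of the total
#'   image area, where n is this value. Default 100 (i.e. 1\% of the
#'   image).
#' @param scale_um_per_px Optional physical pixel size in micrometres per
#'   pixel; when supplied, retained myotube area is additionally reported
#'   in square micrometres. Default `NA` (off).
#'
#' @return An object of class `myofuse_params`: a named list of the
#'   validated parameter values.
#' @seealso [validate_params()], [analyze_image()]
#' @examples
#' p <- myofuse_params()
#' p$min_nuclei
#' myofuse_params(tube_thresh = 0.95)$tube_thresh
#' @export
myofuse_params <- function(smallest_myotube_pixel_count = 500,
                           smallest_nucleus_pixel_count = 300,
                           myotube_channel = 2,
                           nuc_channel = 3,
                           fill_size = 10,
                           nuc_fill_size = 5,
                           min_circle_rad = 15,
                           max_circle_rad = 40,
                           tube_thresh = 1,
                           min_nuclei = 3,
                           max_nuc_size_divisor = 100,
                           scale_um_per_px = NA_real_) {
  p <- list(
    smallest_myotube_pixel_count = as.numeric(smallest_myotube_pixel_count),
    smallest_nucleus_pixel_count = as.numeric(smallest_nucleus_pixel_count),
    myotube_channel = as.integer(myotube_channel),
    nuc_channel = as.integer(nuc_channel),
    fill_size = as.numeric(fill_size),
    nuc_fill_size = as.numeric(nuc_fill_size),
    min_circle_rad = as.numeric(min_circle_rad),
    max_circle_rad = as.numeric(max_circle_rad),
    tube_thresh = as.numeric(tube_thresh),
    min_nuclei = as.integer(min_nuclei),
    max_nuc_size_divisor = as.numeric(max_nuc_size_divisor),
    scale_um_per_px = as.numeric(scale_um_per_px)
  )
  class(p) <- "myofuse_params"
  validate_params(p)
}

#' Validate an analysis parameter set
#'
#' Checks the internal invariants of a parameter set and, when an image is
#' supplied, that the channel indices fit its channel count.
#'
#' @param params A [myofuse_params()] object.
#' @param image Optionally, a `myofuse_image` (see [read_culture()]) whose
#'   channel count the channel indices must respect.
#' @return `params`, unchanged, if all checks pass; otherwise an error
#'   naming the violated constraint.
#' @export
validate_params <- function(params, image = NULL) {
  stopifnot(inherits(params, "myofuse_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid parameter: ", msg, call. = FALSE)
  with(params, {
    chk(smallest_myotube_pixel_count > 0, "smallest_myotube_pixel_count must be > 0")
    chk(smallest_nucleus_pixel_count > 0, "smallest_nucleus_pixel_count must be > 0")
    chk(fill_size > 0, "fill_size must be > 0")
    chk(nuc_fill_size > 0, "nuc_fill_size must be > 0")
    chk(min_circle_rad > 0, "min_circle_rad must be > 0")
    chk(min_circle_rad < max_circle_rad,
        sprintf("min_circle_rad (%g) must be < max_circle_rad (%g)",
                min_circle_rad, max_circle_rad))
    chk(tube_thresh > 0, "tube_thresh must be > 0")
    chk(min_nuclei >= 1, "min_nuclei must be >= 1")
    chk(max_nuc_size_divisor >= 1, "max_nuc_size_divisor must be >= 1")
    chk(myotube_channel >= 1, "myotube_channel must be >= 1")
    chk(nuc_channel >= 1, "nuc_channel must be >= 1")
    chk(myotube_channel != nuc_channel,
        "myotube_channel and nuc_channel must differ")
    chk(is.na(scale_um_per_px) || scale_um_per_px > 0,
        "scale_um_per_px must be > 0 when given")
  })
  if (!is.null(image)) {
    nc <- image$n_channels
    for (fld in c("myotube_channel", "nuc_channel")) {
      if (params[[fld]] > nc)
        stop(sprintf("invalid parameter: %s = %d out of range for a %d-channel image (valid: 1..%d)",
                     fld, params[[fld]], nc, nc), call. = FALSE)
    }
  }
  params
}

# Map of the user-facing (CLI) parameter names, as printed in the original
# tool's documentation, to list fields. Matched case-insensitively.
.cli_param_map <- c(
  smallestmyotubepixelcount = "smallest_myotube_pixel_count",
  smallestnucleuspixelcount = "smallest_nucleus_pixel_count",
  myotubechannel            = "myotube_channel",
  nucchannel                = "nuc_channel",
  fillsize                  = "fill_size",
  nucfillsize               = "nuc_fill_size",
  mincirclerad              = "min_circle_rad",
  maxcirclerad              = "max_circle_rad",
  tubethresh                = "tube_thresh",
  minnuclei                 = "min_nuclei",
  maxnucsizedivisor         = "max_nuc_size_divisor",
  scaleumperpx              = "scale_um_per_px"
)

#' @export
print.myofuse_params <- function(x, ...) {
  cat("Myotube analysis parameters:\n")
  for (nm in names(x))
    cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
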