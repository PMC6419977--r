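#' Read a bi- or tri-channel culture TIFF
#'
#' Reads a fluorescence culture image in which one channel carries the
#' cytoskeletal stain (myotubes) and another the DAPI stain (nuclei).
#' Intensities are rescaled to \[0, 1\] by the full range of the on-disk
#' sample type (8- or 16-bit), not by the per-image minimum/maximum;
#' per-image contrast handling is left to the segmentation stages. Both
#' interleaved multi-sample TIFFs and planar TIFFs (one directory per
#' channel) are accepted, and the channel axis is always resolved to the
#' last position.
#'
#' @param path Path to a readable TIFF file with 2 or 3 channels.
#' @return A `myofuse_image`: list with `pixels` (height x width x
#'   n_channels array in \[0, 1\]), `n_channels` (2 or 3) and
#'   `source_path`.
#' @examples
#' img_gt <- make_culture(height = 192, width = 192, n_tubes = 1,
#'                        nuclei_per_tube = 3, seed = 1)
#' tf <- tempfile(fileext = ".tif")
#' write_culture_tiff(img_gt$image, tf)
#' img <- read_culture(tf)
#' img$n_channels
#' @export
read_culture <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  planes <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE)),
    error = function(e) stop("format error: not a readable TIFF: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (length(planes) == 1L) {
    px <- planes[[1L]]
    if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  } else {
    if (!all(vapply(planes, is.matrix, logical(1))))
      stop("format error: mixed multi-directory TIFF layout in ", path,
           call. = FALSE)
    d <- dim(planes[[1L]])
    if (!all(vapply(planes, function(m) identical(dim(m), d), logical(1))))
      stop("format error: planar TIFF directories differ in size in ", path,
           call. = FALSE)
    px <- array(unlist(planes, use.names = FALSE), c(d, length(planes)))
  }
  nc <- dim(px)[3L]
  if (!nc %in% c(2L, 3L))
    stop("unsupported format: image has ", nc,
         " channel(s); 2 or 3 channels are required", call. = FALSE)
  structure(list(pixels = px, n_channels = nc, source_path = path),
            class = "myofuse_image")
}

#' @export
print.myofuse_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Culture image: %d x %d px, %d channels (%s)\n",
              d[1], d[2], x$n_channels, x$source_path))
  invisible(x)
}

#' Extract one channel plane from a culture image
#'
#' @param image A `myofuse_image` from [read_culture()].
#' @param index 1-based channel index (1 = red, 2 = green, 3 = blue for
#'   an RGB TIFF).
#' @return The 2-D intensity matrix of that channel, values in \[0, 1\].
#' @export
select_channel <- function(image, index) {
  stopifnot(inherits(image, "myofuse_image"))
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L || index > image$n_channels)
    stop(sprintf("parameter error: channel index %s out of range (valid: 1..%d)",
                 format(index), image$n_channels), call. = FALSE)
  image$pixels[, , index]
}

#' Write a culture image as a multi-channel TIFF
#'
#' Companion to [read_culture()]; used mainly to materialise synthetic
#' fixtures as files the CLI can consume.
#'
#' @param image A `myofuse_image` or a height x width x channels array in
#'   \[0, 1\].
#' @param path Output path.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_culture_tiff <- function(image, path, bits = 8L) {
  px <- if (inherits(image, "myofuse_image")) image$pixels else image
  stopifnot(length(dim(px)) == 3L)
  tiff::writeTIFF(pmin(pmax(px, 0), 1), path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# -- diagnostic output writing ------------------------------------------------

# suffixes, in the order the files are written
.output_suffixes <- c(overlay    = "_overlay.png",
                      centroids  = "_nuclei_centroids.png",
                      borders    = "_nuclei_borders.png",
                      stages     = "_nuclei_stages.png",
                      summary    = "_summary.txt")

#' Write the diagnostic outputs for one analysed image
#'
#' Writes exactly five files per analysed image: four 8-bit RGB PNG
#' diagnostics — (1) a combined overlay with myotube borders and accepted
#' nuclei marked, (2) a nucleus centroid overlay, (3) a nucleus border
#' overlay, (4) a nucleus segmentation-stage overlay — and one UTF-8 text
#' summary with every reported metric as a `key: value` line. Filenames
#' derive from the source image stem; if a stem would collide with files
#' already present (e.g. two identically named inputs in one batch), a
#' numeric suffix is appended.
#'
#' @param result A `myofuse_analysis` from [analyze_image()].
#' @param out_dir Writable output directory (created if absent).
#' @return Character vector of the 5 written paths, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "myofuse_analysis"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory: ", out_dir, call. = FALSE)
  if (file.access(out_dir, 2L) != 0L)
    stop("I/O error: output directory not writable: ", out_dir, call. = FALSE)

  stem0 <- tools::file_path_sans_ext(basename(result$summary$source))
  stem <- stem0
  k <- 1L
  while (file.exists(file.path(out_dir, paste0(stem, .output_suffixes["summary"])))) {
    k <- k + 1L
    stem <- paste0(stem0, "_", k)
  }

  paths <- file.path(out_dir, paste0(stem, .output_suffixes))
  names(paths) <- names(.output_suffixes)
  png::writePNG(result$overlays$combined,  paths[["overlay"]])
  png::writePNG(result$overlays$centroids, paths[["centroids"]])
  png::writePNG(result$overlays$borders,   paths[["borders"]])
  png::writePNG(result$overlays$stages,    paths[["stages"]])
  writeLines(format_summary_text(result$summary), paths[["summary"]], useBytes = TRUE)
  invisible(paths)
}

# one `key: value` line per metric, stable order
format_summary_text <- function(s) {
  lines <- c(
    sprintf("source: %s", s$source),
    sprintf("total_nuclei: %d", s$total_nuclei),
    sprintf("nuclei_in_tubes: %d", s$nuclei_in_tubes),
    sprintf("nuclei_in_retained_tubes: %d", s$nuclei_in_retained_tubes),
    sprintf("n_retained_tubes: %d", s$n_retained_tubes),
    sprintf("retained_tube_area_px: %d", s$retained_tube_area),
    sprintf("nfi: %.6g", s$nfi))
  if (!is.null(s$retained_tube_area_um2) && !is.na(s$retained_tube_area_um2))
    lines <- c(lines, sprintf("retained_tube_area_um2: %.6g", s$retained_tube_area_um2))
  lines
}

#' Write the batch summary CSV
#'
#' One header row plus one row per analysed image, in processing order:
#' source filename, total nuclei, nuclei within myotubes, nuclei within
#' retained myotubes, retained myotube area in pixels, and NFI.
#'
#' @param summaries A non-empty list of image summaries (the `summary`
#'   component of [analyze_image()] results, or a `myofuse_batch`).
#' @param out_path Output CSV path.
#' @return `out_path`, invisibly.
#' @export
write_batch_csv <- function(summaries, out_path) {
  if (inherits(summaries, "myofuse_batch")) summaries <- summaries$summaries
  if (length(summaries) == 0L)
    stop("parameter error: no summaries to write", call. = FALSE)
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(source = s$source,
               total_nuclei = s$total_nuclei,
               nuclei_in_tubes = s$nuclei_in_tubes,
               nuclei_in_retained_tubes = s$nuclei_in_retained_tubes,
               retained_tube_area_px = s$retained_tube_area,
               nfi = s$nfi,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, out_path, row.names = FALSE)
  invisible(out_path)
}
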