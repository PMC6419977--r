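#' Assign detected nuclei to myotube components
#'
#' A nucleus belongs to the tube component that contains its centre
#' point (a centre on a foreground border pixel belongs to that
#' component); nuclei whose centre lies on background belong to no tube.
#' Each nucleus is therefore assigned to at most one structure.
#'
#' @param nuclei A `nucleus_set` from [detect_nuclei()].
#' @param tubes A `tube_mask` from [segment_myotubes()], same image.
#' @return Data frame of myotube records: `label`, `area` (px),
#'   `nucleus_count`, `retained` (`NA` until [filter_myoblasts()]), with
#'   attribute `unassigned` (number of nuclei outside all tubes) and
#'   `assignment` (per-nucleus component label, 0 = none).
#' @export
assign_nuclei <- function(nuclei, tubes) {
  stopifnot(inherits(nuclei, "nucleus_set"), inherits(tubes, "tube_mask"))
  if (!identical(dim(nuclei$mask), dim(tubes$labels)))
    stop("consistency error: nucleus and tube rasters differ in shape",
         call. = FALSE)
  labs <- as.integer(names(tubes$areas))
  assignment <- integer(nuclei$n)
  if (nuclei$n > 0)
    assignment <- tubes$labels[cbind(round(nuclei$centres[, 1]),
                                     round(nuclei$centres[, 2]))]
  counts <- vapply(labs, function(l) sum(assignment == l), integer(1))
  rec <- data.frame(label = labs,
                    area = as.integer(tubes$areas),
                    nucleus_count = counts,
                    retained = rep(NA, length(labs)))
  attr(rec, "unassigned") <- sum(assignment == 0L)
  attr(rec, "assignment") <- assignment
  rec
}

#' Flag myoblasts for exclusion
#'
#' Cytoskeletal-marker-positive structures containing fewer than
#' `min_nuclei` recognised nuclei inside their borders are myoblasts and
#' are excluded from the area and fusion metrics; at the default of 3,
#' structures with 2 or fewer nuclei are eliminated.
#'
#' @param records Myotube records from [assign_nuclei()].
#' @param min_nuclei Minimum in-border nucleus count for retention.
#' @return The records with the `retained` flag set.
#' @export
filter_myoblasts <- function(records, min_nuclei = 3) {
  records$retained <- records$nucleus_count >= min_nuclei
  records
}

#' Summarise one analysed image
#'
#' Computes the reported metrics: total nuclei, nuclei within any
#' myotube structure, nuclei within retained myotubes, total retained
#' myotube area, and the nuclear fusion index
#' NFI = nuclei in retained myotubes / total nuclei (0 when the image
#' holds no nuclei).
#'
#' @param nuclei A `nucleus_set`.
#' @param records Filtered records from [filter_myoblasts()].
#' @param source Source filename recorded in the summary.
#' @param scale_um_per_px Optional physical pixel size; when given, the
#'   retained area is also reported in um^2.
#' @return An `image_summary` list.
#' @export
summarize_fusion <- function(nuclei, records, source = "",
                             scale_um_per_px = NA_real_) {
  assignment <- attr(records, "assignment")
  if (is.null(assignment)) assignment <- integer(0)
  ret_labels <- records$label[which(records$retained)]
  total <- nuclei$n
  in_tubes <- sum(assignment != 0L)
  in_ret <- sum(assignment %in% ret_labels)
  area <- sum(records$area[which(records$retained)])
  s <- list(source = source,
            total_nuclei = as.integer(total),
            nuclei_in_tubes = as.integer(in_tubes),
            nuclei_in_retained_tubes = as.integer(in_ret),
            n_retained_tubes = as.integer(sum(records$retained, na.rm = TRUE)),
            retained_tube_area = as.integer(area),
            nfi = if (total > 0) in_ret / total else 0,
            retained_tube_area_um2 =
              if (!is.na(scale_um_per_px)) area * scale_um_per_px^2 else NA_real_)
  class(s) <- "image_summary"
  s
}

#' @export
print.image_summary <- function(x, ...) {
  cat(format_summary_text(x), sep = "\n")
  invisible(x)
}

#' Analyse one culture image end to end
#'
#' Reads the TIFF, extracts the myotube and nuclear channels, segments
#' myotubes, detects nuclei, assigns nuclei to structures, excludes
#' myoblasts (structures with fewer than `min_nuclei` nuclei), and
#' summarises the result. When `out_dir` is given the four diagnostic
#' overlays and the text summary are written there (see
#' [write_outputs()]).
#'
#' @param path Path to a 2- or 3-channel TIFF, or a `myofuse_image`.
#' @param params A [myofuse_params()] object.
#' @param out_dir Optional output directory for the diagnostic files;
#'   `NULL` (default) skips writing.
#' @return A `myofuse_analysis`: list with `summary`, `records`,
#'   `nuclei`, `tubes`, `overlays`, `params`, and (when written)
#'   `output_paths`.
#' @examples
#' cg <- make_culture(height = 256, width = 256, n_tubes = 1,
#'                    nuclei_per_tube = 3, n_free_nuclei = 2, seed = 7)
#' tf <- tempfile(fileext = ".tif")
#' write_culture_tiff(cg$image, tf)
#' res <- analyze_image(tf)
#' res$summary$total_nuclei
#' @export
analyze_image <- function(path, params = myofuse_params(), out_dir = NULL) {
  img <- if (inherits(path, "myofuse_image")) path else read_culture(path)
  validate_params(params, img)
  tube_ch <- select_channel(img, params$myotube_channel)
  nuc_ch <- select_channel(img, params$nuc_channel)
  tubes <- segment_myotubes(tube_ch, params)
  nuclei <- detect_nuclei(nuc_ch, params)
  records <- assign_nuclei(nuclei, tubes)
  records <- filter_myoblasts(records, params$min_nuclei)
  summary <- summarize_fusion(nuclei, records,
                              source = basename(img$source_path),
                              scale_um_per_px = params$scale_um_per_px)
  res <- structure(list(summary = summary, records = records,
                        nuclei = nuclei, tubes = tubes,
                        overlays = render_overlays(img, tubes, nuclei,
                                                   records, params),
                        params = params),
                   class = "myofuse_analysis")
  if (!is.null(out_dir)) res$output_paths <- write_outputs(res, out_dir)
  res
}

#' @export
print.myofuse_analysis <- function(x, ...) {
  cat("Myotube culture analysis of", x$summary$source, "\n")
  cat(format_summary_text(x$summary), sep = "\n")
  invisible(x)
}

#' @export
summary.myofuse_analysis <- function(object, ...) object$summary
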