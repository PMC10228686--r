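#' Read a multi-page TIFF stack
#'
#' One TIFF page per z-plane. Multi-channel pages are reduced to the selected
#' channel (e.g. the neuronal marker channel of a two-channel acquisition).
#'
#' @param path TIFF file path.
#' @param channel channel index for multi-channel pages; `NULL` keeps
#'   single-channel pages as-is (error if the file is multi-channel).
#' @param pixel_size_um optional lateral pixel size to attach.
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path, channel = NULL, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) {
      if (is.null(channel)) {
        stop("multi-channel TIFF: supply a channel index")
      }
      pg[, , channel]
    } else {
      if (!is.null(channel) && channel != 1L) {
        stop("single-channel TIFF but channel > 1 requested")
      }
      pg
    }
  })
  vox <- array(unlist(planes), dim = c(dim(planes[[1L]]), length(planes)))
  image_stack(vox, pixel_size_um = pixel_size_um)
}

#' Write an image stack as multi-page TIFF
#'
#' Intensities are clipped to \[0, 1\] and written at 16 bits per sample.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param path output file path.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  planes <- lapply(seq_len(dim(v)[3L]), function(k) clamp01(v[, , k]))
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write / read a binary mask as PNG
#'
#' @param mask logical matrix (foreground white).
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  structure(img > 0.5, class = c("binary_mask", "matrix", "array"))
}

#' Write a fragment labeling as a 16-bit label TIFF
#'
#' Labels are stored as `label / 65535`, recoverable exactly for up to 65535
#' fragments.
#'
#' @param labeling a [label_fragments()] result.
#' @param path file path.
#' @export
write_labels_tiff <- function(labeling, path) {
  if (labeling$n_fragments > 65535L) {
    stop("more than 65535 fragments cannot be stored in a 16-bit label image")
  }
  tiff::writeTIFF(labeling$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a pseudo-color fragment image as PNG
#'
#' @param rgb_array (y, x, 3) array from [pseudo_color()].
#' @param path file path.
#' @export
write_pseudocolor_png <- function(rgb_array, path) {
  png::writePNG(rgb_array, path)
  invisible(path)
}

#' Write / read physiology tables as long-format CSV
#'
#' Tables are stored with columns exactly `animal_id, group, day, measure,
#' value`: wick rows use measure `"wick_mm"`; blink rows use
#' `"blink_positives_<length>mm"`.
#'
#' @param cohort list with `wick` and `blink` data frames
#'   (see [generate_cohort()]).
#' @param path output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  wick <- data.frame(animal_id = cohort$wick$animal_id,
                     group = cohort$wick$group, day = cohort$wick$day,
                     measure = "wick_mm", value = cohort$wick$wick_mm)
  blink <- data.frame(
    animal_id = cohort$blink$animal_id, group = cohort$blink$group,
    day = cohort$blink$day,
    measure = sprintf("blink_positives_%gmm", cohort$blink$length_mm),
    value = cohort$blink$positives
  )
  write.csv(rbind(wick, blink), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "group", "day", "measure", "value")
                %in% names(long)))
  wick_rows <- long$measure == "wick_mm"
  blink_rows <- grepl("^blink_positives_", long$measure)
  wick <- data.frame(animal_id = long$animal_id[wick_rows],
                     group = long$group[wick_rows],
                     day = long$day[wick_rows],
                     wick_mm = long$value[wick_rows])
  bl <- long[blink_rows, , drop = FALSE]
  blink <- data.frame(
    animal_id = bl$animal_id, group = bl$group, day = bl$day,
    length_mm = as.numeric(sub("^blink_positives_([0-9.]+)mm$", "\\1",
                               bl$measure)),
    positives = as.integer(bl$value)
  )
  list(wick = wick, blink = blink)
}

#' Write synthetic ground truth as sidecar files
#'
#' The scalar truth (fragment count, terminal count, nucleus centers) goes to
#' `<prefix>_truth.json`; the planted coverage mask, when present, to
#' `<prefix>_coverage_mask.png`.
#'
#' @param truth a `synthetic_truth` list.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the JSON path.
#' @export
write_truth_sidecar <- function(truth, dir, prefix) {
  scalars <- truth[setdiff(names(truth),
                           c("true_coverage_mask", "sub_basal_mask",
                             "terminal_mask"))]
  if (!is.null(scalars$nucleus_centers)) {
    scalars$nucleus_centers <- unname(as.matrix(scalars$nucleus_centers))
  }
  json_path <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(scalars, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(truth$true_coverage_mask)) {
    write_mask_png(truth$true_coverage_mask,
                   file.path(dir, paste0(prefix, "_coverage_mask.png")))
  }
  invisible(json_path)
}
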