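#' End-to-end nerve-bed analysis of one confocal stack
#'
#' Runs the full quantification for each requested layer: tiled
#' standard-deviation projection with per-tile plane bounds ([project_stack()]),
#' flood-fill fragment labeling ([label_fragments()]) and coverage /
#' fragmentation metrics ([fragmentation_metrics()]). When `out_dir` is given,
#' writes per layer: the stitched binary mask (PNG), the 16-bit label image
#' (TIFF), the pseudo-color fragment image (PNG), a metrics CSV (one row per
#' layer) and a JSON provenance record (tile rectangles, plane bounds,
#' thresholds).
#'
#' @param stack an [image_stack()] or 3D array.
#' @param layers layers to analyze.
#' @param grid a [tile_grid()]; default 3 x 3 over the stack extent.
#' @param zbounds,window,threshold_method,threshold_scope passed to
#'   [project_stack()].
#' @param connectivity,min_size passed to [label_fragments()].
#' @param out_dir optional output directory (created if missing).
#' @param prefix output file name prefix.
#' @param color_seed seed for pseudo-color assignment.
#' @return named list (per layer) of lists with `mask`, `labeling`,
#'   `metrics`, `provenance`; the combined metrics table is attached as
#'   attribute `"metrics"`.
#' @export
analyze_nerve_stack <- function(stack,
                                layers = c("sub_basal", "epithelial"),
                                grid = NULL, zbounds = "auto", window = 3L,
                                threshold_method = "otsu",
                                threshold_scope = "global",
                                connectivity = 8L, min_size = 0L,
                                out_dir = NULL, prefix = "stack",
                                color_seed = 1L) {
  v <- if (inherits(stack, "image_stack")) stack$voxels else stack
  grid <- grid %||% tile_grid(dim(v)[1:2])
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- lapply(layers, function(layer) {
    pr <- project_stack(stack, layer = layer, grid = grid, zbounds = zbounds,
                        window = window, threshold_method = threshold_method,
                        threshold_scope = threshold_scope)
    lab <- label_fragments(pr$mask, connectivity = connectivity,
                           min_size = min_size)
    met <- fragmentation_metrics(
      lab, pixel_size_um = if (inherits(stack, "image_stack"))
        stack$pixel_size_um else NULL)
    met <- cbind(layer = layer, met)
    if (!is.null(out_dir)) {
      base <- file.path(out_dir, paste0(prefix, "_", layer))
      write_mask_png(pr$mask, paste0(base, "_mask.png"))
      write_labels_tiff(lab, paste0(base, "_labels.tif"))
      write_pseudocolor_png(pseudo_color(lab, seed = color_seed),
                            paste0(base, "_fragments.png"))
      jsonlite::write_json(pr$provenance, paste0(base, "_provenance.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    list(mask = pr$mask, projection = pr$projection, labeling = lab,
         metrics = met, provenance = pr$provenance)
  })
  names(res) <- layers
  metrics <- do.call(rbind, lapply(res, `[[`, "metrics"))
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, paste0(prefix, "_metrics.csv")),
              row.names = FALSE)
  }
  attr(res, "metrics") <- metrics
  res
}

#' Physiology endpoint analysis of a cohort
#'
#' Reduces blink tables to per-animal sensitivity thresholds, summarizes the
#' tear wick with percent change from baseline, and runs the normality-gated
#' group comparison ([group_compare()]) per day for both endpoints. When
#' `out_dir` is given, writes thresholds and wick summary CSVs and a JSON of
#' test results with provenance (test chosen, branch, normality p-values).
#'
#' @param cohort list with `wick` and `blink` data frames.
#' @param baseline_day passed to [wick_summary()].
#' @param out_dir optional output directory.
#' @return list with `thresholds`, `wick_summary`, `tests` (per day, per
#'   endpoint `group_comparison` objects).
#' @export
analyze_endpoints <- function(cohort, baseline_day = NULL, out_dir = NULL) {
  thr <- sensitivity_thresholds(cohort$blink)
  ws <- wick_summary(cohort$wick, baseline_day = baseline_day)
  days <- sort(unique(cohort$wick$day))
  tests <- lapply(days, function(d) {
    w <- cohort$wick[cohort$wick$day == d, ]
    t_ <- thr[thr$day == d, ]
    out <- list()
    if (length(unique(w$group)) >= 2L) {
      out$wick <- group_compare(w$wick_mm, w$group)
    }
    if (nrow(t_) > 0L && length(unique(t_$group)) >= 2L) {
      out$sensitivity <- group_compare(t_$threshold_mm, t_$group)
    }
    out
  })
  names(tests) <- paste0("day", days)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(thr, file.path(out_dir, "sensitivity_thresholds.csv"),
              row.names = FALSE)
    write.csv(ws, file.path(out_dir, "wick_summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(tests, function(day_tests) lapply(day_tests, function(gc) {
        list(test_name = gc$test_name, branch = gc$branch,
             statistic = gc$statistic, p_value = gc$p_value,
             normality_p = as.list(gc$normality_p))
      })),
      file.path(out_dir, "endpoint_tests.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
  }
  list(thresholds = thr, wick_summary = ws, tests = tests)
}
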