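#' Build simulation parameters from a YAML config
#'
#' Maps a YAML mapping onto the matching parameter constructor
#' ([nerve_params()], [epithelium_params()] or [cohort_spec()]); unknown keys
#' are an error, so configs stay honest. Matrix-valued cohort fields
#' (`wick_means_mm`, `threshold_means_mm`) may be given as lists of rows.
#'
#' @param path YAML file path.
#' @param type `"nerve"`, `"epithelium"` or `"cohort"`.
#' @param seed optional seed overriding the config's.
#' @return a parameter object of the matching class.
#' @export
read_sim_config <- function(path, type = c("nerve", "epithelium", "cohort"),
                            seed = NULL) {
  type <- match.arg(type)
  cfg <- yaml::read_yaml(path) %||% list()
  ctor <- switch(type, nerve = nerve_params, epithelium = epithelium_params,
                 cohort = cohort_spec)
  known <- names(formals(ctor))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config keys for type '", type, "': ",
         paste(bad, collapse = ", "))
  }
  for (f in intersect(c("wick_means_mm", "threshold_means_mm"), names(cfg))) {
    cfg[[f]] <- do.call(rbind, cfg[[f]])
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  do.call(ctor, cfg)
}
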