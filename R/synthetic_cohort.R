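#' Default group-by-day means for a desiccation cohort
#'
#' Study design: baseline (day 0), desiccation days 5 and 7, then treatment
#' (vehicle or collagen mimetic peptide, CMP) days 10 and 14. Naive animals
#' stay at baseline. Wick means follow a 43% reduction at day 5 and 60% at
#' day 7 from a 5 mm baseline; sensitivity means are anchored at a 2.65 mm
#' baseline threshold falling to 1.08 mm at day 7, declining further under
#' vehicle and partially recovering under CMP.
#'
#' @return list with matrices `wick_means_mm` and `threshold_means_mm`
#'   (groups x days, dimnames set) and the `days` vector.
#' @export
default_cohort_effects <- function() {
  groups <- c("naive", "vehicle", "cmp")
  days <- c(0, 5, 7, 10, 14)
  wick <- rbind(
    naive   = c(5, 5, 5, 5, 5),
    vehicle = c(5, 2.85, 2.0, 2.0, 2.3),
    cmp     = c(5, 2.85, 2.0, 2.6, 3.8)
  )
  thr <- rbind(
    naive   = c(2.65, 2.65, 2.65, 2.65, 2.65),
    vehicle = c(2.65, 1.8, 1.08, 0.65, 0.85),
    cmp     = c(2.65, 1.8, 1.08, 1.05, 1.75)
  )
  colnames(wick) <- colnames(thr) <- paste0("day", days)
  list(groups = groups, days = days,
       wick_means_mm = wick, threshold_means_mm = thr)
}

#' Specification of a synthetic physiology cohort
#'
#' Defines the groups, measurement days, per-group-per-day mean wick lengths
#' and sensitivity thresholds, and the blink-response model used to generate
#' Cochet-Bonnet tables. The default blink model gives each animal-day a
#' latent threshold around the group mean and a detection probability that is
#' logistic in filament length (longer filament = lower force = harder to
#' detect), hence monotone non-increasing in length.
#'
#' @param groups character vector of group labels.
#' @param n_per_group animals per group; a scalar or a vector named/ordered
#'   like `groups`. The default (13, 11, 11) matches a naive/vehicle/CMP
#'   design.
#' @param days measurement days, sorted ascending.
#' @param wick_means_mm groups x days matrix of mean wick lengths (mm, >= 0).
#' @param wick_sd_mm between-animal wick standard deviation (mm).
#' @param threshold_means_mm groups x days matrix of mean latent sensitivity
#'   thresholds (mm).
#' @param blink_latent_sd SD of the per-animal-day latent threshold (mm).
#' @param blink_scale logistic scale (mm) of the length-response curve.
#' @param blink_prob_model optional `function(length_mm, latent_mm)` returning
#'   a detection probability, overriding the default logistic model.
#' @param lengths_mm tested filament lengths; default the standard set.
#' @param seed integer seed.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(groups = c("naive", "vehicle", "cmp"),
                        n_per_group = c(13L, 11L, 11L),
                        days = c(0, 5, 7, 10, 14),
                        wick_means_mm = NULL,
                        wick_sd_mm = 0.8,
                        threshold_means_mm = NULL,
                        blink_latent_sd = 0.45,
                        blink_scale = 0.25,
                        blink_prob_model = NULL,
                        lengths_mm = c(3.5, 2.5, 2, 1.5, 1, 0.5),
                        seed = 1L) {
  defaults <- default_cohort_effects()
  if (is.null(wick_means_mm) && is.null(threshold_means_mm) &&
      identical(groups, defaults$groups) && identical(days, defaults$days)) {
    wick_means_mm <- defaults$wick_means_mm
    threshold_means_mm <- defaults$threshold_means_mm
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop("days must be sorted strictly ascending")
  }
  if (is.null(wick_means_mm) || is.null(threshold_means_mm)) {
    stop("wick_means_mm and threshold_means_mm are required for ",
         "non-default groups/days")
  }
  wick_means_mm <- as.matrix(wick_means_mm)
  threshold_means_mm <- as.matrix(threshold_means_mm)
  dims_ok <- function(m) all(dim(m) == c(length(groups), length(days)))
  if (!dims_ok(wick_means_mm) || !dims_ok(threshold_means_mm)) {
    stop("mean matrices must be groups x days")
  }
  if (any(wick_means_mm < 0)) stop("wick means must be non-negative")
  if (length(n_per_group) == 1L) {
    n_per_group <- rep(n_per_group, length(groups))
  }
  stopifnot(length(n_per_group) == length(groups), all(n_per_group >= 0))
  if (wick_sd_mm < 0 || blink_latent_sd < 0 || blink_scale <= 0) {
    stop("invalid dispersion parameters")
  }
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 days = days, wick_means_mm = wick_means_mm,
                 wick_sd_mm = wick_sd_mm,
                 threshold_means_mm = threshold_means_mm,
                 blink_latent_sd = blink_latent_sd,
                 blink_scale = blink_scale,
                 blink_prob_model = blink_prob_model,
                 lengths_mm = lengths_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate synthetic tear-wick and blink-response tables
#'
#' Wick lengths are Gaussian around the group-by-day mean, truncated at 0.
#' Blink tables record, per animal-day and per tested filament length, the
#' number of positive responses out of 6 taps, drawn from a binomial with the
#' spec's length-response probability. Generation is a pure function of
#' (spec, seed).
#'
#' @param spec a [cohort_spec()].
#' @return list with data frames `wick` (animal_id, group, day, wick_mm) and
#'   `blink` (animal_id, group, day, length_mm, positives), plus `effects`
#'   (the spec's mean matrices).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  prob_fn <- spec$blink_prob_model %||%
    function(length_mm, latent_mm) {
      plogis((latent_mm - length_mm) / spec$blink_scale)
    }
  wick_rows <- list()
  blink_rows <- list()
  withr::with_seed(spec$seed, {
    for (gi in seq_along(spec$groups)) {
      g <- spec$groups[gi]
      for (ai in seq_len(spec$n_per_group[gi])) {
        id <- sprintf("%s_%02d", g, ai)
        for (di in seq_along(spec$days)) {
          d <- spec$days[di]
          wick <- max(0, rnorm(1, spec$wick_means_mm[gi, di], spec$wick_sd_mm))
          wick_rows[[length(wick_rows) + 1L]] <-
            data.frame(animal_id = id, group = g, day = d, wick_mm = wick)
          latent <- rnorm(1, spec$threshold_means_mm[gi, di],
                          spec$blink_latent_sd)
          pr <- pmin(pmax(prob_fn(spec$lengths_mm, latent), 0), 1)
          pos <- rbinom(length(spec$lengths_mm), 6L, pr)
          blink_rows[[length(blink_rows) + 1L]] <-
            data.frame(animal_id = id, group = g, day = d,
                       length_mm = spec$lengths_mm, positives = pos)
        }
      }
    }
  })
  empty_wick <- data.frame(animal_id = character(), group = character(),
                           day = numeric(), wick_mm = numeric())
  empty_blink <- data.frame(animal_id = character(), group = character(),
                            day = numeric(), length_mm = numeric(),
                            positives = integer())
  list(
    wick = if (length(wick_rows)) do.call(rbind, wick_rows) else empty_wick,
    blink = if (length(blink_rows)) do.call(rbind, blink_rows) else empty_blink,
    effects = list(wick_means_mm = spec$wick_means_mm,
                   threshold_means_mm = spec$threshold_means_mm,
                   days = spec$days, groups = spec$groups)
  )
}
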