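CB_LENGTHS_MM <- c(3.5, 2.5, 2, 1.5, 1, 0.5)

#' Corneal sensitivity threshold from one blink-response table
#'
#' Applies the Cochet-Bonnet positivity rule: a filament length is positive
#' when blinks occurred on at least 3 of the 6 taps. Because a longer
#' monofilament exerts a lower force, responding at a longer length means
#' higher sensitivity, so the threshold is the longest tested length with a
#' positive response; if no length qualifies the threshold is recorded as 0.
#'
#' @param table data frame with columns `length_mm` and `positives`
#'   (integers 0..6), one row per tested length; or a numeric vector of
#'   positives named by length.
#' @return threshold in mm (an element of the tested lengths, or 0).
#' @examples
#' tb <- data.frame(length_mm = c(3.5, 2.5, 2, 1.5, 1, 0.5),
#'                  positives = c(1, 2, 3, 5, 6, 6))
#' sensitivity_threshold(tb) # 2
#' @export
sensitivity_threshold <- function(table) {
  if (is.numeric(table) && !is.null(names(table))) {
    table <- data.frame(length_mm = as.numeric(names(table)),
                        positives = as.numeric(table))
  }
  stopifnot(is.data.frame(table),
            all(c("length_mm", "positives") %in% names(table)))
  if (any(table$positives < 0 | table$positives > 6)) {
    stop("positives must lie in 0..6")
  }
  if (anyDuplicated(table$length_mm)) {
    stop("each filament length may appear at most once")
  }
  if (!all(table$length_mm %in% CB_LENGTHS_MM)) {
    stop("lengths must come from the tested set: ",
         paste(CB_LENGTHS_MM, collapse = ", "))
  }
  if (!all(CB_LENGTHS_MM %in% table$length_mm)) {
    warning("not all standard lengths present; threshold computed over ",
            "those supplied")
  }
  pos <- table$length_mm[table$positives >= 3]
  if (length(pos) == 0L) 0 else max(pos)
}

#' Sensitivity thresholds for every animal-day in a blink table
#'
#' @param blink data frame with columns `animal_id`, `group`, `day`,
#'   `length_mm`, `positives` (as generated by [generate_cohort()]).
#' @return data frame with one row per animal-day: `animal_id`, `group`,
#'   `day`, `threshold_mm`.
#' @export
sensitivity_thresholds <- function(blink) {
  stopifnot(all(c("animal_id", "group", "day", "length_mm", "positives")
                %in% names(blink)))
  if (nrow(blink) == 0L) {
    return(data.frame(animal_id = character(), group = character(),
                      day = numeric(), threshold_mm = numeric()))
  }
  key <- interaction(blink$animal_id, blink$day, drop = TRUE)
  parts <- split(blink, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(animal_id = d$animal_id[1L], group = d$group[1L],
               day = d$day[1L], threshold_mm = sensitivity_threshold(d))
  }))
  rownames(out) <- NULL
  out[order(out$group, out$animal_id, out$day), ]
}

#' Per-group per-day tear-wick summary with percent change from baseline
#'
#' Mean, SEM (sample SD / sqrt(n)) and percent change of the group mean from
#' its baseline-day mean, `100 * (mean_day - mean_baseline) / mean_baseline`.
#' A zero baseline mean leaves the percent change undefined (`NA`) with
#' `baseline_undefined = TRUE`.
#'
#' @param wick data frame with columns `group`, `day`, `wick_mm`.
#' @param baseline_day baseline day; default the earliest day present.
#' @return data frame: `group`, `day`, `n`, `mean_mm`, `sem_mm`,
#'   `pct_change`, `baseline_undefined`.
#' @export
wick_summary <- function(wick, baseline_day = NULL) {
  stopifnot(all(c("group", "day", "wick_mm") %in% names(wick)))
  if (nrow(wick) == 0L) {
    warning("empty wick table: nothing to summarize")
    return(data.frame(group = character(), day = numeric(), n = integer(),
                      mean_mm = numeric(), sem_mm = numeric(),
                      pct_change = numeric(), baseline_undefined = logical()))
  }
  baseline_day <- baseline_day %||% min(wick$day)
  if (!baseline_day %in% wick$day) stop("baseline day not present in data")
  agg <- aggregate(wick_mm ~ group + day, data = wick, FUN = function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- data.frame(group = agg$group, day = agg$day,
                    n = as.integer(agg$wick_mm[, "n"]),
                    mean_mm = agg$wick_mm[, "mean"],
                    sem_mm = agg$wick_mm[, "sem"])
  base <- out[out$day == baseline_day, c("group", "mean_mm")]
  names(base)[2L] <- "base_mean"
  out <- merge(out, base, by = "group", all.x = TRUE)
  out$baseline_undefined <- is.na(out$base_mean) | out$base_mean == 0
  out$pct_change <- ifelse(out$baseline_undefined, NA_real_,
                           100 * (out$mean_mm - out$base_mean) / out$base_mean)
  out$base_mean <- NULL
  out[order(out$group, out$day), ]
}

#' Normality-gated group comparison
#'
#' The dispatch rule used for all endpoint comparisons: each group is checked
#' for normality with a Shapiro-Wilk test at `alpha`; if every group passes,
#' a parametric test is used (Student's t-test for two groups, one-way ANOVA
#' otherwise), and if any group fails, the rank-based analogue is used
#' (Mann-Whitney for two groups, Kruskal-Wallis otherwise). Groups too small
#' or too degenerate for a normality test route to the nonparametric branch
#' with a warning; fully constant identical data is flagged as degenerate.
#'
#' @param values numeric vector of measurements.
#' @param group grouping vector (coerced to factor).
#' @param paired logical; for two groups, use paired tests (values must be
#'   ordered consistently within each group).
#' @param alpha normality-test significance level (default 0.05).
#' @param var_equal use the classical equal-variance Student's t-test
#'   (default `TRUE`); set `FALSE` for Welch.
#' @return a `group_comparison` list: `test_name`, `branch`, `statistic`,
#'   `p_value`, `normality_p` (per group), `summary` (n/mean/sem per group),
#'   `degenerate`.
#' @export
group_compare <- function(values, group, paired = FALSE, alpha = 0.05,
                          var_equal = TRUE) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  parts <- split(values, group)
  if (length(parts) < 2L) stop("need at least two groups")
  summ <- data.frame(
    group = names(parts),
    n = vapply(parts, length, integer(1)),
    mean = vapply(parts, mean, numeric(1)),
    sem = vapply(parts, function(v)
      if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_, numeric(1))
  )
  rownames(summ) <- NULL

  if (length(unique(values)) == 1L) {
    return(structure(list(test_name = "degenerate", branch = "none",
                          statistic = NA_real_, p_value = NA_real_,
                          normality_p = setNames(rep(NA_real_, length(parts)),
                                                 names(parts)),
                          summary = summ, degenerate = TRUE),
                     class = "group_comparison"))
  }

  norm_p <- vapply(parts, function(v) {
    if (length(v) < 3L || length(v) > 5000L || sd(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1))
  if (anyNA(norm_p)) {
    warning("normality untestable for at least one group; ",
            "using the nonparametric branch")
  }
  parametric <- !anyNA(norm_p) && all(norm_p > alpha)

  two <- length(parts) == 2L
  if (parametric) {
    if (two) {
      tt <- t.test(parts[[1L]], parts[[2L]], paired = paired,
                   var.equal = var_equal)
      res <- list(test_name = if (paired) "paired t-test" else
        "Student's t-test", statistic = unname(tt$statistic),
        p_value = tt$p.value)
    } else {
      fit <- aov(values ~ group)
      s <- summary(fit)[[1L]]
      res <- list(test_name = "one-way ANOVA",
                  statistic = s[["F value"]][1L],
                  p_value = s[["Pr(>F)"]][1L])
    }
    branch <- "parametric"
  } else {
    if (two) {
      wt <- suppressWarnings(
        wilcox.test(parts[[1L]], parts[[2L]], paired = paired, exact = FALSE)
      )
      res <- list(test_name = if (paired) "Wilcoxon signed-rank" else
        "Mann-Whitney U", statistic = unname(wt$statistic),
        p_value = wt$p.value)
    } else {
      kt <- kruskal.test(values, group)
      res <- list(test_name = "Kruskal-Wallis (ANOVA on ranks)",
                  statistic = unname(kt$statistic), p_value = kt$p.value)
    }
    branch <- "nonparametric"
  }
  structure(c(res, list(branch = branch, normality_p = norm_p,
                        summary = summ, degenerate = FALSE)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<group_comparison> degenerate (constant data)\n")
    return(invisible(x))
  }
  cat(sprintf("<group_comparison> %s (%s): statistic = %.4g, p = %.4g\n",
              x$test_name, x$branch, x$statistic, x$p_value))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: n = %d, mean = %.3g +/- %.3g (SEM)\n",
                x$summary$group[i], x$summary$n[i], x$summary$mean[i],
                x$summary$sem[i]))
  }
  invisible(x)
}
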