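std_table <- function(positives) {
  data.frame(length_mm = c(3.5, 2.5, 2, 1.5, 1, 0.5), positives = positives)
}

test_that("sensitivity threshold applies the 3-of-6 rule over lengths", {
  expect_equal(sensitivity_threshold(std_table(rep(6, 6))), 3.5)
  expect_equal(sensitivity_threshold(std_table(c(1, 2, 3, 5, 6, 6))), 2)
  expect_equal(sensitivity_threshold(std_table(rep(0, 6))), 0)
  expect_equal(sensitivity_threshold(std_table(rep(2, 6))), 0)

  expect_error(sensitivity_threshold(std_table(c(7, 0, 0, 0, 0, 0))), "0..6")
  expect_error(sensitivity_threshold(
    data.frame(length_mm = c(3.5, 3.5), positives = c(3, 3))), "at most once")
  expect_error(sensitivity_threshold(
    data.frame(length_mm = 4, positives = 3)), "tested set")
  expect_warning(
    t_part <- sensitivity_threshold(
      data.frame(length_mm = c(2, 1), positives = c(4, 6))),
    "not all standard lengths"
  )
  expect_equal(t_part, 2)
})

test_that("threshold matches the descending-scan oracle on sampled tables", {
  withr::with_seed(101, {
    for (i in 1:2000) {
      pos <- sample(0:6, 6, replace = TRUE)
      expect_equal(sensitivity_threshold(std_table(pos)),
                   oracle_threshold(c(3.5, 2.5, 2, 1.5, 1, 0.5), pos))
    }
  })
})

test_that("wick summary computes means, SEM and percent change", {
  w <- data.frame(
    group = rep("vehicle", 6),
    day = rep(c(0, 5), each = 3),
    wick_mm = c(4.9, 5.0, 5.1, 2.75, 2.85, 2.95)
  )
  ws <- wick_summary(w)
  expect_equal(ws$mean_mm, c(5, 2.85))
  expect_equal(ws$pct_change, c(0, -43))
  expect_equal(ws$sem_mm[1], sd(c(4.9, 5, 5.1)) / sqrt(3))

  # single day equals baseline: 0% change
  one <- wick_summary(data.frame(group = "g", day = 0, wick_mm = c(3, 4)))
  expect_equal(one$pct_change, 0)

  # zero baseline flagged, not an error
  z <- wick_summary(data.frame(group = "g", day = c(0, 0, 5, 5),
                               wick_mm = c(0, 0, 1, 2)))
  expect_true(all(z$baseline_undefined))
  expect_true(all(is.na(z$pct_change)))

  expect_warning(empty <- wick_summary(
    data.frame(group = character(), day = numeric(), wick_mm = numeric())),
    "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("normality-gated dispatch picks the right branch", {
  withr::with_seed(7, {
    norm2 <- group_compare(rnorm(60), rep(c("a", "b"), each = 30))
    expect_equal(norm2$branch, "parametric")
    expect_equal(norm2$test_name, "Student's t-test")
    norm3 <- group_compare(rnorm(90), rep(c("a", "b", "c"), each = 30))
    expect_equal(norm3$test_name, "one-way ANOVA")
    skew <- group_compare(c(rexp(30)^2, rexp(30)^2),
                          rep(c("a", "b"), each = 30))
    expect_equal(skew$branch, "nonparametric")
    skew3 <- group_compare(c(rexp(30)^2, rexp(30)^2, rexp(30)^2),
                           rep(c("a", "b", "c"), each = 30))
    expect_equal(skew3$test_name, "Kruskal-Wallis (ANOVA on ranks)")
  })

  cc <- group_compare(rep(1, 10), rep(c("a", "b"), each = 5))
  expect_true(cc$degenerate)
  expect_true(is.na(cc$p_value))

  expect_warning(
    tiny <- group_compare(c(1, 2, 1.5, 2.5), rep(c("a", "b"), each = 2)),
    "untestable"
  )
  expect_equal(tiny$branch, "nonparametric")
  expect_error(group_compare(1:5, rep("a", 5)), "two groups")
})

test_that("dispatched pipeline keeps its nominal level on null cohorts", {
  withr::with_seed(20, {
    p_par <- replicate(400, group_compare(rnorm(40),
                                          rep(c("a", "b"), each = 20))$p_value)
    p_np <- replicate(400, group_compare(rexp(40)^2,
                                         rep(c("a", "b"), each = 20))$p_value)
  })
  expect_gt(mean(p_par < 0.05), 0.02)
  expect_lt(mean(p_par < 0.05), 0.09)
  expect_gt(mean(p_np < 0.05), 0.02)
  expect_lt(mean(p_np < 0.05), 0.09)
})

test_that("per-animal threshold reduction keeps group/day structure", {
  co <- generate_cohort(cohort_spec(n_per_group = 3, seed = 2))
  thr <- sensitivity_thresholds(co$blink)
  expect_equal(nrow(thr), 3 * 3 * 5)
  expect_equal(sort(unique(thr$day)), c(0, 5, 7, 10, 14))
  expect_true(all(table(thr$animal_id) == 5))
})
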