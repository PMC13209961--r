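# Benchmark summaries and threshold derivation.

test_that("benchmark summaries reproduce the reference per-target means", {
  s <- summarize_benchmark(fda_benchmark())
  expect_equal(s$n_total, 48L)
  per <- s$per_target
  expect_equal(round(per$mean_affinity[per$target_id == "VEGFR-2"], 2), -9.77)
  expect_equal(round(per$mean_affinity[per$target_id == "EGFR"], 2), -7.95)
  g <- glance(s)
  expect_equal(round(g$mean_affinity, 2), -9.32)
  expect_equal(g$min_affinity, -11.86)
  expect_equal(sum(per$n), s$n_total)
})

test_that("a single-record table has mean = min = max", {
  one <- score_table(tibble::tibble(
    ligand_id = "x", target_id = "T", affinity = -8.5,
    cnn_pose_score = 0.9, cnn_affinity = 7.5))
  s <- summarize_benchmark(one)
  expect_equal(s$overall$mean, s$overall$min)
  expect_equal(s$overall$mean, s$overall$max)
  expect_error(summarize_benchmark(one[0, ]), "empty")
})

test_that("soft thresholds match an independent closed-form recomputation", {
  set.seed(99)
  n <- 40
  tbl <- score_table(tibble::tibble(
    ligand_id = sprintf("l%02d", 1:n), target_id = "T",
    affinity = rnorm(n, -9, 1.2),
    cnn_pose_score = pmin(1, pmax(0, rnorm(n, 0.85, 0.07))),
    cnn_affinity = rnorm(n, 7.8, 0.3)))

  for (method in c("normal", "student_t")) {
    ts <- derive_soft_thresholds(tbl, threshold_config(0.05, method))
    q <- if (method == "normal") qnorm(0.95) else qt(0.95, n - 1)
    expect_equal(ts$soft$affinity,
                 mean(tbl$affinity) + q * sd(tbl$affinity) / sqrt(n))
    expect_equal(ts$soft$cnn_pose_score,
                 mean(tbl$cnn_pose_score) - q * sd(tbl$cnn_pose_score) / sqrt(n))
    expect_equal(ts$soft$cnn_affinity,
                 mean(tbl$cnn_affinity) - q * sd(tbl$cnn_affinity) / sqrt(n))
  }
})

test_that("identical records give soft = common value and n < 2 errors", {
  same <- score_table(tibble::tibble(
    ligand_id = c("a", "b", "c"), target_id = "T", affinity = -9.5,
    cnn_pose_score = 0.9, cnn_affinity = 7.7))
  ts <- derive_soft_thresholds(same)
  expect_equal(ts$soft$affinity, -9.5)
  expect_equal(ts$soft$cnn_pose_score, 0.9)
  expect_error(derive_soft_thresholds(same[1, ]), "at least 2")
})

test_that("hard thresholds are the benchmark extremes and are stable to
           interior points", {
  ts <- derive_hard_thresholds(fda_benchmark())
  expect_equal(ts$hard$affinity, -6.82)
  expect_equal(ts$hard$cnn_pose_score, 0.526)
  expect_equal(ts$hard$cnn_affinity, 7.010)

  inside <- tibble::tibble(ligand_id = "mid", target_id = "T",
                           affinity = -9, cnn_pose_score = 0.8,
                           cnn_affinity = 7.5)
  ts2 <- derive_hard_thresholds(dplyr::bind_rows(fda_benchmark(), inside))
  expect_equal(ts2$hard, ts$hard)
})

test_that("soft bounds sit strictly between mean and hard bound", {
  bench <- fda_benchmark()
  ts <- derive_thresholds(bench)
  # affinity (lower-is-better): mean < soft upper bound < hard maximum
  expect_gt(ts$soft$affinity, mean(bench$affinity))
  expect_lt(ts$soft$affinity, ts$hard$affinity)
  # maximize-metrics: hard minimum < soft lower bound < mean
  expect_gt(ts$soft$cnn_pose_score, ts$hard$cnn_pose_score)
  expect_lt(ts$soft$cnn_pose_score, mean(bench$cnn_pose_score))
  expect_gt(ts$soft$cnn_affinity, ts$hard$cnn_affinity)
  expect_lt(ts$soft$cnn_affinity, mean(bench$cnn_affinity))
})

test_that("category overrides return per-target mean affinities", {
  bench <- fda_benchmark()
  expect_equal(round(category_override(bench, "EGFR"), 2), -7.95)
  expect_equal(round(category_override(bench, "VEGFR-2"), 2), -9.77)
  expect_error(category_override(bench, "ABL2"), "ABL2")

  # target with one drug: the override is that drug's affinity
  one <- score_table(tibble::tibble(
    ligand_id = "only", target_id = "Solo", affinity = -7.1,
    cnn_pose_score = 0.8, cnn_affinity = 7.2))
  expect_equal(category_override(one, "Solo"), -7.1)

  ts <- derive_thresholds(bench, override_targets = "EGFR")
  expect_equal(ts$category_overrides$EGFR, category_override(bench, "EGFR"))
})

test_that("thresholds survive a JSON round trip", {
  ts <- derive_thresholds(fda_benchmark(), override_targets = c("EGFR"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_thresholds(ts, tmp)
  back <- read_thresholds(tmp)
  expect_equal(back$soft$affinity, ts$soft$affinity)
  expect_equal(back$hard$cnn_affinity, ts$hard$cnn_affinity)
  expect_equal(back$category_overrides$EGFR, ts$category_overrides$EGFR)
  expect_equal(back$alpha, ts$alpha)
})

test_that("tidy/glance expose thresholds as tables", {
  ts <- derive_thresholds(fda_benchmark(), override_targets = "EGFR")
  td <- tidy(ts)
  expect_equal(sum(td$bound == "soft"), 3L)
  expect_equal(sum(td$bound == "hard"), 3L)
  expect_true(any(grepl("EGFR", td$bound)))
  expect_equal(glance(ts)$n, 48L)
})
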