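# a two-model grid with made-up but complete values, for summary arithmetic
demo_grid <- function() {
  metrics_table(data.frame(
    model = rep(c("a", "b"), each = 3),
    method = rep(c("reference", "integrated_gradients", "guided"), 2),
    pixel = c(0.65, 0.61, 0.81, 0.58, 0.60, 0.67),
    sectional = c(0.75, 0.71, 0.76, 0.60, 0.64, 0.65),
    interval = c(0.79, 0.77, 0.89, 0.66, 0.69, 0.77),
    congruence = c(0.48, 0.44, 0.60, 0.37, 0.39, 0.32)))
}

test_that("metrics tables validate their grid", {
  expect_s3_class(demo_grid(), "metrics_table")
  expect_error(metrics_table(data.frame(model = "a")), "columns")
  bad <- as.data.frame(demo_grid()); bad$pixel[1] <- 1.4
  expect_error(metrics_table(bad), "\\[0, 1\\]")
})

test_that("summary arithmetic is zero on identical models, antisymmetric otherwise", {
  tbl <- demo_grid()
  dup <- tbl; dup$model[dup$model == "b"] <- "a2"
  dup$pixel[4:6] <- tbl$pixel[1:3]; dup$sectional[4:6] <- tbl$sectional[1:3]
  dup$interval[4:6] <- tbl$interval[1:3]
  dup$congruence[4:6] <- tbl$congruence[1:3]
  s0 <- summarize_differences(metrics_table(dup), "a", "a2")
  expect_equal(s0$mean_congruence_diff, 0)
  expect_equal(s0$mean_ac_diff, 0)

  ab <- summarize_differences(tbl, "a", "b")
  ba <- summarize_differences(tbl, "b", "a")
  expect_equal(ab$mean_congruence_diff, -ba$mean_congruence_diff)
  expect_equal(ab$mean_ac_diff, -ba$mean_ac_diff)
  expect_equal(ab$per_variant_means, ba$per_variant_means)
  # direct arithmetic on the known grid
  expect_equal(ab$per_model_mean_congruence[["a"]], mean(c(0.48, 0.44, 0.60)))
  expect_equal(ab$mean_congruence_diff,
               mean(c(0.48, 0.44, 0.60)) - mean(c(0.37, 0.39, 0.32)))
  # incomplete grids are refused
  incomplete <- as.data.frame(tbl)[-1, ]
  expect_error(summarize_differences(metrics_table(incomplete), "a", "b"),
               "incomplete|different")
})

test_that("pearson correlation matches hand arithmetic and brute force", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_equal(pearson_cor(x, c(1, 3, 2, 4))$r, 0.8)
  set.seed(41)
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(length(a))
    res <- pearson_cor(a, b)
    brute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(res$r, brute, tolerance = 1e-12)
    expect_true(res$p >= 0 && res$p <= 1)
  }
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
})

test_that("model comparison fills the complete model x method grid", {
  ds <- tiny_dataset(0, 5, seed = 43)
  m1 <- tiny_cnn(ncol(ds$x), seed = 1, channels = 5)
  m2 <- tiny_cnn(ncol(ds$x), seed = 2, channels = 5)
  tbl <- suppressMessages(
    compare_models(list(one = m1, two = m2, one_again = m1), ds,
                   methods = c("guided", "integrated_gradients"),
                   ig_steps = 8))
  expect_identical(nrow(tbl), 6L)  # |models| x |methods|
  expect_true(attr(tbl, "complete"))
  expect_true(all(as.matrix(tbl[c("pixel", "sectional", "interval",
                                  "congruence")]) >= 0, na.rm = TRUE))
  # identical models give identical rows
  expect_equal(tbl[tbl$model == "one", -1], tbl[tbl$model == "one_again", -1],
               ignore_attr = TRUE)
})

test_that("degenerate cells are flagged and mark the grid incomplete", {
  # an untrained head whose weights are all negative sends zero guided
  # gradient everywhere; the congruence of that cell is undefined
  ds <- tiny_dataset(0, 5, seed = 43)
  m <- tiny_cnn(ncol(ds$x), seed = 1, channels = 3)
  stopifnot(all(m$params$w_fc < 0))
  w <- capture_warnings(tbl <- compare_models(list(bad = m), ds,
                                              methods = "guided"))
  expect_true(any(grepl("degenerate", w)))
  expect_true(is.na(tbl$congruence[1]))
  expect_false(attr(tbl, "complete"))
})

test_that("perfect attention in place of saliency yields an all-ones row", {
  ds <- tiny_dataset(0, 4, seed = 47)
  masks <- ds$mask[annotated_records(ds)]
  perfect <- lapply(masks, as.numeric)
  met <- suppressMessages(explainability_metrics(ds, perfect))
  expect_equal(met$congruence, 1)
  expect_equal(met$pixel, 1)
  expect_equal(met$sectional, 1)
  expect_equal(met$interval, 1)
})

test_that("the correlation study emits a well-formed Bonferroni report", {
  train <- tiny_dataset(8, 8, duration_s = 8, fs = 30, seed = 53)
  test <- tiny_dataset(5, 5, duration_s = 8, fs = 30, seed = 59)
  cfg <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 4,
                      seed = 1)
  st <- suppressMessages(explainability_performance_study(
    train, test, fractions = 0.5, reps = 2, config = cfg,
    model_args = list(depth = 1, channels = 3, kernel_size = 11, pool = 4),
    method = "integrated_gradients", seed = 61))
  expect_s3_class(st, "explainability_study")
  expect_identical(nrow(st$records), 2L)
  expect_identical(nrow(st$report), 6L)
  expect_true(all(c("r", "p", "n", "bonferroni_alpha", "significant") %in%
                  names(st$report)))
  expect_equal(unique(st$report$bonferroni_alpha), 0.05 / 6)
  # n = 2 pairs: insufficient for a correlation test, p reported NA
  expect_true(all(is.na(st$report$p)))
  expect_true(all(st$report$metric_1[st$report$metric_2 == "NPV"] ==
                  "Pixel Classification"))
  # reproducible end to end from the master seed
  st2 <- suppressMessages(explainability_performance_study(
    train, test, fractions = 0.5, reps = 2, config = cfg,
    model_args = list(depth = 1, channels = 3, kernel_size = 11, pool = 4),
    method = "integrated_gradients", seed = 61))
  expect_identical(st$records, st2$records)
})

test_that("metrics tables serialize to csv, json and markdown", {
  tbl <- demo_grid()
  for (fmt in c("csv", "json", "markdown")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_metrics_table(tbl, path, fmt)
    expect_true(file.exists(path))
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(tbl, csv, "csv")
  back <- read.csv(csv)
  expect_equal(back$congruence, tbl$congruence)
})
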