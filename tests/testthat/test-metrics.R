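test_that("congruence follows the attention-mass proportion", {
  expect_equal(congruence(c(0.3, 2, 1), c(1, 1, 1)), 1)
  expect_equal(congruence(c(1, 1, 2), c(0, 1, 1)), 0.75)
  expect_equal(congruence(c(2, 0, 0), c(0, 1, 1)), 0)
  # uniform attention: sum(z) / n exactly
  mask <- c(1, 1, 0, 0, 0, 1)
  expect_equal(congruence(rep(0.2, 6), mask), sum(mask) / 6)
  expect_error(congruence(c(0, 0, 0), c(0, 1, 0)), "undefined congruence")
  expect_error(congruence(c(-1, 2), c(0, 1)), "nonnegative")
})

test_that("congruence is invariant to positive rescaling and stays in [0,1]", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    att <- runif(n)
    mask <- as.integer(runif(n) < 0.4)
    if (sum(att) == 0) next
    v <- congruence(att, mask)
    expect_gte(v, 0); expect_lte(v, 1)
    for (c in c(1e-6, 3, 1e6))
      expect_equal(congruence(c * att, mask), v, tolerance = 1e-12)
  }
})

test_that("dataset congruence averages records and skips zero-mass maps", {
  m1 <- c(1, 0, 0, 0, 0); m2 <- c(1, 1, 0, 0, 0)
  a1 <- synthetic_attention(m1, 0.2, "uniform")
  a2 <- synthetic_attention(m2, 0.4, "uniform")
  expect_equal(congruence_dataset(list(a1, a2), list(m1, m2)), 0.3)
  expect_equal(congruence_dataset(list(a1), list(m1)), 0.2)
  expect_warning(
    v <- congruence_dataset(list(a1, rep(0, 5)), list(m1, m2)),
    "zero attention")
  expect_equal(v, 0.2)
  expect_error(
    suppressWarnings(congruence_dataset(list(rep(0, 5)), list(m1))),
    "every record")
})

test_that("auroc equals the Mann-Whitney pair count, including ties", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.7, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(c(1, 2), c(1, 1)), "degenerate")
  set.seed(15)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # heavy ties
    labels <- as.integer(runif(n) < 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  for (i in 1:5) {
    scores <- c(rnorm(30, 1), rnorm(40))
    labels <- rep(c(1, 0), c(30, 40))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("auroc is invariant under strictly increasing score transforms", {
  set.seed(17)
  scores <- runif(60); labels <- as.integer(runif(60) < 0.5)
  base <- auroc(scores, labels)
  for (f in list(function(s) 10 * s - 2, exp, function(s) s^3 + s))
    expect_equal(auroc(f(scores), labels), base, tolerance = 1e-12)
})

test_that("the threshold-sweep ROC curve matches the rank-based area", {
  # perfect separation passes through (0, 1)
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(rc$auroc, 1)
  # all ties: the two corner points, area one half
  rc2 <- roc_curve(rep(0.3, 4), c(1, 0, 1, 0))
  expect_equal(rc2$fpr, c(0, 1)); expect_equal(rc2$tpr, c(0, 1))
  expect_equal(rc2$auroc, 0.5)
  expect_equal(roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auroc, 0.75)
  # structural invariants and exact agreement with auroc() on random data
  set.seed(18)
  for (i in 1:25) {
    n <- sample(4:300, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    labels <- as.integer(runif(n) < 0.5)
    if (length(unique(labels)) < 2) next
    rc <- roc_curve(scores, labels)
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[length(rc$fpr)], 1)
    expect_equal(rc$tpr[length(rc$tpr)], 1)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(rc$auroc, auroc(scores, labels), tolerance = 1e-12)
  }
})

test_that("pixel units pool samples across records", {
  atts <- list(a = c(0.1, 0.9, 0.8, 0.2, 0.3), b = c(0.5, 0.6, 0.1, 0, 0.2))
  masks <- list(a = c(0, 1, 1, 0, 0), b = c(1, 1, 0, 0, 0))
  u <- pixel_units(atts, masks)
  expect_identical(nrow(u), 10L)
  expect_identical(attr(u, "unit_kind"), "pixel")
  # attention identical to the mask separates perfectly
  expect_equal(auroc(pixel_units(masks, masks)), 1)
  # attention independent of the mask: near-chance AUROC on 1e4 samples
  set.seed(19)
  mask <- as.integer(runif(1e4) < 0.3)
  att <- runif(1e4)
  expect_lt(abs(auroc(pixel_units(list(att), list(mask))) - 0.5), 0.05)
})

test_that("sectional units score runs by their maximum attention", {
  u <- sectional_units(list(c(0.1, 0.2, 0.9, 0.8, 0.3)),
                       list(c(0, 0, 1, 1, 0)))
  expect_equal(u$score, c(0.2, 0.9, 0.3))
  expect_equal(u$label, c(0L, 1L, 0L))
  # an all-artifact record contributes a single positive unit
  u2 <- sectional_units(list(c(0.5, 0.7)), list(c(1, 1)))
  expect_identical(nrow(u2), 1L)
  expect_identical(u2$label, 1L)
})

test_that("interval units tile records by fixed durations", {
  # hand tiling: 2-sample intervals at fs = 1 Hz
  u <- interval_units(list(c(0, 0, 5, 4, 1, 0)), list(c(0, 0, 1, 1, 0, 0)),
                      fs = 1, interval_len_s = 2)
  expect_equal(u$score, c(0, 5, 1))
  expect_equal(u$label, c(0L, 1L, 0L))
  # default geometry: a 30-s record in 5-s intervals gives exactly 6 units
  mask <- integer(7201); mask[3000:3001] <- 1L
  u6 <- interval_units(list(runif(7201)), list(mask), fs = 240,
                       interval_len_s = 5)
  expect_identical(nrow(u6), 6L)
  # any-overlap rule: the single annotated pair sits in interval 3 (index 2)
  expect_identical(which(u6$label == 1L), 3L)
  # interval longer than the record: one whole-record unit with a warning
  expect_warning(
    u1 <- interval_units(list(runif(100)), list(c(rep(0L, 50), rep(1L, 50))),
                         fs = 10, interval_len_s = 60),
    "whole-record")
  expect_identical(nrow(u1), 1L)
})

test_that("annotation classification hits the perfect and chance corners", {
  set.seed(20)
  masks <- lapply(1:4, function(i) {
    m <- integer(120); m[sample(10:100, 1) + 0:15] <- 1L; m
  })
  exact <- lapply(masks, as.numeric)
  unif <- lapply(masks, function(m) rep(1 / 120, 120))
  for (v in c("pixel", "sectional", "interval")) {
    expect_equal(annotation_classification(exact, masks, v, fs = 12), 1)
    expect_equal(annotation_classification(unif, masks, v, fs = 12), 0.5)
  }
  # attention = mask + vanishing noise still classifies perfectly
  eps <- lapply(masks, function(m) m + 1e-9 * runif(120))
  for (v in c("pixel", "sectional", "interval"))
    expect_equal(annotation_classification(eps, masks, v, fs = 12), 1)
  # single-class pooled units are degenerate
  expect_error(annotation_classification(list(c(0.1, 0.2)), list(c(1, 1)),
                                         "pixel"),
               "degenerate")
})

test_that("pixel AUROC increases with the attention mass inside annotations", {
  masks <- lapply(1:6, function(i) {
    m <- integer(400); m[(50 * i):(50 * i + 60)] <- 1L; m
  })
  au <- function(p) {
    atts <- lapply(seq_along(masks), function(i)
      synthetic_attention(masks[[i]], p, "random_uniform", seed = i))
    annotation_classification(atts, masks, "pixel")
  }
  expect_gt(au(0.9), au(0.5))
})
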