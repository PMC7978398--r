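#' Congruence of an attention map with an annotation mask
#'
#' The proportion of the model's attention mass that falls inside the
#' expert-annotated region:
#' `Cong(z, zhat) = sum_j z_j * zhat_j / sum_j zhat_j`,
#' where `z` is the binary annotation and `zhat` the nonnegative attention.
#' Scale-free: multiplying the attention by any positive constant leaves
#' the value unchanged. Undefined when the attention mass is zero.
#'
#' @param attention Nonnegative numeric vector.
#' @param mask Binary 0/1 vector of the same length.
#' @return A number in `[0, 1]`.
#' @examples
#' congruence(c(1, 1, 2), c(0, 1, 1))  # (1 + 2) / 4 = 0.75
#' @export
congruence <- function(attention, mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  check_attention(attention, length(mask))
  total <- sum(attention)
  if (total == 0) stop("undefined congruence: total attention mass is zero")
  sum(attention[mask == 1]) / total
}

#' Mean congruence over a dataset
#'
#' Unweighted arithmetic mean of the per-record congruences. Records whose
#' attention mass is zero have undefined congruence and are skipped with a
#' warning; it is an error if every record is skipped.
#'
#' @param attentions List of nonnegative attention vectors.
#' @param masks List of binary masks, parallel to `attentions` (matched by
#'   name when both are named).
#' @return Mean congruence in `[0, 1]`.
#' @export
congruence_dataset <- function(attentions, masks) {
  if (!is.null(names(attentions)) && !is.null(names(masks)))
    masks <- masks[names(attentions)]
  stopifnot(length(attentions) == length(masks), length(attentions) > 0)
  vals <- numeric(0); skipped <- 0L
  for (i in seq_along(attentions)) {
    if (sum(attentions[[i]]) == 0) { skipped <- skipped + 1L; next }
    vals <- c(vals, congruence(attentions[[i]], masks[[i]]))
  }
  if (skipped > 0)
    warning(skipped, " record(s) with zero attention mass skipped from congruence")
  if (!length(vals)) stop("congruence undefined for every record")
  mean(vals)
}

#' Bundle scores and binary labels for ROC analysis
#'
#' @param scores Real-valued scores (attention summaries).
#' @param labels Binary 0/1 labels (1 = annotated).
#' @param unit_kind What one unit is: `"pixel"`, `"section"`, or
#'   `"interval"`.
#' @return A data.frame of class `scored_units` with columns `score`,
#'   `label` and attribute `unit_kind`.
#' @export
scored_units <- function(scores, labels, unit_kind = c("pixel", "section",
                                                       "interval")) {
  unit_kind <- match.arg(unit_kind)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  structure(data.frame(score = as.numeric(scores), label = as.integer(labels)),
            unit_kind = unit_kind, class = c("scored_units", "data.frame"))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: over all (positive, negative)
#' unit pairs, the fraction in which the positive scores higher, counting
#' ties as one half. Identical to the trapezoidal area under
#' [roc_curve()].
#'
#' @param scores A numeric score vector or a [scored_units()] object.
#' @param labels Binary labels (ignored when `scores` is `scored_units`).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auroc <- function(scores, labels = NULL) {
  if (inherits(scores, "scored_units")) {
    labels <- scores$label; scores <- scores$score
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate AUROC: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold through the sorted distinct scores (tied
#' scores cross the threshold together), recording one operating point per
#' distinct score plus the all-negative corner. The `auroc` field is the
#' trapezoidal area and equals [auroc()] exactly.
#'
#' @inheritParams auroc
#' @return An object of class `roc_curve` with elements `fpr`, `tpr`,
#'   `thresholds` and `auroc`.
#' @export
roc_curve <- function(scores, labels = NULL) {
  if (inherits(scores, "scored_units")) {
    labels <- scores$label; scores <- scores$score
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate ROC: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tpr <- c(0, cumsum(y == 1)[keep] / n1)
  fpr <- c(0, cumsum(y == 0)[keep] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[keep]), auroc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d operating points, AUROC %.4f>\n",
              length(x$fpr), x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate", xlim = c(0, 1), ylim = c(0, 1),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# match attention and mask lists by name where possible
align_pairs <- function(attentions, masks) {
  if (!is.null(names(attentions)) && !is.null(names(masks)))
    masks <- masks[names(attentions)]
  stopifnot(length(attentions) == length(masks))
  for (i in seq_along(attentions))
    check_attention(attentions[[i]], length(masks[[i]]))
  list(attentions = attentions, masks = masks)
}

#' Pixel units: one scored unit per sample
#'
#' Pools every sample of every record into one collection: the score is the
#' attention on the sample, the label whether the sample is annotated.
#'
#' @param attentions List of nonnegative attention vectors.
#' @param masks Parallel list of binary masks.
#' @return A [scored_units()] of kind `"pixel"`.
#' @export
pixel_units <- function(attentions, masks) {
  p <- align_pairs(attentions, masks)
  scored_units(unlist(p$attentions, use.names = FALSE),
               unlist(p$masks, use.names = FALSE), "pixel")
}

#' Sectional units: one scored unit per annotation-delimited run
#'
#' Each record is split into its maximal constant-annotation sections
#' ([mask_to_sections()]); a unit's score is the maximum attention within
#' the section and its label the section's annotation value.
#'
#' @inheritParams pixel_units
#' @return A [scored_units()] of kind `"section"`.
#' @export
sectional_units <- function(attentions, masks) {
  p <- align_pairs(attentions, masks)
  scores <- numeric(0); labels <- integer(0)
  for (i in seq_along(p$attentions)) {
    sec <- mask_to_sections(p$masks[[i]])
    att <- p$attentions[[i]]
    scores <- c(scores, vapply(seq_len(nrow(sec)), function(r)
      max(att[(sec$start[r] + 1L):sec$end[r]]), numeric(1)))
    labels <- c(labels, sec$value)
  }
  scored_units(scores, labels, "section")
}

# 0-based interval index of each sample under fixed-duration tiling; the
# segment's inclusive endpoint sample joins the final interval, so a 30-s
# segment at 5-s intervals yields exactly six units
interval_index <- function(n, fs, interval_len_s) {
  len <- round(interval_len_s * fs)
  if (len < 1) stop("interval_len_s too short for the sampling rate")
  n_int <- ceiling((n - 1) / len)
  if (n_int < 1) n_int <- 1
  pmin((seq_len(n) - 1L) %/% len, n_int - 1L)
}

#' Interval units: one scored unit per fixed-duration tile
#'
#' Each record is tiled into consecutive intervals of `interval_len_s`
#' seconds (a final shorter remainder is kept as its own interval; the
#' inclusive endpoint sample joins the last interval). A unit's score is
#' the maximum attention in the tile; its label is 1 if any annotated
#' sample overlaps the tile.
#'
#' @inheritParams pixel_units
#' @param fs Sampling rate in Hz.
#' @param interval_len_s Tile length in seconds (default 5).
#' @return A [scored_units()] of kind `"interval"`.
#' @export
interval_units <- function(attentions, masks, fs, interval_len_s = 5) {
  if (interval_len_s <= 0) stop("interval_len_s must be > 0")
  p <- align_pairs(attentions, masks)
  scores <- numeric(0); labels <- integer(0)
  for (i in seq_along(p$attentions)) {
    n <- length(p$masks[[i]])
    if (round(interval_len_s * fs) >= n)
      warning("interval_len_s exceeds the record duration; ",
              "using one whole-record interval")
    gi <- interval_index(n, fs, interval_len_s)
    scores <- c(scores, as.numeric(tapply(p$attentions[[i]], gi, max)))
    labels <- c(labels, as.integer(tapply(p$masks[[i]], gi, max)))
  }
  scored_units(scores, labels, "interval")
}

#' Annotation Classification AUROC
#'
#' How well the model's attention, thresholded, predicts whether a unit of
#' the signal is expert-annotated. Units are pooled across all records into
#' a single ROC. The three variants differ in what a unit is: a single
#' sample (`"pixel"`), a maximal annotation-delimited run (`"sectional"`),
#' or a fixed-duration tile (`"interval"`).
#'
#' @inheritParams pixel_units
#' @param variant `"pixel"`, `"sectional"`, or `"interval"`.
#' @param fs Sampling rate (required for the interval variant).
#' @param interval_len_s Tile length in seconds for the interval variant.
#' @return AUROC in `[0, 1]`.
#' @export
annotation_classification <- function(attentions, masks,
                                      variant = c("pixel", "sectional",
                                                  "interval"),
                                      fs = NULL, interval_len_s = 5) {
  variant <- match.arg(variant)
  units <- switch(variant,
    pixel = pixel_units(attentions, masks),
    sectional = sectional_units(attentions, masks),
    interval = {
      if (is.null(fs)) stop("fs is required for the interval variant")
      interval_units(attentions, masks, fs, interval_len_s)
    })
  auroc(units)
}

#' All four explainability metrics for one model's attention maps
#'
#' Computes Congruence and the three Annotation Classification variants for
#' the annotated records of a dataset, given that model's attention maps.
#' Also reports the mean section length per class, since the sectional
#' variant scores sections by their maximum attention and is therefore
#' sensitive to the typical length difference between annotated and
#' unannotated sections.
#'
#' @param dataset A [ppg_dataset()] with annotated records.
#' @param attentions Named list of attention maps covering the annotated
#'   records (e.g. from [attention_maps()] or [synthetic_attention()]).
#' @param interval_len_s Tile length for the interval variant.
#' @return List with `congruence`, `pixel`, `sectional`, `interval`, and
#'   `section_length` (mean lengths per class, in samples).
#' @export
explainability_metrics <- function(dataset, attentions, interval_len_s = 5) {
  rec <- annotated_records(dataset)
  if (!length(rec)) stop("dataset has no annotated records")
  masks <- dataset$mask[rec]
  excluded <- setdiff(dataset$record_id, dataset$record_id[rec])
  if (length(excluded))
    message(length(excluded), " unannotated record(s) excluded from ",
            "explainability metrics")
  attentions <- attentions[names(masks)]
  if (anyNA(names(attentions)) || any(vapply(attentions, is.null, logical(1))))
    stop("attentions must cover every annotated record")
  sec_len <- do.call(rbind, lapply(masks, function(m) {
    s <- mask_to_sections(m)
    c(annotated = mean((s$end - s$start)[s$value == 1]),
      unannotated = mean((s$end - s$start)[s$value == 0]))
  }))
  list(congruence = congruence_dataset(attentions, masks),
       pixel = annotation_classification(attentions, masks, "pixel"),
       sectional = annotation_classification(attentions, masks, "sectional"),
       interval = annotation_classification(attentions, masks, "interval",
                                            fs = dataset$fs,
                                            interval_len_s = interval_len_s),
       section_length = colMeans(sec_len, na.rm = TRUE))
}
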