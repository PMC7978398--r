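#' Construct a PPG segment
#'
#' A segment is a fixed-length real-valued sample vector with its sampling
#' rate and an optional quality label. The default geometry is a 30-second
#' segment sampled at 240 Hz with an inclusive final endpoint, giving
#' `240 * 30 + 1 = 7201` samples.
#'
#' @param samples Numeric vector of at least 2 finite samples.
#' @param fs Sampling rate in Hz.
#' @param record_id Character identifier for the segment.
#' @param label Quality label: one of `"UNLABELED"`, `"ARTIFACT_FREE"`,
#'   `"ARTIFACTUAL"`.
#' @return An object of class `ppg_segment`: a list with elements
#'   `record_id`, `samples`, `fs`, `duration_s` and `label`.
#' @examples
#' seg <- ppg_segment(sin(seq(0, 2 * pi, length.out = 241)), fs = 240)
#' seg$duration_s
#' @export
ppg_segment <- function(samples, fs = 240, record_id = "segment",
                        label = c("UNLABELED", "ARTIFACT_FREE", "ARTIFACTUAL")) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a segment needs at least 2 samples")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  structure(
    list(record_id = as.character(record_id), samples = samples, fs = fs,
         duration_s = (length(samples) - 1L) / fs, label = label),
    class = "ppg_segment"
  )
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("<ppg_segment '%s': %d samples @ %g Hz (%.2f s), label %s>\n",
              x$record_id, length(x$samples), x$fs, x$duration_s, x$label))
  invisible(x)
}

#' Construct a set of expert annotation intervals
#'
#' Annotations mark the onset and offset, in seconds, of artifactual stretches
#' within one segment. Intervals are half-open `[onset, offset)`, must be
#' sorted, non-overlapping, and contained in `[0, duration_s]`.
#'
#' @param onset_s,offset_s Numeric vectors of equal length; `onset_s < offset_s`.
#' @param duration_s Segment duration in seconds (upper bound for offsets).
#' @param record_id Identifier of the annotated segment.
#' @return An object of class `annotation_intervals`: a data.frame with columns
#'   `onset_s` and `offset_s` plus attributes `record_id` and `duration_s`.
#' @examples
#' annotation_intervals(c(5, 20), c(10, 22), duration_s = 30)
#' @export
annotation_intervals <- function(onset_s = numeric(), offset_s = numeric(),
                                 duration_s = 30, record_id = "segment") {
  if (length(onset_s) != length(offset_s)) stop("onset/offset lengths differ")
  onset_s <- as.numeric(onset_s); offset_s <- as.numeric(offset_s)
  if (length(onset_s)) {
    o <- order(onset_s)
    onset_s <- onset_s[o]; offset_s <- offset_s[o]
    if (any(onset_s < 0) || any(offset_s > duration_s + 1e-9))
      stop("interval outside [0, duration]")
    if (any(onset_s >= offset_s)) stop("each interval needs onset < offset")
    if (length(onset_s) > 1L && any(onset_s[-1L] < offset_s[-length(offset_s)]))
      stop("overlapping annotation intervals")
  }
  structure(
    data.frame(onset_s = onset_s, offset_s = offset_s),
    record_id = as.character(record_id), duration_s = duration_s,
    class = c("annotation_intervals", "data.frame")
  )
}

#' Rasterize annotation intervals to a binary per-sample mask
#'
#' Sample `j` (0-based) is annotated iff `floor(onset * fs) <= j <
#' floor(offset * fs)` for some interval: intervals are half-open on the
#' sample grid, so abutting intervals never double-count a sample.
#'
#' @param intervals An [annotation_intervals()] object (or a data.frame with
#'   `onset_s`/`offset_s` columns).
#' @param fs Sampling rate in Hz.
#' @param n Number of samples in the mask.
#' @return Integer vector of length `n` with values 0/1.
#' @examples
#' m <- intervals_to_mask(annotation_intervals(5, 10), fs = 240, n = 7201)
#' range(which(m == 1)) - 1  # 0-based: 1200 .. 2399
#' @export
intervals_to_mask <- function(intervals, fs, n) {
  duration <- (n - 1L) / fs
  if (nrow(intervals) && any(intervals$offset_s > duration + 1 / fs + 1e-9))
    stop("interval extends beyond the sampled duration")
  mask <- integer(n)
  for (r in seq_len(nrow(intervals))) {
    a <- floor(intervals$onset_s[r] * fs)
    b <- floor(intervals$offset_s[r] * fs)
    b <- min(b, n)
    if (b > a) {
      if (any(mask[(a + 1L):b] == 1L)) stop("overlapping annotation intervals")
      mask[(a + 1L):b] <- 1L
    }
  }
  mask
}

#' Decompose a binary mask into maximal constant-value sections
#'
#' Sections are the maximal runs of constant annotation value; they tile the
#' whole segment and alternate between annotated and unannotated. These are
#' the units of Sectional Annotation Classification.
#'
#' @param mask Binary (0/1) vector.
#' @return A data.frame with 0-based half-open columns `start`, `end` and the
#'   run `value` (0 or 1); `end` of the last run equals `length(mask)`.
#' @examples
#' mask_to_sections(c(0, 0, 1, 1, 0))
#' @export
mask_to_sections <- function(mask) {
  stopifnot(length(mask) >= 1L)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  r <- rle(as.integer(mask))
  end <- cumsum(r$lengths)
  data.frame(start = c(0L, end[-length(end)]), end = end, value = r$values)
}

#' Expand a section table back to a binary mask
#'
#' Inverse of [mask_to_sections()]; mainly used to verify round-trips.
#'
#' @param sections A data.frame with `start`, `end`, `value` columns.
#' @return Integer 0/1 vector of length `max(sections$end)`.
#' @export
sections_to_mask <- function(sections) {
  rep(as.integer(sections$value), sections$end - sections$start)
}

# internal: validate an attention map against a mask length
check_attention <- function(attention, n = NULL) {
  if (!is.numeric(attention)) stop("attention must be numeric")
  if (any(!is.finite(attention))) stop("attention must be finite")
  if (any(attention < 0)) stop("attention must be nonnegative (apply to_attention first)")
  if (!is.null(n) && length(attention) != n)
    stop("attention length does not match mask length")
  invisible(attention)
}
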