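# All generators funnel randomness through one seeded RNG per call and
# restore the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a clean PPG segment
#'
#' Generates a quasi-periodic pulse train: each beat is a systolic Gaussian
#' bump followed by a smaller, delayed dicrotic bump, with optional beat-period
#' and beat-amplitude jitter plus low-amplitude baseline wander. With
#' `jitter = 0` the waveform is exactly periodic at the requested heart rate
#' (up to the slow wander term). The morphology is a plausibility device, not
#' a hemodynamic model; the downstream metrics are waveform-agnostic.
#'
#' @param duration_s Segment duration in seconds (default 30).
#' @param fs Sampling rate in Hz (default 240, giving 7201 samples per 30 s
#'   with the inclusive endpoint).
#' @param heart_rate_bpm Heart rate in beats per minute, in `[30, 220]`.
#' @param jitter Relative beat-to-beat variability (0 disables it).
#' @param seed Integer seed; identical seeds give identical segments.
#' @param record_id Identifier for the returned segment.
#' @return A [ppg_segment()] of length `round(fs * duration_s) + 1`.
#' @examples
#' seg <- simulate_clean_ppg(duration_s = 5, fs = 60, seed = 1)
#' length(seg$samples)
#' @export
simulate_clean_ppg <- function(duration_s = 30, fs = 240, heart_rate_bpm = 70,
                               jitter = 0.05, seed = 1,
                               record_id = "segment") {
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220)
    stop("heart_rate_bpm outside the physiologic range [30, 220]")
  n <- round(fs * duration_s) + 1L
  t <- seq(0, duration_s, length.out = n)
  with_seed(seed, {
    base_period <- 60 / heart_rate_bpm
    # beat onsets cover [-1, duration + 1] so edge beats are partial, not absent
    onsets <- -base_period
    repeat {
      period <- base_period * (1 + jitter * stats::runif(1, -1, 1))
      nxt <- onsets[length(onsets)] + period
      if (nxt > duration_s + base_period) break
      onsets <- c(onsets, nxt)
    }
    amps <- 1 + 0.5 * jitter * stats::runif(length(onsets), -1, 1)
    x <- numeric(n)
    for (k in seq_along(onsets)) {
      dt <- t - onsets[k]
      x <- x + amps[k] * (
        exp(-((dt - 0.25 * base_period) / (0.08 * base_period))^2 / 2) +
        0.35 * exp(-((dt - 0.55 * base_period) / (0.12 * base_period))^2 / 2))
    }
    # respiratory-band baseline wander, small relative to the pulse amplitude
    wander_f <- stats::runif(1, 0.15, 0.35)
    wander_ph <- stats::runif(1, 0, 2 * pi)
    x <- x + 0.03 * sin(2 * pi * wander_f * t + wander_ph)
    ppg_segment(x, fs = fs, record_id = record_id, label = "ARTIFACT_FREE")
  })
}

#' Describe artifact episodes to inject
#'
#' @param kind Artifact morphology: additive Gaussian noise, a flatlined
#'   sensor, a burst of spikes, or amplitude saturation.
#' @param duration_range_s Min/max episode duration in seconds.
#' @param amplitude Relative corruption scale (multiples of the clean
#'   signal's standard deviation, where applicable).
#' @param count Number of non-overlapping episodes to place.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("GAUSSIAN_NOISE", "FLATLINE", "SPIKE_BURST",
                                   "SATURATION"),
                          duration_range_s = c(2, 8), amplitude = 3,
                          count = 2) {
  kind <- match.arg(kind)
  if (length(duration_range_s) != 2L || duration_range_s[1] <= 0 ||
      duration_range_s[1] > duration_range_s[2])
    stop("duration_range_s must satisfy 0 < min <= max")
  if (count < 0) stop("count must be >= 0")
  structure(list(kind = kind, duration_range_s = duration_range_s,
                 amplitude = amplitude, count = count),
            class = "artifact_spec")
}

#' Inject annotated artifact episodes into a clean segment
#'
#' Places `spec$count` non-overlapping episodes uniformly at random, corrupts
#' the samples covered by each episode under the half-open `[onset, offset)`
#' rule, and returns the corrupted segment together with the ground-truth
#' annotation intervals. Outside the returned intervals the signal is
#' bit-identical to the input.
#'
#' @param segment A clean [ppg_segment()].
#' @param spec An [artifact_spec()].
#' @param seed Integer seed for placement and corruption noise.
#' @return A list with elements `segment` (corrupted, labeled `ARTIFACTUAL`
#'   when `count > 0`) and `intervals` ([annotation_intervals()]).
#' @export
inject_artifacts <- function(segment, spec, seed = 1) {
  stopifnot(inherits(segment, "ppg_segment"), inherits(spec, "artifact_spec"))
  if (spec$count == 0)
    return(list(segment = segment,
                intervals = annotation_intervals(duration_s = segment$duration_s,
                                                 record_id = segment$record_id)))
  if (spec$duration_range_s[2] > segment$duration_s)
    stop("artifact duration exceeds the segment duration")
  dur_s <- segment$duration_s
  fs <- segment$fs
  with_seed(seed, {
    gap <- 0.25  # seconds kept between episodes so intervals stay disjoint
    onsets <- numeric(0); offsets <- numeric(0)
    for (i in seq_len(spec$count)) {
      len <- stats::runif(1, spec$duration_range_s[1], spec$duration_range_s[2])
      placed <- FALSE
      for (try in 1:500) {
        a <- stats::runif(1, 0, dur_s - len)
        b <- a + len
        if (!any(a < offsets + gap & b > onsets - gap)) {
          onsets <- c(onsets, a); offsets <- c(offsets, b)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("cannot place ", spec$count, " non-overlapping artifact episodes")
    }
    o <- order(onsets)
    iv <- annotation_intervals(onsets[o], offsets[o], duration_s = dur_s,
                               record_id = segment$record_id)
    x <- segment$samples
    s <- stats::sd(x)
    mask <- intervals_to_mask(iv, fs = fs, n = length(x))
    for (r in seq_len(nrow(iv))) {
      idx <- which(intervals_to_mask(iv[r, , drop = FALSE], fs, length(x)) == 1L)
      x[idx] <- switch(spec$kind,
        GAUSSIAN_NOISE = x[idx] + stats::rnorm(length(idx), 0, spec$amplitude * s),
        FLATLINE = x[idx[1]],
        SPIKE_BURST = {
          spikes <- stats::runif(length(idx)) < 0.15
          x[idx] + spikes * sample(c(-1, 1), length(idx), TRUE) *
            stats::runif(length(idx), 0.5, 1) * spec$amplitude * s
        },
        SATURATION = pmin(pmax(x[idx], stats::quantile(x, 0.2)),
                          stats::quantile(x, 0.55)))
    }
    out <- segment
    out$samples <- x
    out$label <- "ARTIFACTUAL"
    list(segment = out, intervals = iv)
  })
}

#' Generate an attention map with a known congruence
#'
#' Distributes one unit of attention mass so that a fraction
#' `target_congruence` falls on annotated samples. With the `"uniform"`
#' profile the split is exact, so the measured congruence equals the request
#' to machine precision; `"random_uniform"` randomizes per-sample weights so
#' the congruence fluctuates around the target; `"peaked"` concentrates mass
#' in Gaussian bumps near run centers, with the region totals rescaled to the
#' exact split.
#'
#' @param mask Binary annotation mask.
#' @param target_congruence Desired fraction of attention mass inside the
#'   annotation, in `[0, 1]`.
#' @param profile Attention shape: `"uniform"`, `"random_uniform"`, `"peaked"`.
#' @param seed Integer seed (used by the stochastic profiles).
#' @return Nonnegative numeric vector summing to 1, with attribute
#'   `method = "synthetic"`.
#' @export
synthetic_attention <- function(mask, target_congruence,
                                profile = c("uniform", "random_uniform",
                                            "peaked"),
                                seed = 1) {
  profile <- match.arg(profile)
  p <- target_congruence
  if (p < 0 || p > 1) stop("target_congruence must lie in [0, 1]")
  n <- length(mask)
  inside <- mask == 1
  n1 <- sum(inside); n0 <- n - n1
  if (p > 0 && n1 == 0) stop("no annotated samples to place attention mass on")
  if (p < 1 && n0 == 0) stop("no unannotated samples to place attention mass on")
  att <- numeric(n)
  if (profile == "uniform") {
    if (n1 > 0) att[inside] <- p / n1
    if (n0 > 0) att[!inside] <- (1 - p) / n0
  } else if (profile == "random_uniform") {
    att <- with_seed(seed, {
      w <- stats::runif(n)
      if (p == 0) w[inside] <- 0
      else if (p == 1) w[!inside] <- 0
      else w[inside] <- w[inside] * (p / (1 - p)) * (n0 / n1)
      w / sum(w)
    })
  } else {  # peaked: bumps near run centers, region masses rescaled exactly
    att <- with_seed(seed, {
      sec <- mask_to_sections(mask)
      w <- numeric(n)
      j <- seq_len(n) - 1L
      for (r in seq_len(nrow(sec))) {
        len <- sec$end[r] - sec$start[r]
        ctr <- sec$start[r] + len * stats::runif(1, 0.35, 0.65)
        w <- w + exp(-((j - ctr) / pmax(len / 6, 1))^2 / 2)
      }
      # force region totals to the exact requested split
      s1 <- sum(w[inside]); s0 <- sum(w[!inside])
      if (n1 > 0) w[inside] <- if (s1 > 0) w[inside] * p / s1 else p / n1
      if (n0 > 0) w[!inside] <- if (s0 > 0) w[!inside] * (1 - p) / s0 else (1 - p) / n0
      w
    })
  }
  structure(att, method = "synthetic")
}

#' Generate a labeled synthetic dataset
#'
#' Simulates `n_clean` artifact-free and `n_artifactual` artifact-bearing
#' segments sharing one sampling geometry, with ground-truth annotation
#' intervals (and masks) on every artifactual record. Deterministic given
#' `seed`.
#'
#' @param n_clean,n_artifactual Record counts (>= 0).
#' @param spec An [artifact_spec()] applied to every artifactual record.
#' @param duration_s,fs Sampling geometry (defaults 30 s at 240 Hz).
#' @param heart_rate_range Range the per-record heart rate is drawn from, bpm.
#' @param jitter Beat-to-beat variability passed to [simulate_clean_ppg()].
#' @param seed Master seed; per-record seeds are derived from it.
#' @return A [ppg_dataset()].
#' @examples
#' ds <- make_labeled_dataset(3, 3, duration_s = 5, fs = 60, seed = 7)
#' table(ds$label)
#' @export
make_labeled_dataset <- function(n_clean, n_artifactual,
                                 spec = artifact_spec(),
                                 duration_s = 30, fs = 240,
                                 heart_rate_range = c(55, 95),
                                 jitter = 0.05, seed = 1) {
  stopifnot(n_clean >= 0, n_artifactual >= 0, n_clean + n_artifactual > 0)
  m <- n_clean + n_artifactual
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * m))
  hrs <- with_seed(seed + 1L,
                   stats::runif(m, heart_rate_range[1], heart_rate_range[2]))
  n <- round(fs * duration_s) + 1L
  x <- matrix(0, m, n)
  ids <- c(sprintf("clean%03d", seq_len(n_clean)),
           sprintf("art%03d", seq_len(n_artifactual)))
  label <- rep(c("ARTIFACT_FREE", "ARTIFACTUAL"), c(n_clean, n_artifactual))
  intervals <- list()
  for (i in seq_len(m)) {
    seg <- simulate_clean_ppg(duration_s, fs, hrs[i], jitter,
                              seed = seeds[i], record_id = ids[i])
    if (label[i] == "ARTIFACTUAL") {
      inj <- inject_artifacts(seg, spec, seed = seeds[m + i])
      seg <- inj$segment
      intervals[[ids[i]]] <- inj$intervals
    }
    x[i, ] <- seg$samples
  }
  ppg_dataset(x, fs = fs, record_id = ids, label = label,
              intervals = intervals)
}
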