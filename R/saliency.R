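new_attribution <- function(values, method, baseline_descriptor = "none") {
  if (!all(is.finite(values))) stop("attribution contains non-finite values")
  structure(list(values = values, method = method,
                 baseline_descriptor = baseline_descriptor),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  v <- x$values
  cat(sprintf("<attribution: %s, %s, range [%.3g, %.3g], sum %.4g>\n",
              x$method,
              if (is.matrix(v)) paste(dim(v), collapse = "x") else
                sprintf("length %d", length(v)),
              min(v), max(v), sum(v)))
  cat(sprintf("  baseline: %s\n", x$baseline_descriptor))
  invisible(x)
}

#' Integrated-gradients attribution
#'
#' Attribution of the scalar model output to each input element:
#' `attr_j = (x_j - baseline_j) * mean_k dF/dx_j` with the gradient evaluated
#' at `steps` points along the straight path from the baseline to `x`
#' (midpoint rule, which is exact for linear models and converges for
#' ReLU-family networks). The attributions satisfy completeness:
#' `sum_j attr_j ~ F(x) - F(baseline)`, with error shrinking as `steps`
#' grows.
#'
#' The path integral is evaluated adaptively (when `refine = TRUE`): after
#' the `steps` midpoint evaluations, every gap whose endpoint gradients
#' disagree is bisected recursively. For piecewise-linear networks (ReLU
#' activations, linear head) the path gradient is piecewise constant, so
#' bisection isolates the activation-pattern changes and the completeness
#' error drops to the bisection resolution; for smooth integrands (e.g. a
#' sigmoid head) recursion stops as soon as the midpoint gradient matches
#' the linear interpolation of the endpoints, where a Simpson panel is
#' already accurate. A global budget of `50 * steps` extra gradient
#' evaluations bounds the cost.
#'
#' @param model A model supporting [model_output()] / [model_input_gradient()].
#' @param x Numeric input vector.
#' @param baseline Reference input of the same length; default all zeros.
#' @param steps Number of path evaluation points (>= 1; default 64).
#' @param refine Adaptively refine gaps where the path gradient varies?
#' @return An [`attribution`][guided_backprop] object with signed `values`.
#' @examples
#' lin <- mlp_net(w2 = c(2, -1), b2 = 1)
#' integrated_gradients(lin, c(3, 4))$values  # 2*3, -1*4 exactly
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 64,
                                 refine = TRUE) {
  if (steps < 1) stop("steps must be >= 1")
  x <- as.numeric(x)
  if (is.null(baseline)) baseline <- numeric(length(x))
  if (length(baseline) != length(x)) stop("baseline must match the input length")
  diff <- x - baseline
  grad_at <- function(alpha) model_input_gradient(model, baseline + alpha * diff)
  mids <- (seq_len(steps) - 0.5) / steps
  grads <- matrix(vapply(mids, grad_at, numeric(length(x))),
                  nrow = length(x))
  if (!refine || steps < 2) {
    gbar <- rowMeans(grads)
  } else {
    nodes_t <- c(0, mids, 1)
    nodes_g <- cbind(grad_at(0), grads, grad_at(1))
    gscale <- max(abs(nodes_g), 1e-12)
    budget <- new.env()
    budget$left <- 8L * steps
    gap_integral <- function(a, b, ga, gb, depth) {
      jump <- max(abs(ga - gb))
      if (jump <= 1e-9 * gscale) return((b - a) * (ga + gb) / 2)
      if (depth >= 24L || budget$left <= 0L)
        return((b - a) * (ga + gb) / 2)
      budget$left <- budget$left - 1L
      gm <- grad_at((a + b) / 2)
      # gradient varying about linearly across the gap: a Simpson panel is
      # accurate; only jump-like variation (midpoint hugging one side, the
      # signature of a ReLU pattern change) is worth recursing into
      if (max(abs(gm - (ga + gb) / 2)) <= 0.25 * jump)
        return((b - a) * (ga + 4 * gm + gb) / 6)
      gap_integral(a, (a + b) / 2, ga, gm, depth + 1L) +
        gap_integral((a + b) / 2, b, gm, gb, depth + 1L)
    }
    acc <- numeric(length(x))
    for (k in seq_len(length(nodes_t) - 1L))
      acc <- acc + gap_integral(nodes_t[k], nodes_t[k + 1L],
                                nodes_g[, k], nodes_g[, k + 1L], 0L)
    gbar <- acc
  }
  new_attribution(diff * gbar, "integrated_gradients",
                  sprintf("straight path from a fixed baseline, %d steps", steps))
}

#' Guided-backpropagation attribution
#'
#' Backpropagates the pre-sigmoid score through the network with the guided
#' ReLU rule: at each ReLU, entries whose forward pre-activation was
#' negative and entries whose incoming backward signal is negative are both
#' zeroed. The final map is clamped at zero, so guided attributions are
#' always nonnegative and pass unchanged through [to_attention()].
#'
#' @inheritParams integrated_gradients
#' @return An `attribution` with nonnegative `values`.
#' @export
guided_backprop <- function(model, x) {
  act <- model$activation
  if (!is.null(act) && !act %in% c("relu", "identity"))
    stop("guided backpropagation requires ReLU-family nonlinearities")
  g <- model_input_gradient(model, as.numeric(x), guided = TRUE)
  new_attribution(pmax(g, 0), "guided", "none (gradient-based)")
}

#' Difference-from-reference attribution (expected gradients)
#'
#' Attributes the output difference between `x` and a background of
#' reference inputs, in the style of DeepSHAP: integrated gradients are
#' computed against every reference and averaged, so the attributions
#' satisfy summation-to-delta,
#' `sum_j attr_j ~ F(x) - mean_r F(ref_r)`.
#' The default background is 16 all-zero signals with small Gaussian jitter,
#' drawn under `seed`.
#'
#' @inheritParams integrated_gradients
#' @param background List of reference inputs (non-empty), or `NULL` for the
#'   default jittered-zero background.
#' @param n_background Number of default references when `background` is
#'   `NULL`.
#' @param steps Path points per reference.
#' @param seed Seed for the default background jitter.
#' @param refine Adaptive path refinement, as in [integrated_gradients()].
#' @return An `attribution` with signed `values`.
#' @export
reference_attribution <- function(model, x, background = NULL,
                                  n_background = 16, steps = 16, seed = 1,
                                  refine = TRUE) {
  x <- as.numeric(x)
  if (is.null(background)) {
    background <- with_seed(seed, lapply(seq_len(n_background), function(i)
      stats::rnorm(length(x), 0, 0.01)))
    desc <- sprintf("%d jittered-zero references (sd 0.01, seed %d), %d steps each",
                    n_background, seed, steps)
  } else {
    if (length(background) == 0) stop("background must be non-empty")
    desc <- sprintf("%d user references, %d steps each", length(background), steps)
  }
  acc <- numeric(length(x))
  for (ref in background) {
    acc <- acc + integrated_gradients(model, x, baseline = ref,
                                      steps = steps, refine = refine)$values
  }
  new_attribution(acc / length(background), "reference", desc)
}

#' Convert an attribution to a nonnegative attention map
#'
#' Takes the elementwise absolute value of a 1D attribution, the model's
#' attention. Guided attributions are already nonnegative and pass through
#' unchanged; the operation is idempotent. For a 2D attribution apply
#' [reduce_columns()] first.
#'
#' @param attr An `attribution` object or a numeric vector.
#' @return Nonnegative numeric vector with attribute `method`.
#' @export
to_attention <- function(attr) {
  if (inherits(attr, "attribution")) {
    v <- attr$values
    if (is.matrix(v)) stop("2D attribution: apply reduce_columns() first")
    structure(abs(v), method = attr$method)
  } else {
    structure(abs(as.numeric(attr)), method = attr(attr, "method"))
  }
}

#' Reduce a 2D attribution to a 1D attention profile
#'
#' For image-input models the attribution is a matrix over an H x W trace
#' image; the per-column maximum of its absolute values gives a length-W
#' attention profile, which is mapped to the `n` signal samples by
#' nearest-neighbor index scaling when `W != n`.
#'
#' @param attr2d Numeric matrix (or 2D `attribution`).
#' @param n Target length in samples; default the number of columns.
#' @return Nonnegative numeric vector of length `n`.
#' @examples
#' reduce_columns(rbind(c(1, 0, 2), c(0, 3, 1)))  # 1 3 2
#' @export
reduce_columns <- function(attr2d, n = NULL) {
  m <- if (inherits(attr2d, "attribution")) attr2d$values else attr2d
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("attr2d must be a non-empty matrix")
  prof <- apply(abs(m), 2, max)
  w <- length(prof)
  if (is.null(n) || n == w) return(prof)
  idx <- if (n == 1L) 1L else round((seq_len(n) - 1) * (w - 1) / (n - 1)) + 1L
  prof[idx]
}

#' Compute attention maps for the records of a dataset
#'
#' Applies one saliency method to each requested record and returns the
#' resulting nonnegative attention maps (absolute values applied). By
#' default only the annotated (artifactual) records are explained, since
#' the explainability metrics are defined on those.
#'
#' @param model A model supporting the saliency interface.
#' @param dataset A [ppg_dataset()].
#' @param method `"integrated_gradients"`, `"guided"`, or `"reference"`.
#' @param records Row indices to explain; default the annotated records.
#' @param ig_steps Path steps for integrated gradients.
#' @param ref_background,ref_steps Background size and per-reference steps
#'   for the difference-from-reference method.
#' @param seed Seed for the reference background.
#' @param refine Adaptive path refinement; off by default here because an
#'   attention map needs the relative score profile, not completeness-grade
#'   quadrature, and the plain midpoint rule is markedly cheaper.
#' @return Named list of attention vectors with attribute `method`.
#' @export
attention_maps <- function(model, dataset,
                           method = c("integrated_gradients", "guided",
                                      "reference"),
                           records = NULL, ig_steps = 32,
                           ref_background = 8, ref_steps = 8, seed = 1,
                           refine = FALSE) {
  method <- match.arg(method)
  if (is.null(records)) records <- annotated_records(dataset)
  maps <- lapply(records, function(i) {
    x <- dataset$x[i, ]
    attr <- switch(method,
      integrated_gradients = integrated_gradients(model, x, steps = ig_steps,
                                                  refine = refine),
      guided = guided_backprop(model, x),
      reference = reference_attribution(model, x, n_background = ref_background,
                                        steps = ref_steps, seed = seed,
                                        refine = refine))
    to_attention(attr)
  })
  names(maps) <- dataset$record_id[records]
  attr(maps, "method") <- method
  maps
}
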