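# Minimal differentiable-network engine for the 1D residual CNN fixture.
# The backward pass is written out explicitly because the attribution methods
# need (a) gradients of the scalar output w.r.t. the input and (b) a modified
# ReLU backward rule for guided backpropagation; both are easier to guarantee
# with a hand-rolled pass than through an opaque autodiff layer.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# non-overlapping average pooling along time; a final partial window is kept
pool_groups <- function(n, pool) {
  g <- (seq_len(n) - 1L) %/% pool + 1L
  list(g = g, sizes = tabulate(g))
}

avg_pool <- function(x, pg) rowsum(x, pg$g, reorder = TRUE) / pg$sizes

avg_unpool <- function(dy, pg) dy[pg$g, , drop = FALSE] / pg$sizes[pg$g]

#' Build a compact 1D residual convolutional classifier
#'
#' A reduced residual network for binary signal-quality classification: one
#' stem convolution, average pooling, `depth` residual blocks (two
#' convolutions each with a skip connection), global average pooling, and a
#' dense sigmoid head. Convolutions use "same" zero padding and
#' Glorot-uniform initialization. The scalar output is the probability that
#' the segment is artifact-free (the positive class).
#'
#' @param n Input length in samples (default 7201, a 30-s segment at 240 Hz).
#' @param depth Number of residual blocks (>= 1).
#' @param channels Convolution channels per layer.
#' @param kernel_size Convolution kernel length in taps (default 80).
#' @param pool Average-pooling factor applied after the stem convolution.
#' @param seed Integer seed; identical seeds give identical initial weights.
#' @return An object of class `cnn1d`.
#' @examples
#' m <- build_cnn1d(n = 601, depth = 1, channels = 2, kernel_size = 9, seed = 1)
#' predict(m, matrix(rnorm(601), 1))
#' @export
build_cnn1d <- function(n, depth = 2, channels = 8, kernel_size = 80,
                        pool = 5, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (kernel_size > n) stop("kernel longer than the input")
  C <- channels; k <- kernel_size
  params <- with_seed(seed, {
    p <- list(W0 = glorot_uniform(k * 1, k * C, c(k, 1, C)), b0 = numeric(C))
    p$blocks <- lapply(seq_len(depth), function(i) {
      list(Wa = glorot_uniform(k * C, k * C, c(k, C, C)), ba = numeric(C),
           Wb = glorot_uniform(k * C, k * C, c(k, C, C)), bb = numeric(C))
    })
    p$w_fc <- as.numeric(glorot_uniform(C, 1, c(C, 1)))
    p$b_fc <- 0
    p
  })
  structure(list(params = params,
                 arch = list(n = n, depth = depth, channels = C,
                             kernel_size = k, pool = pool,
                             pad = (k - 1L) %/% 2L, seed = seed),
                 history = NULL),
            class = "cnn1d")
}

# forward pass; with cache = TRUE returns all pre-activations needed by the
# backward passes
cnn_forward <- function(model, x, cache = FALSE) {
  a <- model$arch; p <- model$params
  if (length(x) != a$n) stop("input length does not match the model")
  x1 <- matrix(as.numeric(x), ncol = 1)
  z0 <- conv1d_fwd(x1, p$W0, p$b0, a$pad)
  h0 <- relu(z0)
  pg <- pool_groups(a$n, a$pool)
  h <- avg_pool(h0, pg)
  zs_list <- za_list <- a_list <- in_list <- vector("list", a$depth)
  for (i in seq_len(a$depth)) {
    bl <- p$blocks[[i]]
    in_list[[i]] <- h
    za <- conv1d_fwd(h, bl$Wa, bl$ba, a$pad)
    act <- relu(za)
    zb <- conv1d_fwd(act, bl$Wb, bl$bb, a$pad)
    zs <- h + zb
    h <- relu(zs)
    if (cache) { za_list[[i]] <- za; a_list[[i]] <- act; zs_list[[i]] <- zs }
  }
  g <- colMeans(h)
  logit <- sum(p$w_fc * g) + p$b_fc
  prob <- sigmoid(logit)
  if (!cache) return(prob)
  list(prob = prob, logit = logit, g = g, h_final = h, x1 = x1, z0 = z0,
       h0 = h0, pg = pg, za = za_list, a = a_list, zs = zs_list,
       inp = in_list)
}

# backward pass to the input. dlogit scales the gradient (1 for the
# pre-sigmoid score, prob * (1 - prob) for the probability). guided = TRUE
# applies the guided-backpropagation ReLU rule: the backward signal is zeroed
# where either the forward pre-activation or the incoming gradient is
# negative.
cnn_backward_input <- function(model, fw, dlogit = 1, guided = FALSE) {
  a <- model$arch; p <- model$params
  m_rows <- nrow(fw$h_final)
  dh <- matrix(rep(p$w_fc * dlogit / m_rows, each = m_rows), nrow = m_rows)
  back_relu <- function(dz, z) {
    m <- dz * (z > 0)
    if (guided) m <- m * (dz > 0)
    m
  }
  for (i in rev(seq_len(a$depth))) {
    bl <- p$blocks[[i]]
    dzs <- back_relu(dh, fw$zs[[i]])
    da <- conv1d_bwd_input(dzs, bl$Wb, m_rows, a$pad)
    dza <- back_relu(da, fw$za[[i]])
    dh <- conv1d_bwd_input(dza, bl$Wa, m_rows, a$pad) + dzs
  }
  dh0 <- avg_unpool(dh, fw$pg)
  dz0 <- back_relu(dh0, fw$z0)
  dx <- conv1d_bwd_input(dz0, p$W0, a$n, a$pad)[, 1]
  dx
}

# backward pass to the parameters, from d loss / d logit
cnn_backward_params <- function(model, fw, dlogit) {
  a <- model$arch; p <- model$params
  m_rows <- nrow(fw$h_final)
  grads <- list(W0 = NULL, b0 = NULL, blocks = vector("list", a$depth),
                w_fc = fw$g * dlogit, b_fc = dlogit)
  dh <- matrix(rep(p$w_fc * dlogit / m_rows, each = m_rows), nrow = m_rows)
  for (i in rev(seq_len(a$depth))) {
    bl <- p$blocks[[i]]
    dzs <- dh * (fw$zs[[i]] > 0)
    da <- conv1d_bwd_input(dzs, bl$Wb, m_rows, a$pad)
    dza <- da * (fw$za[[i]] > 0)
    # field order must mirror the parameter template for flattening
    grads$blocks[[i]] <- list(
      Wa = conv1d_bwd_kernel(fw$inp[[i]], dza, a$kernel_size, a$pad),
      ba = colSums(dza),
      Wb = conv1d_bwd_kernel(fw$a[[i]], dzs, a$kernel_size, a$pad),
      bb = colSums(dzs))
    dh <- conv1d_bwd_input(dza, bl$Wa, m_rows, a$pad) + dzs
  }
  dh0 <- avg_unpool(dh, fw$pg)
  dz0 <- dh0 * (fw$z0 > 0)
  grads$W0 <- conv1d_bwd_kernel(fw$x1, dz0, a$kernel_size, a$pad)
  grads$b0 <- colSums(dz0)
  grads
}

# flatten/unflatten parameter trees for the vectorized Adam update
params_flatten <- function(p) {
  unlist(p, use.names = FALSE)
}

params_unflatten <- function(flat, template) {
  rebuild <- function(tpl, cursor) {
    if (is.list(tpl)) {
      out <- tpl
      for (i in seq_along(tpl)) {
        res <- rebuild(tpl[[i]], cursor)
        out[[i]] <- res$value; cursor <- res$cursor
      }
      return(list(value = out, cursor = cursor))
    }
    len <- length(tpl)
    v <- flat[cursor:(cursor + len - 1L)]
    if (!is.null(dim(tpl))) dim(v) <- dim(tpl)
    list(value = v, cursor = cursor + len)
  }
  rebuild(template, 1L)$value
}

#' @export
print.cnn1d <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<cnn1d: n=%d, %d residual block(s), %d channels, kernel %d, pool %d>\n",
              a$n, a$depth, a$channels, a$kernel_size, a$pool))
  cat(sprintf("  parameters: %d%s\n", length(params_flatten(x$params)),
              if (is.null(x$history)) " (untrained)" else ""))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epoch(s); best val accuracy %.4f (epoch %d)\n",
                nrow(x$history), max(x$history$val_accuracy),
                which.max(x$history$val_accuracy)))
  invisible(x)
}

#' @export
summary.cnn1d <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.cnn1d <- function(object, ...) object$params

#' @export
plot.cnn1d <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history to plot")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training BCE loss", ...)
  graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' Predict artifact-free probabilities from a fitted classifier
#'
#' @param object A `cnn1d` model.
#' @param newdata A [ppg_dataset()] or a numeric matrix with one record per
#'   row.
#' @param type `"response"` for probabilities, `"class"` for hard labels at
#'   threshold 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities that each record is artifact-free,
#'   or a character vector of labels.
#' @export
predict.cnn1d <- function(object, newdata,
                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "ppg_dataset")) newdata$x else as.matrix(newdata)
  p <- vapply(seq_len(nrow(x)), function(i) cnn_forward(object, x[i, ]),
              numeric(1))
  if (type == "class")
    return(ifelse(p >= 0.5, "ARTIFACT_FREE", "ARTIFACTUAL"))
  p
}
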