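# Small, fast fixtures shared across the suite. Geometry is scaled down
# (short duration / low sampling rate) wherever the property under test is
# independent of segment length.

tiny_dataset <- function(n_clean = 3, n_art = 3, duration_s = 10, fs = 40,
                         seed = 1, kind = "GAUSSIAN_NOISE") {
  make_labeled_dataset(n_clean, n_art,
                       spec = artifact_spec(kind, c(1.5, 3), 3, 1),
                       duration_s = duration_s, fs = fs, seed = seed)
}

tiny_cnn <- function(n, seed = 1, depth = 1, channels = 3, kernel_size = 15,
                     pool = 4) {
  build_cnn1d(n = n, depth = depth, channels = channels,
              kernel_size = kernel_size, pool = pool, seed = seed)
}

# random one-hidden-layer ReLU net with a linear scalar output
random_relu_net <- function(d = 8, h = 8, seed = 1) {
  set.seed(seed)
  mlp_net(w2 = rnorm(h), b2 = rnorm(1),
          W1 = matrix(rnorm(h * d), h, d), b1 = rnorm(h))
}

# brute-force Mann-Whitney AUROC: fraction of (positive, negative) pairs
# with score_pos > score_neg, ties counting one half
auroc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# a predict-only stub whose "probabilities" are fixed, for confusion-matrix
# arithmetic tests
stub_model <- function(probs) structure(list(probs = probs),
                                        class = "stub_model")
predict.stub_model <- function(object, newdata, ...) object$probs
registerS3method("predict", "stub_model", predict.stub_model,
                 envir = asNamespace("stats"))
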