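# Reference explainability grid from the published clinical comparison of a
# signal-based (1D) and an image-based (2D) PPG quality classifier: three
# saliency methods x four metrics per model. Used as *input* to the summary
# arithmetic, the way a reader would feed reported values into the package.
published_grid <- function() {
  metrics_table(data.frame(
    model = rep(c("resnet1d", "resnet2d"), each = 3),
    method = rep(c("deepshap", "integrated_gradients", "guided"), 2),
    pixel = c(0.6526, 0.6073, 0.8061, 0.5820, 0.5951, 0.6689),
    sectional = c(0.7477, 0.7136, 0.7607, 0.6010, 0.6420, 0.6477),
    interval = c(0.7934, 0.7665, 0.8864, 0.6601, 0.6887, 0.7709),
    congruence = c(0.4825, 0.4393, 0.6017, 0.3737, 0.3852, 0.3220)))
}
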