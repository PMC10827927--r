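# Fixtures built in code: small recordings, epoch sets and model configs.

make_sine_recording <- function(freqs = c(10), fs = 200, seconds = 10,
                                n_channels = 2, amplitude = 1) {
  tt <- (seq_len(fs * seconds) - 1) / fs
  sig <- matrix(0, n_channels, length(tt))
  for (c in seq_len(n_channels)) {
    for (f in freqs) sig[c, ] <- sig[c, ] + amplitude * sin(2 * pi * f * tt)
  }
  eeg_recording(sig, fs, paste0("CH", seq_len(n_channels)), "s01", "t01")
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 4L, n_samples = 64L, n_classes = 2L, F1 = 2L, T = 8L,
         D = 2L, pool1 = 2L, pool2 = 2L, sep_kernel = 4L, n_heads = 2L,
         n_blocks = 1L, dropout = 0),
    list(...))
  do.call(ertnet_config, args)
}

# A small, easily separable two-class epoch set: class 1 carries a strong
# oscillation on channels 1-2.
tiny_task <- function(n_per_class = 30, fs = 64, seconds = 1,
                      n_channels = 4, seed = 42, n_subjects = 2,
                      freq = 16, amplitude = 3) {
  set.seed(seed)
  n_s <- fs * seconds
  total <- 2 * n_per_class
  ep <- array(stats::rnorm(total * n_channels * n_s, sd = 1),
              c(total, n_channels, n_s))
  labels <- rep(0:1, each = n_per_class)
  tt <- (seq_len(n_s) - 1) / fs
  for (i in which(labels == 1L)) {
    ph <- stats::runif(1, 0, 2 * pi)
    for (c in 1:2) ep[i, c, ] <- ep[i, c, ] + amplitude * sin(2 * pi * freq * tt + ph)
  }
  ord <- sample(total)
  epoch_set(ep[ord, , , drop = FALSE], labels[ord], c("rest", "active"),
            rep_len(sprintf("s%02d", seq_len(n_subjects)), total)[ord],
            fs, paste0("CH", seq_len(n_channels)), seconds)
}

quick_tc <- function(...) {
  utils::modifyList(
    train_config(epochs = 10, batch_size = 16, learning_rate = 1e-2,
                 early_stop_patience = 0, validation_split = 0, seed = 11),
    list(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
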