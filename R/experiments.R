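# Packaged validation experiments on synthetic data.  These wire the
# generator, the classifier and the interpretability procedures into the
# two end-to-end checks the package makes of itself: recovery of a planted
# band/channel code, and the minimum-detectable-frequency (Fmin = Sr/T)
# effect of the temporal kernel length.

#' Synthetic configuration for the band/channel recovery experiment
#'
#' Two classes at the 32-channel, 128 Hz, 4-s geometry: a baseline class
#' with pure 1/f-plus-white background and a target class carrying a beta
#' oscillation (18-22 Hz, centred on 20 Hz) on the temporal-lobe pair
#' T7/T8 at an amplitude about twice the background standard deviation.
#'
#' @param seed Integer seed.
#' @param epochs_per_subject_per_class Epochs per subject and class
#'   (default 100; with 4 subjects this gives 800 epochs).
#' @param amplitude Signature amplitude in microvolts (default 2.5, about
#'   2.2x the background SD of ~1.12).
#' @return A [synth_config()].
#' @export
recovery_synth_config <- function(seed = 1L,
                                  epochs_per_subject_per_class = 100L,
                                  amplitude = 2.5) {
  synth_config(
    montage = "deap32", sampling_rate = 128, epoch_seconds = 4,
    n_subjects = 4, epochs_per_subject_per_class = epochs_per_subject_per_class,
    signatures = list(
      calm = NULL,
      excited = class_signature(c(18, 22), c("T7", "T8"),
                                amplitude = amplitude)),
    noise = list(pink_exponent = 1, pink_sd = 1, white_sd = 0.5,
                 line_50hz_amp = 0, hf_artifact_amp = 0),
    seed = seed)
}

#' Band/channel recovery experiment (one seed)
#'
#' Generates the two-class beta-signature data, trains a small
#' transformer model (F1=4, T=32, D=2, one block) on a stratified 8:2
#' split, and asks whether the trained model recovered the planted code:
#' (a) test accuracy above 85%; (b) at least one temporal kernel dominant
#' in the beta band; (c) the single-kernel ablation that hurts macro AUC
#' most belongs to a beta-band kernel; (d) the top-weight channels of that
#' kernel's spatial maps intersect the planted pair \{T7, T8\}.
#'
#' @param seed Integer seed driving generation, splitting and training.
#' @param epochs_per_subject_per_class Passed to
#'   [recovery_synth_config()].
#' @param train_epochs Training passes (default 10 at learning rate 3e-3).
#' @param top_n Channels counted as "top" per kernel (default 4 of 32).
#' @return A list with the measured quantities and logical flags
#'   `acc_ok`, `beta_ok`, `ablation_ok`, `channels_ok`, `success`.
#' @export
recovery_experiment <- function(seed = 1L,
                                epochs_per_subject_per_class = 100L,
                                train_epochs = 10L, top_n = 4L) {
  gen <- generate_synth(recovery_synth_config(
    seed = derive_seed(seed, 1L),
    epochs_per_subject_per_class = epochs_per_subject_per_class))
  ep <- gen$epochs
  sp <- holdout_split(ep, ratio = 0.8, seed = derive_seed(seed, 2L))
  cfg <- ertnet_config(n_channels = 32, n_samples = 512, n_classes = 2,
                       F1 = 4, T = 32, D = 2, n_heads = 4, n_blocks = 1,
                       dropout = 0)
  model <- build_ertnet(cfg, seed = derive_seed(seed, 3L))
  tc <- train_config(epochs = train_epochs, batch_size = 64,
                     learning_rate = 1e-2, early_stop_patience = 0,
                     validation_split = 0, seed = derive_seed(seed, 4L))
  model <- fit(model, sp$train, tc)$model

  res <- evaluate(model, sp$test)
  rep <- kernel_report(model, sampling_rate = 128, montage = "deap32")
  dom <- rep$summary$dominant_frequency
  beta_kernels <- which(dom >= 13 & dom < 30)

  none <- ablate(model, integer(0), sp$test)
  drops <- vapply(seq_len(cfg$F1), function(k) {
    none$auc_average - ablate(model, k, sp$test)$auc_average
  }, 0)
  crit <- which.max(drops)
  strict <- all(drops[crit] > drops[-crit])

  # group-level ablation: when the model distributes the band code over
  # several kernels, removing the whole band-matched group is the
  # informative probe (singleton drops can tie at zero on a saturated task)
  beta_group_drop <- if (length(beta_kernels) > 0) {
    none$auc_average - ablate(model, beta_kernels, sp$test)$auc_average
  } else NA_real_
  nonbeta <- setdiff(seq_len(cfg$F1), beta_kernels)
  nonbeta_group_drop <- if (length(nonbeta) > 0) {
    none$auc_average - ablate(model, nonbeta, sp$test)$auc_average
  } else NA_real_

  imp <- apply(abs(model$params$Ws[, , crit, drop = FALSE]), 1, max)
  top_channels <- ep$channel_names[order(imp, decreasing = TRUE)][seq_len(top_n)]

  out <- list(seed = seed, accuracy = res$accuracy, auc = res$auc_macro,
              dominant_frequencies = dom, beta_kernels = beta_kernels,
              auc_drops = drops, critical_kernel = crit,
              critical_band = rep$summary$band[crit],
              beta_group_drop = beta_group_drop,
              nonbeta_group_drop = nonbeta_group_drop,
              top_channels = top_channels,
              acc_ok = res$accuracy > 85,
              beta_ok = length(beta_kernels) >= 1,
              ablation_ok = strict && (dom[crit] >= 13 && dom[crit] < 30),
              channels_ok = length(intersect(top_channels,
                                             c("T7", "T8"))) > 0)
  out$success <- out$acc_ok && out$beta_ok && out$ablation_ok &&
    out$channels_ok
  # group-level recovery: the band-matched kernel group is load-bearing
  # and the complement is not
  out$group_ok <- !is.na(beta_group_drop) && beta_group_drop > 0.2 &&
    (is.na(nonbeta_group_drop) || nonbeta_group_drop < 0.1)
  out
}

#' Run the recovery experiment over several seeds
#'
#' @param seeds Integer vector of seeds.
#' @param ... Passed to [recovery_experiment()].
#' @return A list with `runs` (per-seed results), `success_rate`,
#'   `accuracy_mean`.
#' @export
run_recovery <- function(seeds = 1:10, ...) {
  runs <- lapply(seeds, function(s) recovery_experiment(seed = s, ...))
  list(runs = runs,
       success_rate = mean(vapply(runs, `[[`, TRUE, "success")),
       group_success_rate = mean(vapply(runs, `[[`, TRUE, "group_ok")),
       accuracy_mean = mean(vapply(runs, `[[`, 0, "accuracy")),
       flags = data.frame(
         seed = seeds,
         acc_ok = vapply(runs, `[[`, TRUE, "acc_ok"),
         beta_ok = vapply(runs, `[[`, TRUE, "beta_ok"),
         ablation_ok = vapply(runs, `[[`, TRUE, "ablation_ok"),
         channels_ok = vapply(runs, `[[`, TRUE, "channels_ok")))
}

#' Kernel-length (Fmin) sweep experiment
#'
#' Constructs a task that only a frequency-selective *first* layer can
#' solve: two classes with equal-amplitude oscillations on the same
#' channel pair at 28-30 Hz (high beta) and 34-36 Hz (low gamma).  The
#' bands are chosen so that the later stages are structurally blind to
#' the difference: under the first average pool (length 4, pooled rate
#' 32 Hz) both bands alias onto the same ~3 Hz residue, and both sit
#' near the pool's spectral null so that residue is tiny and nearly
#' equal in amplitude for the two classes.  The only stage that sees the
#' bands apart is the full-rate temporal convolution, whose frequency
#' resolution is Sr/T: at 128 Hz a T=32 kernel resolves 4 Hz and
#' separates 29 from 35 Hz cleanly, while a T=4 kernel resolves only
#' 32 Hz -- far coarser than the 6 Hz band separation -- and cannot;
#' the accuracy curve over `values` of T exposes this.
#'
#' @param seed Integer seed.
#' @param values Kernel lengths to sweep (default `c(4, 32)`).
#' @param epochs_per_subject_per_class Default 100 (2 subjects, 2 classes:
#'   400 epochs).
#' @param train_epochs Training passes per fold (default 15).
#' @return The sweep table from [sweep_parameter()] (one row per T).
#' @export
fmin_sweep_experiment <- function(seed = 1L, values = c(4L, 32L),
                                  epochs_per_subject_per_class = 100L,
                                  train_epochs = 15L) {
  cfgs <- synth_config(
    montage = "deap32", sampling_rate = 128, epoch_seconds = 4,
    n_subjects = 2,
    epochs_per_subject_per_class = epochs_per_subject_per_class,
    signatures = list(
      high_beta = class_signature(c(28, 30), c("T7", "T8"), amplitude = 1),
      low_gamma = class_signature(c(34, 36), c("T7", "T8"), amplitude = 1)),
    noise = list(pink_exponent = 1, pink_sd = 1, white_sd = 0.5,
                 line_50hz_amp = 0, hf_artifact_amp = 0),
    seed = derive_seed(seed, 11L))
  ep <- generate_synth(cfgs)$epochs
  tc <- train_config(epochs = train_epochs, batch_size = 64,
                     learning_rate = 1e-2, early_stop_patience = 0,
                     validation_split = 0, seed = derive_seed(seed, 12L))
  sweep_parameter(ep, "T", values, tc = tc, k = 2L,
                  F1 = 4, D = 2, n_heads = 4, n_blocks = 1, dropout = 0.25)
}
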