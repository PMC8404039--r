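# Shared desk-scale study fixtures for the acceptance suite.  One synthetic
# Dataset-1 analogue (clean / misaligned / 20%-noise maps on the full MNI
# grid) is generated lazily, immediately reduced to every representation
# the tests need (1D striatal profiles; 3D volumes decimated by 8 to
# 12 x 14 x 12 at 16 mm), and then discarded: keeping 150 full-resolution
# volumes alive for the whole suite costs over 1 GB and slows every
# numerical test through GC pressure.

.study <- new.env(parent = emptyenv())

study_subsample <- function(d, n_per_class) {
  keep <- unlist(lapply(levels(d$y), function(cl)
    head(which(d$y == cl), n_per_class)))
  list(x = fdopaqc:::slice_samples(d$x, keep), y = droplevels(d$y[keep]))
}

study_build <- function() {
  if (!is.null(.study$built)) return(invisible())
  ds <- synth_dataset(c(good = 50, misaligned = 50, noisy = 50),
                      phantom_spec(), seed = 20210901)
  for (task in c("alignment", "snr")) {
    cls <- c("good", if (task == "alignment") "misaligned" else "noisy")
    .study[[paste0("d1_", task)]] <- stack_dataset(ds, dims = 1,
                                                   classes = cls)
    .study[[paste0("d3_", task)]] <- stack_dataset(ds, dims = 3,
                                                   downsample = 8,
                                                   classes = cls)
  }
  .study$built <- TRUE
  rm(ds)
  invisible(gc())
}

study_1d <- function(task = c("alignment", "snr")) {
  task <- match.arg(task)
  study_build()
  .study[[paste0("d1_", task)]]
}

study_3d <- function(task = c("alignment", "snr"), n_per_class) {
  task <- match.arg(task)
  study_build()
  study_subsample(.study[[paste0("d3_", task)]], n_per_class)
}

# Cross-validated 3D models; the alignment ensemble is reused by the
# out-of-sample test.  The alignment task trains longer: at 16 mm desk
# resolution near-threshold displacements are sub-voxel and need the extra
# updates for margin, while the voxel-level noise signature of the SNR
# task is learnt almost immediately.
study_3d_cv <- function(task = c("alignment", "snr")) {
  task <- match.arg(task)
  key <- paste0("cv3_", task)
  if (is.null(.study[[key]])) {
    d <- study_3d(task, n_per_class = 32)
    .study[[key]] <- cross_validate(
      d$x, d$y, densenet_config(dims = 3),
      train_control(learning_rate = 0.1,
                    max_epochs = if (task == "alignment") 12L else 6L,
                    seed = 101))
  }
  .study[[key]]
}
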