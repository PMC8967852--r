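# Shared fixtures, built lazily once per test run. Everything is generated
# in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 6-subject, 2-channel synthetic dataset used by most module tests
small_config <- function() synthetic_config(n_subjects = 6, channels_per_subject = 2,
                                            seed = 42)

small_dataset <- function() fixture("small_dataset", function() {
  generate_dataset(small_config())
})

small_epochs <- function() fixture("small_epochs", function() {
  bind_epoch_sets(lapply(small_dataset(), epoch_and_label))
})

# one trained FDBB fold on the small dataset (reused by probe tests)
small_fdbb_fold <- function() fixture("small_fdbb_fold", function() {
  es <- small_epochs()
  sp <- loo_split(es, "S01", n_val_subjects = 2, seed = 1)
  m <- assemble_model("fdbb", seed = 2)
  train_fold(m, sp$train, sp$val, sp$test, max_epochs = 150, patience = 40, seed = 2)
})

# cheap fold checkpoints (FDBB briefly trained, TDBB barely trained) for
# ensemble plumbing tests where feature definitions, not accuracy, matter
cheap_checkpoints <- function() fixture("cheap_checkpoints", function() {
  es <- small_epochs()
  rf_ <- run_loo(es, "fdbb", n_val_subjects = 2, seed = 1, max_epochs = 3, patience = 3)
  rt <- run_loo(es, "tdbb", n_val_subjects = 2, seed = 1, max_epochs = 1, patience = 1)
  loo_checkpoints(fdbb = rf_, tdbb = rt)
})

small_ensemble <- function() fixture("small_ensemble", function() {
  extract_ensemble(cheap_checkpoints(), small_epochs())
})

# synthetic iid feature table with ensemble column names; labels planted on
# log_beta so importance recovery is unconfounded by feature correlations
planted_feature_table <- function(n = 240, n_subjects = 6, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * 48), n, 48))
  names(X) <- ensemble_feature_names()
  X$subject_id <- rep_len(sprintf("P%02d", seq_len(n_subjects)), n)
  X$label <- as.integer(X$log_beta > 0)
  X
}

# deterministic test sinusoid epochs
tone_epoch <- function(freq, fs = 400, amp = 1, phase = 0) {
  t <- (seq_len(fs) - 1) / fs
  amp * sin(2 * pi * freq * t + phase)
}
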