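# LOO splitting, metrics, training contract, narrowband probe

fake_epoch_set <- function(n_subjects, epochs_each = 4) {
  n <- n_subjects * epochs_each
  structure(list(
    samples = matrix(rnorm(n * 400), n, 400),
    index = data.frame(
      subject_id = rep(sprintf("F%02d", seq_len(n_subjects)), each = epochs_each),
      channel_id = "ch1",
      offset = rep(c(-2, -1, 0, 1), length.out = n),
      label = rep(c(0, 0, 1, 1), length.out = n),
      stringsAsFactors = FALSE),
    sample_rate = 400), class = "epoch_set")
}

test_that("loo_split partitions 25 subjects into 16 train / 8 val / 1 test", {
  es <- fake_epoch_set(25)
  sp <- loo_split(es, "F03", n_val_subjects = 8, seed = 5)
  subs <- lapply(sp, function(p) unique(p$index$subject_id))
  expect_length(subs$train, 16)
  expect_length(subs$val, 8)
  expect_identical(subs$test, "F03")
  expect_length(intersect(subs$train, subs$val), 0)
  expect_length(intersect(subs$train, subs$test), 0)
  expect_length(intersect(subs$val, subs$test), 0)
  # reproducible under the same seed, and seed-sensitive
  sp2 <- loo_split(es, "F03", n_val_subjects = 8, seed = 5)
  expect_identical(subs$val, unique(sp2$val$index$subject_id))
  expect_error(loo_split(fake_epoch_set(9), "F01", 8), "too few")
})

test_that("leakage assertions fire on overlapping partitions", {
  es <- fake_epoch_set(4)
  sp <- loo_split(es, "F01", n_val_subjects = 1, seed = 1)
  expect_true(ictalmetrics:::assert_no_leakage(sp))
  bad <- sp
  bad$val <- sp$test
  expect_error(ictalmetrics:::assert_no_leakage(bad), "leakage")
})

test_that("classification metrics match closed forms on a known confusion table", {
  p <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.2)
  y <- c(1, 0, 1, 1, 0, 0)
  m <- classification_metrics(p, y)
  # TP=2 FP=1 FN=1 TN=2 at threshold 0.5
  expect_equal(m[["ppv"]], 2 / 3)
  expect_equal(m[["npv"]], 2 / 3)
  expect_equal(m[["recall"]], 2 / 3)
  expect_equal(m[["accuracy"]], 4 / 6)
  expect_equal(m[["brier"]], mean((p - y)^2))
  expect_equal(m[["auc"]], 7 / 9)  # 7 of 9 positive-negative pairs ordered
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- runif(60) + 0.3 * y
    expect_equal(classification_metrics(p, y)[["auc"]],
                 as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("training respects the early-stopping contract and learns the easy task", {
  fr <- small_fdbb_fold()
  expect_lte(fr$epochs_trained, 150)
  expect_gt(fr$metrics[["auc"]], 0.9)
  expect_identical(fr$heldout_subject, "S01")
  expect_true(all(c("auc", "brier", "ppv", "npv", "recall", "accuracy")
                  %in% names(fr$metrics)))
})

test_that("run_loo yields one fold per subject, each held out exactly once", {
  es <- small_epochs()
  r <- run_loo(es, "emc", n_val_subjects = 2, seed = 4, max_epochs = 5, patience = 5)
  expect_length(r$folds, 6)
  held <- vapply(r$folds, `[[`, character(1), "heldout_subject")
  expect_setequal(held, unique(es$index$subject_id))
  expect_false(any(duplicated(held)))
  # reproducible under the same seed
  r2 <- run_loo(es, "emc", n_val_subjects = 2, seed = 4, max_epochs = 5, patience = 5)
  expect_equal(r$summary$mean, r2$summary$mean)
})

test_that("biquad band-pass concentrates power around its resonant frequency", {
  set.seed(44)
  X <- matrix(rnorm(30 * 400), 30, 400)
  for (ctr in c(20, 60, 120)) {
    Xf <- biquad_bandpass(X, ctr)
    frac <- mean(apply(Xf, 1, function(x) {
      psd <- welch_psd(x)
      sum(psd$power[psd$freq >= ctr - 5 & psd$freq <= ctr + 5]) /
        sum(psd$power[psd$freq > 0])
    }))
    expect_gt(frac, 0.6)   # second-order skirts put ~70-75% inside +/- 5 Hz
    # response peaks at the resonant frequency
    pk <- mean(apply(Xf, 1, function(x) {
      psd <- welch_psd(x)
      psd$freq[which.max(psd$power)]
    }))
    expect_lt(abs(pk - ctr), 5)
  }
  expect_error(biquad_bandpass(X, 250), "Nyquist")
})

test_that("probe of a gamma-trained model peaks at gamma frequencies", {
  fr <- small_fdbb_fold()
  es <- small_epochs()
  sub <- epoch_subset(es, seq(1, nrow(es$samples), by = 8))
  pr <- narrowband_probe(fr$model, sub)
  expect_equal(nrow(pr$response), 77)                      # 2,4,...,154 Hz
  expect_equal(range(pr$response$center_freq), c(2, 154))
  peak <- pr$response$center_freq[which.max(pr$response$output_cor)]
  expect_gte(peak, 30)
  expect_true(all(abs(pr$response$output_cor) <= 1))
  expect_equal(dim(pr$feature_cor), c(77, 16))
})

test_that("EMC probe localizes band features to their own bands", {
  # engineered features need no training: probe an assembled EMC directly
  m <- assemble_model("emc", seed = 3)
  es <- small_epochs()
  sub <- epoch_subset(es, seq(1, nrow(es$samples), by = 12))
  pr <- narrowband_probe(m, sub)
  peak_of <- function(feat) {
    pr$response$center_freq[which.max(pr$feature_mean[, feat])]
  }
  bands <- eeg_bands()
  # each relative band power responds most inside its own band
  # (+/- half the 5 Hz probe bandwidth at the edges)
  for (b in names(bands)) {
    pk <- peak_of(paste0("rel_", b))
    expect_true(pk >= bands[[b]][1] - 2.5 && pk <= bands[[b]][2] + 2.5,
                label = sprintf("rel_%s peak at %g Hz inside [%g, %g]",
                                b, pk, bands[[b]][1], bands[[b]][2]))
  }
})

test_that("point-biserial correlation handles degenerate inputs", {
  expect_equal(point_biserial(rep(1, 10), rep(0:1, 5)), 0)
  expect_equal(point_biserial(rnorm(10), rep(1, 10)), 0)
  y <- rep(0:1, each = 20)
  x <- y + rnorm(40, sd = 0.1)
  expect_gt(point_biserial(x, y), 0.9)
})
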