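#' Subset an epoch set by row index
#' @param es An \code{epoch_set}.
#' @param idx Integer or logical row index.
#' @return The subsetted \code{epoch_set}.
#' @export
epoch_subset <- function(es, idx) {
  structure(list(samples = es$samples[idx, , drop = FALSE],
                 index = es$index[idx, , drop = FALSE],
                 sample_rate = es$sample_rate),
            class = "epoch_set")
}

#' Subject-wise leave-one-out split
#'
#' The test partition is every epoch of the held-out subject; the
#' validation partition is every epoch of \code{n_val_subjects} other
#' subjects drawn at random (the same seed gives the same split for every
#' model, so folds stay comparable across models); the rest train. The
#' three partitions are disjoint by subject, which makes subject-level
#' leakage impossible by construction.
#'
#' @param es An \code{epoch_set} covering at least
#'   \code{n_val_subjects + 2} subjects.
#' @param heldout_subject Subject id to hold out.
#' @param n_val_subjects Number of validation subjects (default 8).
#' @param seed Integer seed for the validation draw.
#' @return List with \code{train}, \code{val}, \code{test} epoch sets.
#' @export
loo_split <- function(es, heldout_subject, n_val_subjects = 8, seed = 0) {
  subjects <- unique(es$index$subject_id)
  if (!heldout_subject %in% subjects) stop("unknown heldout subject")
  others <- setdiff(subjects, heldout_subject)
  if (length(others) < n_val_subjects + 1) {
    stop("too few subjects for the requested validation size")
  }
  val_sub <- with_seed(seed * 104729L + 7L, sample(others, n_val_subjects))
  sid <- es$index$subject_id
  list(train = epoch_subset(es, !(sid %in% c(heldout_subject, val_sub))),
       val = epoch_subset(es, sid %in% val_sub),
       test = epoch_subset(es, sid == heldout_subject))
}

#' Binary classification metrics
#'
#' AUC by the rank (Mann-Whitney) statistic, Brier score, and
#' threshold-0.5 PPV, NPV, recall and accuracy.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector \code{auc, brier, ppv, npv, recall,
#'   accuracy}.
#' @export
classification_metrics <- function(p, y, threshold = 0.5) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- if (n1 > 0 && n0 > 0) {
    (sum(rank(p)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  yhat <- as.integer(p >= threshold)
  tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
  tn <- sum(yhat == 0 & y == 0); fn <- sum(yhat == 0 & y == 1)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  c(auc = auc, brier = mean((p - y)^2),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
    recall = div(tp, tp + fn), accuracy = (tp + tn) / length(y))
}

# combined sequential layer list for training; remembers the encoder length
combine_model <- function(model) {
  enc_layers <- if (is.null(model$encoder)) list() else model$encoder$layers
  list(layers = c(enc_layers, model$classifier$layers),
       n_enc = length(enc_layers), spec = model$spec)
}

split_model <- function(net, model) {
  if (net$n_enc > 0) model$encoder$layers <- net$layers[seq_len(net$n_enc)]
  model$classifier$layers <- net$layers[(net$n_enc + 1):length(net$layers)]
  model
}

#' Train one model on one leave-one-out fold
#'
#' Mini-batch Adam (learning rate 0.001) with binary cross-entropy loss,
#' early-stopped when the validation loss has not improved for
#' \code{patience} epochs or \code{max_epochs} is reached. The returned
#' model is the minimum-validation-loss checkpoint; if a test partition is
#' supplied its metrics are attached.
#'
#' @param model A \code{seizure_model} from \code{\link{assemble_model}}.
#' @param train,val,test \code{epoch_set} partitions (test optional).
#' @param lr Learning rate (default 0.001).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param max_epochs Maximum training epochs (default 200).
#' @param batch_size Mini-batch size (default 128).
#' @param seed Seed for shuffling and dropout.
#' @param inputs Optional precomputed model inputs (list with
#'   \code{train}, \code{val}, \code{test}), to avoid recomputing
#'   engineered features or spectra.
#' @return A \code{fold_result}: list with \code{model},
#'   \code{heldout_subject}, \code{metrics}, \code{epochs_trained},
#'   \code{best_val_loss}.
#' @export
train_fold <- function(model, train, val, test = NULL, lr = 1e-3,
                       patience = 10, max_epochs = 200, batch_size = 128,
                       seed = 0, inputs = NULL) {
  if (is.null(inputs)) {
    inputs <- list(train = model_input(model, train$samples, train$sample_rate),
                   val = model_input(model, val$samples, val$sample_rate),
                   test = if (!is.null(test)) model_input(model, test$samples, test$sample_rate))
  }
  net <- combine_model(model)
  opt <- adam_init(net)
  y_tr <- train$index$label
  y_va <- val$index$label
  n <- nrow(rbind(inputs$train))
  best <- list(loss = Inf, net = NULL, epoch = 0L)
  t_step <- 0L
  with_seed(seed * 7121L + 13L, {
    for (ep in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        Xb <- take_rows(inputs$train, b)
        r <- nn_forward(net, Xb, training = TRUE)
        net$layers <- r$model$layers
        p <- as.numeric(r$out)
        if (any(!is.finite(p))) stop("training diverged: non-finite model output")
        g <- matrix(bce_grad(p, y_tr[b]), ncol = 1)
        grads <- nn_backward(net, g)
        t_step <- t_step + 1L
        st <- adam_step(net, grads, opt, lr = lr, t = t_step)
        net$layers <- st$model$layers
        opt <- st$opt
      }
      p_val <- as.numeric(nn_forward(net, inputs$val)$out)
      vloss <- bce_loss(p_val, y_va)
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, net = nn_strip_cache(net), epoch = ep)
      }
      if (ep - best$epoch >= patience) break
    }
  })
  model <- split_model(best$net %||% nn_strip_cache(net), model)
  metrics <- NULL
  if (!is.null(test)) {
    p_test <- predict_epochs(model, inputs$test, prepared = TRUE)
    metrics <- classification_metrics(p_test, test$index$label)
  }
  structure(list(model = model, heldout_subject = if (!is.null(test)) test$index$subject_id[1],
                 metrics = metrics, epochs_trained = ep,
                 best_val_loss = best$loss),
            class = "fold_result")
}

take_rows <- function(X, idx) {
  if (length(dim(X)) == 3) X[idx, , , drop = FALSE] else X[idx, , drop = FALSE]
}

#' Subject-wise leave-one-out cross-validation
#'
#' Trains one model per subject with that subject held out, computing
#' held-out metrics for each fold. Model inputs (spectra, engineered
#' features) are computed once for the whole epoch set and reused across
#' folds.
#'
#' @param es An \code{epoch_set} for the full dataset.
#' @param kind Model kind: "tdbb", "fdbb" or "emc".
#' @param n_val_subjects Validation subjects per fold.
#' @param seed Master seed (splits, initialization, shuffling).
#' @param ... Passed to \code{\link{train_fold}} (e.g. \code{max_epochs}).
#' @return A \code{loo_result}: list of \code{fold_result}s plus
#'   \code{summary} (mean and sd of each metric across folds).
#' @export
run_loo <- function(es, kind, n_val_subjects = 8, seed = 0, ...) {
  subjects <- unique(es$index$subject_id)
  proto <- assemble_model(kind, seed = seed)
  X_all <- model_input(proto, es$samples, es$sample_rate)
  sid <- es$index$subject_id
  folds <- lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    sp <- loo_split(es, s, n_val_subjects, seed = seed)
    assert_no_leakage(sp)
    pick <- function(part) which(sid %in% unique(part$index$subject_id))
    inputs <- list(train = take_rows(X_all, pick(sp$train)),
                   val = take_rows(X_all, pick(sp$val)),
                   test = take_rows(X_all, pick(sp$test)))
    model <- assemble_model(kind, seed = seed + i)
    train_fold(model, sp$train, sp$val, sp$test, seed = seed + i,
               inputs = inputs, ...)
  })
  m <- do.call(rbind, lapply(folds, `[[`, "metrics"))
  structure(list(folds = folds,
                 summary = list(mean = colMeans(m, na.rm = TRUE),
                                sd = apply(m, 2, stats::sd, na.rm = TRUE))),
            class = "loo_result")
}

# fails loudly if any two partitions share a subject
assert_no_leakage <- function(sp) {
  subs <- lapply(sp, function(p) unique(p$index$subject_id))
  if (length(intersect(subs$train, subs$val)) ||
      length(intersect(subs$train, subs$test)) ||
      length(intersect(subs$val, subs$test))) {
    stop("subject leakage between LOO partitions")
  }
  invisible(TRUE)
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("LOO cross-validation over %d folds\n", length(x$folds)))
  m <- x$summary
  for (k in names(m$mean)) {
    cat(sprintf("  %-8s %.3f +/- %.3f\n", k, m$mean[[k]], m$sd[[k]]))
  }
  invisible(x)
}

#' Narrowband biquad band-pass of epochs
#'
#' Second-order (biquad) band-pass with the given center (resonant)
#' frequency and bandwidth, applied causally to each epoch row, as used by
#' the frequency-response probe.
#'
#' @param epochs Epoch matrix (rows = epochs).
#' @param center Center frequency in Hz (must be below Nyquist).
#' @param bandwidth Full bandwidth in Hz (default 5).
#' @param fs Sample rate in Hz.
#' @return Filtered epoch matrix.
#' @export
biquad_bandpass <- function(epochs, center, bandwidth = 5, fs = 400) {
  ny <- fs / 2
  if (center >= ny) stop("center frequency must be below Nyquist")
  lo <- max(0.25, center - bandwidth / 2)
  hi <- min(0.999 * ny, center + bandwidth / 2)
  flt <- signal::butter(1, c(lo, hi) / ny, type = "pass")
  epochs <- rbind(epochs)
  t(apply(epochs, 1, function(x) signal::filter(flt, x)))
}

#' Narrowband frequency-response probe of a trained model
#'
#' Band-pass filters the probe epochs with a 5 Hz-wide biquad whose center
#' frequency steps at 2 Hz intervals (2, 4, ..., up to \code{f_stop}
#' inclusive as a bound), min-max normalizes each filtered epoch and
#' rescales it to the amplitude of the negative (preictal) class — the
#' mean peak-to-peak amplitude of preictal probe epochs — then records the
#' point-biserial correlation of the model output and of each of the 16
#' encoded features with the seizure label, plus classification metrics,
#' per frequency bin.
#'
#' @param model A trained \code{seizure_model}.
#' @param es An \code{epoch_set} of probe epochs (training or held-out
#'   partition, at the caller's choice).
#' @param bandwidth Filter bandwidth in Hz (default 5).
#' @param f_start,f_step,f_stop Center-frequency grid (default 2 to
#'   155 Hz in 2 Hz steps, i.e. centers 2..154).
#' @return A \code{probe_result}: data.frame \code{response} with columns
#'   \code{center_freq}, \code{output_cor}, and the per-bin metrics; matrix
#'   \code{feature_cor} (bins x 16) of feature-label correlations; and
#'   matrix \code{feature_mean} (bins x 16) of mean feature responses,
#'   which localizes band-defined features to their own bands.
#' @export
narrowband_probe <- function(model, es, bandwidth = 5, f_start = 2,
                             f_step = 2, f_stop = 155) {
  centers <- seq(f_start, f_stop, by = f_step)
  centers <- centers[centers < es$sample_rate / 2]
  y <- es$index$label
  neg <- es$samples[y == 0, , drop = FALSE]
  target_amp <- mean(apply(neg, 1, function(x) diff(range(x))))
  rows <- vector("list", length(centers))
  fcor <- matrix(NA_real_, length(centers), 16,
                 dimnames = list(NULL, encoded_feature_names(model$spec$kind)))
  fmean <- fcor
  for (i in seq_along(centers)) {
    Xf <- biquad_bandpass(es$samples, centers[i], bandwidth, es$sample_rate)
    Xf <- t(apply(Xf, 1, function(x) {
      rng <- range(x)
      if (diff(rng) == 0) return(numeric(length(x)))
      ((x - rng[1]) / diff(rng) - 0.5) * target_amp
    }))
    Xin <- model_input(model, Xf, fs = es$sample_rate)
    p <- predict_epochs(model, Xin, prepared = TRUE)
    Z <- encode(model, Xin, prepared = TRUE)
    rows[[i]] <- data.frame(center_freq = centers[i],
                            output_cor = point_biserial(p, y),
                            t(classification_metrics(p, y)))
    fcor[i, ] <- apply(Z, 2, point_biserial, y = y)
    fmean[i, ] <- colMeans(Z)
  }
  structure(list(response = do.call(rbind, rows), feature_cor = fcor,
                 feature_mean = fmean),
            class = "probe_result")
}

#' Point-biserial correlation of a continuous score with a binary label
#'
#' Pearson correlation between the score and the 0/1 label; 0 when either
#' argument has zero variance.
#'
#' @param x Numeric scores.
#' @param y 0/1 labels.
#' @return Correlation in \[-1, 1\].
#' @export
point_biserial <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}
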