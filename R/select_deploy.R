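#' Names of the 48-feature ensemble
#'
#' 16 engineered metrics, then the 16 FDBB features p0..p15, then the 16
#' TDBB features z0..z15.
#' @return Character vector of length 48.
#' @export
ensemble_feature_names <- function() {
  c(engineered_feature_names(), paste0("p", 0:15), paste0("z", 0:15))
}

#' Extract the leakage-guarded 48-feature ensemble
#'
#' For every epoch, the encoded (FDBB/TDBB) features are computed only by
#' the checkpoint whose held-out subject matches the epoch's subject, so
#' no epoch is ever encoded by a model that saw that subject in training.
#' The 16 engineered metrics are appended; a missing matching checkpoint
#' raises a leakage-guard error.
#'
#' @param checkpoints Named list: \code{checkpoints[[subject_id]]} is a
#'   list with trained \code{fdbb} and \code{tdbb} models held out on that
#'   subject (see \code{\link{loo_checkpoints}}).
#' @param es An \code{epoch_set}.
#' @return Data frame of 48 feature columns plus the epoch index columns.
#' @export
extract_ensemble <- function(checkpoints, es) {
  sid <- es$index$subject_id
  eng <- t(apply(es$samples, 1, engineered_features, fs = es$sample_rate))
  P <- matrix(NA_real_, nrow(eng), 16)
  Z <- matrix(NA_real_, nrow(eng), 16)
  for (s in unique(sid)) {
    ck <- checkpoints[[s]]
    if (is.null(ck) || is.null(ck$fdbb) || is.null(ck$tdbb)) {
      stop("leakage guard: no held-out checkpoint for subject ", s)
    }
    if (!identical(ck$heldout %||% s, s)) {
      stop("leakage guard: checkpoint held-out subject does not match ", s)
    }
    rows <- which(sid == s)
    P[rows, ] <- encode(ck$fdbb, es$samples[rows, , drop = FALSE], es$sample_rate)
    Z[rows, ] <- encode(ck$tdbb, es$samples[rows, , drop = FALSE], es$sample_rate)
  }
  out <- data.frame(eng, P, Z)
  names(out) <- ensemble_feature_names()
  cbind(out, es$index)
}

#' Collect per-subject checkpoints from LOO runs
#'
#' @param ... Named \code{loo_result} objects, e.g.
#'   \code{loo_checkpoints(fdbb = r1, tdbb = r2)}.
#' @return Named list keyed by held-out subject id; each element holds the
#'   corresponding trained model per kind plus \code{heldout}.
#' @export
loo_checkpoints <- function(...) {
  runs <- list(...)
  subjects <- vapply(runs[[1]]$folds, `[[`, character(1), "heldout_subject")
  out <- lapply(seq_along(subjects), function(i) {
    ck <- lapply(runs, function(r) r$folds[[i]]$model)
    ck$heldout <- subjects[i]
    ck
  })
  names(out) <- subjects
  out
}

#' Fit an interpretable random forest on a feature table
#'
#' 30 trees of maximum depth five (the paper-scale forest), returning the
#' fitted forest and its impurity (Gini) importances normalized to sum to
#' one.
#'
#' @param features Data frame or matrix of feature columns.
#' @param labels 0/1 labels (both classes must be present).
#' @param num_trees,max_depth Forest size and depth (defaults 30 and 5).
#' @param seed Integer seed.
#' @return List with \code{forest} (a ranger object) and
#'   \code{importance} (named, nonnegative, sums to 1).
#' @export
rfc_fit <- function(features, labels, num_trees = 30, max_depth = 5, seed = 0) {
  if (length(unique(labels)) < 2) stop("labels are single-class; cannot fit a classifier")
  df <- as.data.frame(features)
  df$.label <- factor(labels, levels = c(0, 1))
  fr <- ranger::ranger(dependent.variable.name = ".label", data = df,
                       num.trees = num_trees, max.depth = max_depth,
                       importance = "impurity", probability = TRUE,
                       seed = seed %% .Machine$integer.max,
                       num.threads = 1)
  imp <- fr$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(forest = fr, importance = imp)
}

#' Nested cross-validated Gini-importance distributions
#'
#' For each external (held-out) subject, the remaining subjects' feature
#' rows are split into \code{internal_folds} folds (capped at the row
#' count); an RFC is fitted on each internal training split and its
#' normalized Gini importances recorded. The result is an importance
#' distribution of external x internal draws per feature, with the
#' most-significant (MSF) and least-significant (LSF) features read off
#' the mean-importance ranking (ties broken by name order).
#'
#' @param features Ensemble feature table from
#'   \code{\link{extract_ensemble}} (index columns are detected and used
#'   for grouping/labels).
#' @param internal_folds Internal CV fold count (default 100).
#' @param label_col,subject_col Column names for labels and subjects.
#' @param num_trees,max_depth,seed Forest parameters.
#' @return An \code{importance_table}: list with \code{draws} (matrix of
#'   draws x features), \code{summary} (data.frame with mean, sd, rank),
#'   \code{msf}, \code{lsf}.
#' @export
nested_importances <- function(features, internal_folds = 100,
                               label_col = "label", subject_col = "subject_id",
                               num_trees = 30, max_depth = 5, seed = 0) {
  meta_cols <- intersect(c("subject_id", "channel_id", "offset", "label"),
                         names(features))
  fcols <- setdiff(names(features), meta_cols)
  subjects <- unique(features[[subject_col]])
  draws <- list()
  for (si in seq_along(subjects)) {
    ext <- features[[subject_col]] != subjects[si]
    X <- features[ext, fcols, drop = FALSE]
    y <- features[[label_col]][ext]
    k <- min(internal_folds, nrow(X))
    fold_id <- with_seed(seed * 3331L + si,
                         sample(rep_len(seq_len(k), nrow(X))))
    for (f in seq_len(k)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) next
      fit <- rfc_fit(X[tr, , drop = FALSE], y[tr],
                     num_trees = num_trees, max_depth = max_depth,
                     seed = seed + si * 1000L + f)
      draws[[length(draws) + 1L]] <- fit$importance
    }
  }
  D <- do.call(rbind, draws)
  mu <- colMeans(D)
  ord <- order(-mu, names(mu))
  summ <- data.frame(feature = names(mu), mean = mu,
                     sd = apply(D, 2, stats::sd),
                     row.names = NULL)
  summ$rank <- match(summ$feature, summ$feature[ord])
  structure(list(draws = D, summary = summ,
                 msf = summ$feature[ord],
                 lsf = rev(summ$feature[ord])),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, n = 5, ...) {
  cat(sprintf("Gini importance over %d forest fits, %d features\n",
              nrow(x$draws), ncol(x$draws)))
  cat("top:", paste(utils::head(x$msf, n), collapse = ", "), "\n")
  cat("bottom:", paste(utils::head(x$lsf, n), collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation matrix between features
#'
#' Symmetric with unit diagonal; entries involving a zero-variance feature
#' are reported as missing rather than 0.
#'
#' @param features Feature table (index columns dropped automatically).
#' @return Square correlation matrix.
#' @export
correlation_matrix <- function(features) {
  meta_cols <- intersect(c("subject_id", "channel_id", "offset", "label"),
                         names(features))
  X <- as.matrix(features[, setdiff(names(features), meta_cols), drop = FALSE])
  suppressWarnings(C <- stats::cor(X))
  diag(C) <- ifelse(apply(X, 2, stats::sd) > 0, 1, NA_real_)
  C
}

# 48-feature table with encoded features averaged over all fold
# checkpoints (the deployment scheme for unseen subjects)
ensemble_features_averaged <- function(checkpoints, es) {
  eng <- t(apply(es$samples, 1, engineered_features, fs = es$sample_rate))
  avg_encode <- function(kind_name) {
    mats <- lapply(checkpoints, function(ck) {
      encode(ck[[kind_name]], es$samples, es$sample_rate)
    })
    Reduce(`+`, mats) / length(mats)
  }
  out <- data.frame(eng, avg_encode("fdbb"), avg_encode("tdbb"))
  names(out) <- ensemble_feature_names()
  cbind(out, es$index)
}

#' Deploy the feature ensemble on new recordings
#'
#' Implements the transfer scheme for an unseen dataset: epochs are cut
#' per channel, encoded features are extracted by every pretraining fold
#' checkpoint and averaged, channel feature vectors are aggregated
#' (concatenated across a fixed channel count, or averaged per feature),
#' and a per-subject random forest (30 trees, depth 5) is evaluated with
#' internal cross-validation by sample. The latency task labels ictal
#' epochs within the first 15 s of onset as positive.
#'
#' @param recordings List of \code{\link{ieeg_recording}}s (any channel
#'   count) belonging to one subject/deployment unit.
#' @param checkpoints Fold checkpoints from \code{\link{loo_checkpoints}}.
#' @param feature_subset Character vector of ensemble feature names to
#'   keep (default: all 48).
#' @param task "identification" (ictal vs preictal) or "latency" (ictal
#'   within 15 s of onset vs everything else).
#' @param aggregate "concat" (default; requires a fixed channel count) or
#'   "mean" across channels.
#' @param overlap Epoching overlap for augmentation (0 or 0.5).
#' @param n_folds Internal CV folds by sample (default 5).
#' @param latency_window Latency-positive window in seconds (default 15).
#' @param num_trees,max_depth,seed Forest parameters.
#' @return A \code{deploy_result}: data.frame \code{predictions} (one row
#'   per time window: offset, label, out-of-fold probability) and
#'   \code{metrics}.
#' @export
deploy <- function(recordings, checkpoints, feature_subset = NULL,
                   task = c("identification", "latency"),
                   aggregate = c("concat", "mean"), overlap = 0,
                   n_folds = 5, latency_window = 15,
                   num_trees = 30, max_depth = 5, seed = 0) {
  task <- match.arg(task)
  aggregate <- match.arg(aggregate)
  if (inherits(recordings, "ieeg_recording")) recordings <- list(recordings)
  if (is.null(feature_subset)) feature_subset <- ensemble_feature_names()

  agg <- lapply(recordings, function(rec) {
    es <- epoch_and_label(rec, overlap = overlap)
    ft <- ensemble_features_averaged(checkpoints, es)
    keep <- ft[, feature_subset, drop = FALSE]
    offs <- sort(unique(ft$offset))
    rows <- lapply(offs, function(o) {
      sel <- which(ft$offset == o)
      sel <- sel[order(ft$channel_id[sel])]
      v <- if (aggregate == "mean") {
        colMeans(keep[sel, , drop = FALSE])
      } else {
        x <- unlist(keep[sel, , drop = FALSE], use.names = FALSE)
        names(x) <- as.vector(outer(feature_subset, seq_along(sel),
                                    function(f, c) paste0(f, "_ch", c)))
        x
      }
      c(v, offset = o)
    })
    do.call(rbind, rows)
  })
  M <- as.data.frame(do.call(rbind, agg))
  y <- if (task == "latency") {
    as.integer(M$offset >= 0 & M$offset < latency_window)
  } else as.integer(M$offset >= 0)
  X <- M[, setdiff(names(M), "offset"), drop = FALSE]
  fold_id <- with_seed(seed * 911L + 3L, sample(rep_len(seq_len(n_folds), nrow(X))))
  prob <- rep(NA_real_, nrow(X))
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    fit <- rfc_fit(X[tr, , drop = FALSE], y[tr], num_trees = num_trees,
                   max_depth = max_depth, seed = seed + f)
    pr <- stats::predict(fit$forest, data = X[!tr, , drop = FALSE])$predictions
    prob[!tr] <- pr[, "1"]
  }
  structure(list(predictions = data.frame(offset = M$offset, label = y,
                                          prob = prob),
                 metrics = classification_metrics(prob, y),
                 task = task, n_features = ncol(X)),
            class = "deploy_result")
}

#' @export
print.deploy_result <- function(x, ...) {
  cat(sprintf("deployment (%s task): %d windows, %d aggregated features, AUC %.3f\n",
              x$task, nrow(x$predictions), x$n_features, x$metrics[["auc"]]))
  invisible(x)
}
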