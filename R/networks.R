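#' Model specification for the three seizure classifiers
#'
#' TDBB (time-domain black box): 1-D convolutional encoder over raw
#' 400-sample epochs. FDBB (frequency-domain black box): dense encoder over
#' the 200-bin one-sided FFT magnitude spectrum (DC dropped). EMC
#' (engineered-metrics classifier): the shared classifier alone, consuming
#' the 16 engineered features. Classifier dropout is 0.90 / 0.75 / 0.40
#' for TDBB / FDBB / EMC respectively.
#'
#' @param kind One of "tdbb", "fdbb", "emc".
#' @return A \code{model_spec} list with \code{kind},
#'   \code{classifier_dropout} and \code{input_arity}.
#' @export
model_spec <- function(kind = c("tdbb", "fdbb", "emc")) {
  kind <- match.arg(kind)
  structure(list(
    kind = kind,
    classifier_dropout = switch(kind, tdbb = 0.90, fdbb = 0.75, emc = 0.40),
    input_arity = switch(kind, tdbb = 400L, fdbb = 200L, emc = 16L)
  ), class = "model_spec")
}

#' Build the TDBB convolutional encoder
#'
#' Twelve Conv1d layers (stride 1, "same"-style padding k = 2p + 1) in six
#' stages separated by five max-pooling steps (kernel 6, stride 2 — the
#' unique stride-2 setting reproducing the printed intermediate lengths
#' 400, 198, 97, 46, 21, 8), ending in a 16-channel, length-1 feature map:
#' the 16 learned time-domain features z0..z15.
#'
#' @return Encoder network (list of layers).
#' @export
build_tdbb_encoder <- function() {
  list(layers = list(
    layer_conv1d(1, 2, k = 27, p = 13), layer_act("relu"),
    layer_conv1d(2, 4, k = 27, p = 13), layer_act("relu"), layer_bn(4),
    layer_maxpool(),                                        # 400 -> 198
    layer_conv1d(4, 5, k = 13, p = 6), layer_act("relu"),
    layer_conv1d(5, 7, k = 13, p = 6), layer_act("relu"), layer_bn(7),
    layer_maxpool(),                                        # 198 -> 97
    layer_conv1d(7, 9, k = 7, p = 3), layer_act("relu"),
    layer_conv1d(9, 10, k = 7, p = 3), layer_act("relu"),
    layer_conv1d(10, 11, k = 7, p = 3), layer_act("relu"), layer_bn(11),
    layer_maxpool(),                                        # 97 -> 46
    layer_conv1d(11, 12, k = 5, p = 2), layer_act("relu"),
    layer_conv1d(12, 13, k = 5, p = 2), layer_act("relu"),
    layer_conv1d(13, 14, k = 5, p = 2), layer_act("relu"), layer_bn(14),
    layer_maxpool(),                                        # 46 -> 21
    layer_conv1d(14, 15, k = 3, p = 1), layer_act("relu"), layer_bn(15),
    layer_maxpool(),                                        # 21 -> 8
    layer_conv1d(15, 16, k = 8, p = 0), layer_act("relu"),  # -> (16, 1)
    layer_flatten()
  ))
}

#' Build the FDBB dense encoder
#'
#' Input batch-norm and 75% dropout on the 200-bin spectrum, then dense
#' 200 -> 100 -> 50 -> 16 with leaky-ReLU activations and 75% dropout
#' between hidden layers: the 16 learned spectral features p0..p15.
#'
#' @return Encoder network (list of layers).
#' @export
build_fdbb_encoder <- function() {
  list(layers = list(
    layer_bn(200), layer_dropout(0.75),
    layer_dense(200, 100), layer_act("leaky_relu"), layer_dropout(0.75),
    layer_dense(100, 50), layer_act("leaky_relu"), layer_dropout(0.75),
    layer_dense(50, 16), layer_act("leaky_relu")
  ))
}

#' Build the shared classifier subnetwork
#'
#' Dense chain 16 -> 14 -> 12 -> 10 -> 8 -> 6 -> 4 -> 2 -> 1 with
#' leaky-ReLU activations through width 6, sigmoid on the last two layers
#' (as printed), input batch-norm + dropout, and a second batch-norm +
#' dropout at width 8.
#'
#' @param dropout Dropout fraction used at both dropout sites.
#' @return Classifier network (list of layers).
#' @export
build_classifier <- function(dropout) {
  stopifnot(dropout >= 0, dropout < 1)
  list(layers = list(
    layer_bn(16), layer_dropout(dropout),
    layer_dense(16, 14), layer_act("leaky_relu"),
    layer_dense(14, 12), layer_act("leaky_relu"),
    layer_dense(12, 10), layer_act("leaky_relu"),
    layer_dense(10, 8), layer_act("leaky_relu"), layer_bn(8), layer_dropout(dropout),
    layer_dense(8, 6), layer_act("leaky_relu"),
    layer_dense(6, 4), layer_act("leaky_relu"),
    layer_dense(4, 2), layer_act("sigmoid"),
    layer_dense(2, 1), layer_act("sigmoid")
  ))
}

#' Assemble a full model from its specification
#'
#' TDBB and FDBB are encoder -> classifier; the EMC is the classifier
#' alone. Weight initialization is deterministic given \code{seed}.
#'
#' @param spec A \code{\link{model_spec}} (or a kind string).
#' @param seed Integer seed for weight initialization.
#' @return A \code{seizure_model} with elements \code{spec}, \code{encoder}
#'   (NULL for the EMC) and \code{classifier}.
#' @export
assemble_model <- function(spec, seed = 0) {
  if (is.character(spec)) spec <- model_spec(spec)
  with_seed(seed * 2011L + 17L, {
    enc <- switch(spec$kind, tdbb = build_tdbb_encoder(),
                  fdbb = build_fdbb_encoder(), emc = NULL)
    cls <- build_classifier(spec$classifier_dropout)
    structure(list(spec = spec, encoder = enc, classifier = cls),
              class = "seizure_model")
  })
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf("seizure model %s: input arity %d, classifier dropout %.2f, %d parameters\n",
              toupper(x$spec$kind), x$spec$input_arity, x$spec$classifier_dropout,
              n_params(x)))
  invisible(x)
}

#' Count trainable parameters of a model
#' @param model A \code{seizure_model} or bare network.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  nets <- if (inherits(model, "seizure_model")) {
    Filter(Negate(is.null), list(model$encoder, model$classifier))
  } else list(model)
  sum(vapply(nets, function(net) {
    sum(vapply(net$layers, function(ly) {
      sum(vapply(intersect(names(ly), nn_trainable),
                 function(p) length(ly[[p]]), numeric(1)))
    }, numeric(1)))
  }, numeric(1)))
}

#' Model input representation for a batch of epochs
#'
#' Maps raw 1 s epochs to what each model consumes: the (batch, 1, 400)
#' array of raw samples for the TDBB, the 200-bin FFT magnitude spectrum
#' for the FDBB, or the 16 engineered features for the EMC.
#'
#' @param model A \code{seizure_model}.
#' @param epochs Matrix of epochs (rows) x samples (columns).
#' @param fs Sample rate in Hz.
#' @return Array or matrix matching the model's input arity.
#' @export
model_input <- function(model, epochs, fs = 400) {
  epochs <- rbind(epochs)
  switch(model$spec$kind,
    tdbb = {
      A <- array(0, c(nrow(epochs), 1, ncol(epochs)))
      A[, 1, ] <- epochs
      A
    },
    fdbb = t(apply(epochs, 1, spectrum_magnitude)),
    emc = t(apply(epochs, 1, engineered_features, fs = fs)))
}

check_arity <- function(model, X) {
  got <- if (length(dim(X)) == 3) dim(X)[3] else ncol(rbind(X))
  if (got != model$spec$input_arity) {
    stop(sprintf("shape error: %s expects input arity %d, got %d",
                 toupper(model$spec$kind), model$spec$input_arity, got))
  }
  invisible(TRUE)
}

model_forward <- function(model, X, training = FALSE) {
  check_arity(model, X)
  if (!is.null(model$encoder)) {
    r <- nn_forward(model$encoder, X, training)
    model$encoder <- r$model
    X <- r$out
  }
  r <- nn_forward(model$classifier, X, training)
  model$classifier <- r$model
  list(model = model, out = as.numeric(r$out), features = X)
}

#' Encoded 16-feature representation of epochs
#'
#' Runs the encoder in evaluation mode (dropout off, batch-norm running
#' statistics), returning the learned features z0..z15 (TDBB), p0..p15
#' (FDBB), or the engineered 16-vector (EMC).
#'
#' @param model A \code{seizure_model}.
#' @param epochs Epoch matrix, or a prepared input from
#'   \code{\link{model_input}}.
#' @param fs Sample rate in Hz.
#' @param prepared Set \code{TRUE} if \code{epochs} is already the model
#'   input representation.
#' @return Matrix (epochs x 16) with the model's feature names.
#' @export
encode <- function(model, epochs, fs = 400, prepared = FALSE) {
  X <- if (prepared) epochs else model_input(model, epochs, fs)
  check_arity(model, X)
  Z <- if (is.null(model$encoder)) X else nn_forward(model$encoder, X)$out
  Z <- rbind(Z)
  colnames(Z) <- encoded_feature_names(model$spec$kind)
  Z
}

#' Names of a model's 16 encoded features
#' @param kind Model kind string.
#' @return Character vector of length 16.
#' @export
encoded_feature_names <- function(kind) {
  switch(kind,
    tdbb = paste0("z", 0:15),
    fdbb = paste0("p", 0:15),
    emc = engineered_feature_names())
}

#' Seizure probability for a batch of epochs
#'
#' Full evaluation-mode forward pass (encoder then classifier, or
#' classifier alone for the EMC).
#'
#' @inheritParams encode
#' @return Numeric vector of probabilities in (0, 1), one per epoch.
#' @export
predict_epochs <- function(model, epochs, fs = 400, prepared = FALSE) {
  X <- if (prepared) epochs else model_input(model, epochs, fs)
  model_forward(model, X, training = FALSE)$out
}
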