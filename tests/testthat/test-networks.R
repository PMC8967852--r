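# architecture shape contracts, determinism, parameter-count stability

layer_trace <- function(net, X) {
  # dims after every layer, via the internal forward
  out <- list()
  for (i in seq_along(net$layers)) {
    r <- ictalmetrics:::forward_layer(net$layers[[i]], X, training = FALSE)
    X <- r$out
    out[[i]] <- dim(X) %||% length(X)
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TDBB encoder reproduces every printed intermediate tensor shape", {
  set.seed(1)
  enc <- build_tdbb_encoder()
  X <- array(rnorm(3 * 400), c(3, 1, 400))
  tr <- layer_trace(enc, X)
  types <- vapply(enc$layers, `[[`, character(1), "type")
  # (channels, length) after each conv, in printed order
  conv_shapes <- lapply(tr[types == "conv1d"], function(d) d[2:3])
  expect_equal(conv_shapes,
               list(c(2, 400), c(4, 400), c(5, 198), c(7, 198), c(9, 97),
                    c(10, 97), c(11, 97), c(12, 46), c(13, 46), c(14, 46),
                    c(15, 21), c(16, 1)))
  # lengths after the five pooling stages
  pool_lengths <- vapply(tr[types == "maxpool"], function(d) d[3], numeric(1))
  expect_equal(pool_lengths, c(198, 97, 46, 21, 8))
  # final feature vector
  expect_equal(tr[[length(tr)]], c(3, 16))
})

test_that("FDBB encoder maps a 200-bin spectrum to 16 features", {
  set.seed(2)
  enc <- build_fdbb_encoder()
  X <- matrix(rnorm(5 * 200), 5, 200)
  tr <- layer_trace(enc, X)
  types <- vapply(enc$layers, `[[`, character(1), "type")
  dense_widths <- vapply(tr[types == "dense"], function(d) d[2], numeric(1))
  expect_equal(dense_widths, c(100, 50, 16))
  expect_equal(tr[[length(tr)]], c(5, 16))
  # model input representation is the 200-bin DC-free magnitude spectrum
  m <- assemble_model("fdbb")
  X2 <- model_input(m, matrix(rnorm(2 * 400), 2, 400))
  expect_equal(dim(X2), c(2, 200))
})

test_that("classifier narrows 16 -> 1 through the printed widths", {
  set.seed(3)
  cls <- build_classifier(0.4)
  X <- matrix(rnorm(4 * 16), 4, 16)
  tr <- layer_trace(cls, X)
  types <- vapply(cls$layers, `[[`, character(1), "type")
  dense_widths <- vapply(tr[types == "dense"], function(d) d[2], numeric(1))
  expect_equal(dense_widths, c(14, 12, 10, 8, 6, 4, 2, 1))
  out <- tr[[length(tr)]]
  expect_equal(out, c(4, 1))
})

test_that("probabilities lie strictly in (0,1), one per epoch, even for zeros", {
  m <- assemble_model("emc", seed = 5)
  X <- matrix(0, 7, 16)
  p <- predict_epochs(m, X, prepared = TRUE)
  expect_length(p, 7)
  expect_true(all(p > 0 & p < 1))
})

test_that("parameter counts are stable across instantiations", {
  counts <- vapply(c("tdbb", "fdbb", "emc"),
                   function(k) n_params(assemble_model(k, seed = 99)), numeric(1))
  expect_equal(unname(counts), c(8725, 27145, 779))
  counts2 <- vapply(c("tdbb", "fdbb", "emc"),
                    function(k) n_params(assemble_model(k, seed = 1)), numeric(1))
  expect_identical(counts, counts2)
})

test_that("evaluation mode is deterministic; training mode applies dropout noise", {
  m <- assemble_model("fdbb", seed = 7)
  X <- matrix(rnorm(6 * 200), 6, 200)
  expect_identical(predict_epochs(m, X, prepared = TRUE),
                   predict_epochs(m, X, prepared = TRUE))
  set.seed(123)
  o1 <- ictalmetrics:::model_forward(m, X, training = TRUE)$out
  o2 <- ictalmetrics:::model_forward(m, X, training = TRUE)$out
  expect_false(identical(o1, o2))
})

test_that("weight initialization is reproducible from the seed", {
  m1 <- assemble_model("tdbb", seed = 11)
  m2 <- assemble_model("tdbb", seed = 11)
  expect_identical(m1, m2)
  m3 <- assemble_model("tdbb", seed = 12)
  expect_false(identical(m1, m3))
})

test_that("arity mismatches raise shape errors", {
  m <- assemble_model("fdbb", seed = 1)
  expect_error(predict_epochs(m, matrix(0, 2, 16), prepared = TRUE), "shape error")
  me <- assemble_model("emc", seed = 1)
  expect_error(encode(me, matrix(0, 2, 200), prepared = TRUE), "shape error")
})

test_that("encoded features are named and finite", {
  m <- assemble_model("tdbb", seed = 13)
  Z <- encode(m, matrix(rnorm(2 * 400), 2, 400))
  expect_equal(colnames(Z), paste0("z", 0:15))
  expect_true(all(is.finite(Z)))
  mf <- assemble_model("fdbb", seed = 13)
  expect_equal(colnames(encode(mf, matrix(rnorm(400), 1, 400))), paste0("p", 0:15))
})

test_that("backpropagation matches numerical gradients on a mixed network", {
  im <- asNamespace("ictalmetrics")
  set.seed(17)
  net <- list(layers = list(
    im$layer_conv1d(1, 3, k = 5, p = 2), im$layer_act("relu"), im$layer_bn(3),
    im$layer_maxpool(4, 2),
    im$layer_conv1d(3, 2, k = 3, p = 1), im$layer_act("leaky_relu"),
    im$layer_flatten(),
    im$layer_dense(2 * 9, 4), im$layer_act("sigmoid"),
    im$layer_dense(4, 1), im$layer_act("sigmoid")))
  X <- array(rnorm(6 * 20), c(6, 1, 20))
  y <- rep(0:1, 3)
  loss_train <- function(nn) {
    im$bce_loss(as.numeric(im$nn_forward(nn, X, training = TRUE)$out), y)
  }
  r <- im$nn_forward(net, X, training = TRUE)
  g <- matrix(im$bce_grad(as.numeric(r$out), y), ncol = 1)
  grads <- im$nn_backward(r$model, g)
  eps <- 1e-6
  for (i in seq_along(grads)) {
    if (is.null(grads[[i]])) next
    for (pn in names(grads[[i]])) {
      P <- net$layers[[i]][[pn]]
      for (j in sample(length(P), min(4, length(P)))) {
        np <- net; np$layers[[i]][[pn]][j] <- P[j] + eps
        nm <- net; nm$layers[[i]][[pn]][j] <- P[j] - eps
        fd <- (loss_train(np) - loss_train(nm)) / (2 * eps)
        expect_equal(grads[[i]][[pn]][j], fd, tolerance = 1e-3)
      }
    }
  }
})
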