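# Neural-network engine: analytic gradients vs finite differences,
# shape bookkeeping, optimizer behavior. The engine is internal, so it
# is reached with ':::'.

nn_build <- dmripost:::nn_build
nn_forward <- dmripost:::nn_forward
nn_backward <- dmripost:::nn_backward
nn_opt_init <- dmripost:::nn_opt_init
nn_opt_step <- dmripost:::nn_opt_step
nn_softmax_ce <- dmripost:::nn_softmax_ce

test_that("conv/pool/dense backward matches finite differences", {
  spec <- list(
    list("conv", F = 2, K = 3, P = 1), list("relu"), list("pool"),
    list("dense", n = 5), list("relu"), list("dense", n = 3))
  net <- nn_build(spec, input_dim = c(8, 8, 2), seed = 42)
  set.seed(1)
  X <- matrix(runif(3 * 8 * 8 * 2), 3)
  y <- c(1L, 3L, 2L)
  fw <- nn_forward(net, X, train = TRUE)
  ls <- nn_softmax_ce(fw$out, y)
  grads <- nn_backward(net, fw$caches, ls$dlogits)
  eps <- 1e-5
  for (li in seq_along(net$layers)) {
    if (is.null(net$layers[[li]]$W_)) next
    for (pn in c("W_", "b_")) {
      gname <- if (pn == "W_") "dW" else "db"
      P <- net$layers[[li]][[pn]]
      idx <- seq_len(min(6, length(P)))
      for (k in idx) {
        bump <- function(h) {
          n2 <- net
          n2$layers[[li]][[pn]][k] <- P[k] + h
          nn_softmax_ce(nn_forward(n2, X)$out, y)$loss
        }
        num <- (bump(eps) - bump(-eps)) / (2 * eps)
        ana <- as.numeric(grads[[li]][[gname]])[k]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = paste("layer", li, pn, "coord", k))
      }
    }
  }
})

test_that("MDN head loss gradient matches finite differences", {
  set.seed(3)
  m <- 3; d <- 4
  dtri <- d * (d + 1) / 2
  nH <- m * (1 + d + dtri)
  raw <- matrix(rnorm(2 * nH, sd = 0.3), 2)
  A <- matrix(runif(2 * d, -0.5, 0.5), 2)
  base <- dmripost:::.mdn_batch_loss(raw, A, m, d)
  eps <- 1e-6
  for (k in sample.int(nH, 12)) {
    rp <- raw; rp[1, k] <- rp[1, k] + eps
    rm <- raw; rm[1, k] <- rm[1, k] - eps
    num <- (dmripost:::.mdn_batch_loss(rp, A, m, d, FALSE)$nll -
            dmripost:::.mdn_batch_loss(rm, A, m, d, FALSE)$nll) /
      (2 * eps)
    expect_equal(base$draw[1, k], num, tolerance = 1e-4,
                 label = paste("head coord", k))
  }
})

test_that("softmax cross-entropy has textbook values and gradient", {
  logits <- matrix(c(0, 0, 0), 1)
  ls <- nn_softmax_ce(logits, 1L)
  expect_equal(ls$loss, log(3))
  expect_equal(as.numeric(ls$dlogits), c(1 / 3 - 1, 1 / 3, 1 / 3))
})

test_that("max pooling forwards the 2x2 block maxima", {
  arr <- matrix(c(1, 5, 2, 0,
                  3, 4, 0, 0,
                  0, 0, 9, 8,
                  0, 0, 7, 6), 4, byrow = TRUE)
  img <- matrix(as.numeric(arr), 1)     # h-fastest column-major
  r <- dmripost:::maxpool2_fwd_cpp(img, 4L, 4L, 1L)
  expect_equal(sort(as.numeric(r$out)), sort(c(5, 2, 0, 9)))
})

test_that("SGD momentum and Adam reduce a quadratic loss", {
  spec <- list(list("dense", n = 1))
  for (kind in c("sgd", "adam")) {
    net <- nn_build(spec, input_dim = 2, seed = 5)
    opt <- nn_opt_init(net, kind, lr = 0.05, momentum = 0.9)
    X <- matrix(c(1, 0, 0, 1, 1, 1), 3, byrow = TRUE)
    yt <- c(2, -1, 1)
    l0 <- NULL
    for (it in 1:100) {
      fw <- nn_forward(net, X, train = TRUE)
      err <- fw$out[, 1] - yt
      if (is.null(l0)) l0 <- mean(err^2)
      grads <- nn_backward(net, fw$caches,
                           matrix(2 * err / 3, ncol = 1))
      st <- nn_opt_step(net, grads, opt)
      net <- st$net; opt <- st$opt
    }
    l1 <- mean((nn_forward(net, X)$out[, 1] - yt)^2)
    expect_lt(l1, l0 / 10)
  }
})

test_that("dropout is inactive at evaluation time", {
  spec <- list(list("dense", n = 8), list("dropout", rate = 0.5),
               list("dense", n = 2))
  net <- nn_build(spec, input_dim = 4, seed = 6)
  X <- matrix(runif(8), 2)
  o1 <- nn_forward(net, X)$out
  o2 <- nn_forward(net, X)$out
  expect_identical(o1, o2)
})

test_that("classifier architecture has the reference layer shapes", {
  model <- build_classifier(classifier_config())
  net <- model$net
  types <- vapply(net$layers, function(L) L$type, character(1))
  expect_equal(sum(types == "conv"), 2)
  expect_equal(sum(types == "pool"), 2)
  # flatten after the trunk: 11 x 11 x 6 = 726 inputs to the first FC
  first_dense <- which(types == "dense")[1]
  expect_equal(nrow(net$layers[[first_dense]]$W_), 726)
  dense_widths <- vapply(net$layers[types == "dense"],
                         function(L) ncol(L$W_), numeric(1))
  expect_equal(dense_widths, c(1000, 500, 84, 64, 32, 16, 3))
  expect_equal(net$output_dim, 3)
})
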