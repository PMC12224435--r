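# Minimal feed-forward neural-network engine used by the fiber-count
# classifier and the mixture-density posterior networks. Batches are
# plain matrices (one row per sample); images use the flat layout
# column = h + H (w - 1) + H W (c - 1). Convolution, pooling and the
# mixture likelihood run in compiled code; everything else is dense
# linear algebra.

# ---- layer constructors (internal) ----

.nn_dims_flat <- function(d) prod(d)

#' Build a feed-forward network
#'
#' @param spec list of layer specs; each element is a list whose first
#'   element is the type: `"conv"` (fields F, K, P), `"pool"` (2x2,
#'   stride 2), `"relu"`, `"dropout"` (field rate), `"dense"` (field n).
#' @param input_dim input dimensions `c(H, W, C)` for image input or a
#'   single integer for flat input.
#' @param seed integer seed for weight initialization.
#' @return object of class `nn_net`.
#' @keywords internal
nn_build <- function(spec, input_dim, seed = 1L) {
  set.seed(seed)
  dims <- input_dim                    # c(H, W, C) or scalar
  layers <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    type <- s[[1]]
    if (type == "conv") {
      stopifnot(length(dims) == 3)
      K <- s$K; P <- s$P; Fm <- s$F
      fan_in <- K * K * dims[3]
      L <- list(type = "conv", H = dims[1], W = dims[2], C = dims[3],
                K = K, P = P, F = Fm,
                W_ = matrix(rnorm(fan_in * Fm, 0, sqrt(2 / fan_in)),
                            fan_in, Fm),
                b_ = rep(0, Fm))
      OH <- dims[1] + 2 * P - K + 1
      OW <- dims[2] + 2 * P - K + 1
      dims <- c(OH, OW, Fm)
    } else if (type == "pool") {
      stopifnot(length(dims) == 3, dims[1] %% 2 == 0, dims[2] %% 2 == 0)
      L <- list(type = "pool", H = dims[1], W = dims[2], C = dims[3])
      dims <- c(dims[1] / 2, dims[2] / 2, dims[3])
    } else if (type == "relu") {
      L <- list(type = "relu")
    } else if (type == "dropout") {
      L <- list(type = "dropout", rate = s$rate)
    } else if (type == "dense") {
      n_in <- .nn_dims_flat(dims)
      n_out <- s$n
      L <- list(type = "dense",
                W_ = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)),
                            n_in, n_out),
                b_ = rep(0, n_out))
      dims <- n_out
    } else stop("unknown layer type: ", type)
    layers[[i]] <- L
  }
  structure(list(layers = layers, input_dim = input_dim,
                 output_dim = .nn_dims_flat(dims), seed = seed),
            class = "nn_net")
}

# forward pass; when train = TRUE dropout is active (inverted dropout)
nn_forward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    L <- net$layers[[i]]
    if (L$type == "conv") {
      r <- conv2d_fwd_cpp(X, L$W_, L$b_, L$H, L$W, L$C, L$K, L$P)
      caches[[i]] <- list(cols = r$cols)
      X <- r$out
    } else if (L$type == "pool") {
      r <- maxpool2_fwd_cpp(X, L$H, L$W, L$C)
      caches[[i]] <- list(which = r$which)
      X <- r$out
    } else if (L$type == "relu") {
      mask <- X > 0
      X <- X * mask
      caches[[i]] <- list(mask = mask)
    } else if (L$type == "dropout") {
      if (train && L$rate > 0) {
        mask <- matrix(runif(length(X)) >= L$rate, nrow(X)) / (1 - L$rate)
        X <- X * mask
        caches[[i]] <- list(mask = mask)
      } else caches[[i]] <- list(mask = NULL)
    } else if (L$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- X %*% L$W_
      X <- sweep(X, 2, L$b_, "+")
    }
  }
  list(out = X, caches = caches)
}

# backward pass; returns per-layer gradients (same shape as params)
nn_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    L <- net$layers[[i]]
    cc <- caches[[i]]
    if (L$type == "conv") {
      need_dx <- i > 1
      r <- conv2d_bwd_cpp(cc$cols, dOut, L$W_, L$H, L$W, L$C, L$K, L$P,
                          need_dx)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dOut <- if (need_dx) r$dX else NULL
    } else if (L$type == "pool") {
      dOut <- maxpool2_bwd_cpp(dOut, cc$which, L$H, L$W, L$C)
    } else if (L$type == "relu") {
      dOut <- dOut * cc$mask
    } else if (L$type == "dropout") {
      if (!is.null(cc$mask)) dOut <- dOut * cc$mask
    } else if (L$type == "dense") {
      grads[[i]] <- list(dW = crossprod(cc$X, dOut),
                         db = colSums(dOut))
      dOut <- tcrossprod(dOut, L$W_)
    }
  }
  grads
}

# ---- optimizers ----

nn_opt_init <- function(net, method = c("sgd", "adam"),
                        lr = 1e-4, momentum = 0.95,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  state <- lapply(net$layers, function(L) {
    if (!is.null(L$W_))
      list(vW = L$W_ * 0, vb = L$b_ * 0,
           mW = L$W_ * 0, mb = L$b_ * 0)
    else NULL
  })
  list(method = method, lr = lr, momentum = momentum,
       beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, state = state)
}

nn_opt_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- opt$state[[i]]
    if (opt$method == "sgd") {
      st$vW <- opt$momentum * st$vW - opt$lr * g$dW
      st$vb <- opt$momentum * st$vb - opt$lr * g$db
      net$layers[[i]]$W_ <- net$layers[[i]]$W_ + st$vW
      net$layers[[i]]$b_ <- net$layers[[i]]$b_ + st$vb
    } else {
      st$mW <- opt$beta1 * st$mW + (1 - opt$beta1) * g$dW
      st$mb <- opt$beta1 * st$mb + (1 - opt$beta1) * g$db
      st$vW <- opt$beta2 * st$vW + (1 - opt$beta2) * g$dW^2
      st$vb <- opt$beta2 * st$vb + (1 - opt$beta2) * g$db^2
      corr1 <- 1 - opt$beta1^opt$t
      corr2 <- 1 - opt$beta2^opt$t
      net$layers[[i]]$W_ <- net$layers[[i]]$W_ -
        opt$lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + opt$eps)
      net$layers[[i]]$b_ <- net$layers[[i]]$b_ -
        opt$lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + opt$eps)
    }
    opt$state[[i]] <- st
  }
  list(net = net, opt = opt)
}

# softmax cross-entropy loss and gradient; labels in 1..K
nn_softmax_ce <- function(logits, labels) {
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, prob = p, dlogits = dlogits / n)
}
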