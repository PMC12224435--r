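# Mixture-density-network posterior over the 6n-dimensional parameter
# vector alpha, conditioned on the 32 x 32 x 3 ODF map. One network is
# trained per fiber count; the mixture must have at least n! components
# to represent the exchange symmetry of the forward model.

#' Gaussian mixture posterior
#'
#' @param weights mixture weights, non-negative, summing to 1 (1e-6).
#' @param means m x d matrix of component means (natural units: rad for
#'   angles, um^2/ms for eigenvalues).
#' @param covs list of m symmetric positive definite d x d covariance
#'   matrices.
#' @return object of class `mixture_posterior`.
#' @export
mixture_posterior <- function(weights, means, covs) {
  means <- as.matrix(means)
  m <- length(weights)
  if (nrow(means) != m || length(covs) != m)
    stop("component count mismatch")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1")
  for (S in covs) {
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop("covariances must be symmetric")
    # Cholesky is the factorization every downstream density uses, so
    # it is also the acceptance test (eigen underflows for valid but
    # ill-conditioned L L' factors)
    if (inherits(try(chol(S), silent = TRUE), "try-error"))
      stop("covariances must be positive definite")
  }
  structure(list(weights = weights, means = means, covs = covs,
                 m = m, d = ncol(means)),
            class = "mixture_posterior")
}

# log multivariate normal density via Cholesky
.log_mvn <- function(x, mu, Sigma) {
  Rch <- chol(Sigma)
  z <- backsolve(Rch, x - mu, transpose = TRUE)
  -sum(log(diag(Rch))) - 0.5 * sum(z^2) -
    0.5 * length(x) * log(2 * pi)
}

#' Mixture posterior density
#'
#' q(alpha) = sum_i w_i N(alpha; mu_i, Sigma_i).
#'
#' @param post a [mixture_posterior()].
#' @param alpha parameter vector of length `post$d` (or matrix with
#'   one row per evaluation point).
#' @param log if TRUE return the log density.
#' @return density value(s).
#' @export
mdn_density <- function(post, alpha, log = FALSE) {
  stopifnot(inherits(post, "mixture_posterior"))
  A <- if (is.matrix(alpha)) alpha else matrix(alpha, nrow = 1)
  if (ncol(A) != post$d) stop("alpha dimension mismatch")
  out <- apply(A, 1, function(x) {
    ll <- vapply(seq_len(post$m), function(i)
      log(post$weights[i] + 1e-300) +
        .log_mvn(x, post$means[i, ], post$covs[[i]]), numeric(1))
    mx <- max(ll)
    mx + log(sum(exp(ll - mx)))
  })
  if (log) out else exp(out)
}

# ---- parameter standardization from the prior bounds ----

# per-coordinate affine map: alpha_std = (alpha - center) / scale
.alpha_standardizer <- function(spec, n_fibers) {
  lo <- rep(c(spec$theta_range[1], spec$phi_range[1],
              spec$fast_range[1], spec$fast_range[1],
              spec$slow_range[1], spec$slow_range[1]), n_fibers)
  hi <- rep(c(spec$theta_range[2], spec$phi_range[2],
              spec$fast_range[2], spec$fast_range[2],
              spec$slow_range[2], spec$slow_range[2]), n_fibers)
  list(center = (lo + hi) / 2, scale = (hi - lo) / 2, lo = lo, hi = hi)
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# split a raw head row-batch into logits / means / packed factors
.head_split <- function(raw, m, d) {
  dtri <- d * (d + 1) / 2
  stopifnot(ncol(raw) == m * (1 + d + dtri))
  list(logits = raw[, seq_len(m), drop = FALSE],
       Mu = raw[, m + seq_len(m * d), drop = FALSE],
       Lpraw = raw[, m + m * d + seq_len(m * dtri), drop = FALSE],
       dtri = dtri)
}

# indices (within a packed triangle) of the diagonal entries
.tri_diag_idx <- function(d) {
  q <- seq_len(d)
  cumsum(c(1, rev(seq_len(d - 1) + 1)))[seq_len(d)]
}

#' Map raw network outputs to a valid mixture posterior
#'
#' Weights are obtained by a normalized exponential of the first m
#' outputs; each covariance is assembled as Sigma = L L' from a packed
#' lower-triangular factor whose diagonal is made strictly positive by
#' a softplus (plus a small floor), which guarantees positive
#' definiteness for any finite input. Means and covariances are mapped
#' from the standardized parameter space back to natural units using
#' the prior bounds.
#'
#' @param raw numeric vector of length m(1 + d + d(d+1)/2).
#' @param m number of mixture components.
#' @param d parameter dimension (6 per fiber).
#' @param std standardizer from prior bounds (internal; defaults to the
#'   default prior for d/6 fibers).
#' @return a [mixture_posterior()] in natural units.
#' @export
network_head_to_mixture <- function(raw, m, d,
                                    std = .alpha_standardizer(
                                      prior_spec(), d / 6)) {
  if (any(!is.finite(raw))) stop("non-finite head outputs")
  sp <- .head_split(matrix(raw, nrow = 1), m, d)
  lg <- drop(sp$logits)
  w <- exp(lg - max(lg)); w <- w / sum(w)
  didx <- .tri_diag_idx(d)
  means <- matrix(0, m, d)
  covs <- vector("list", m)
  Smat <- diag(std$scale, d)
  for (i in seq_len(m)) {
    mu_std <- sp$Mu[1, (i - 1) * d + seq_len(d)]
    means[i, ] <- std$center + std$scale * mu_std
    lp <- sp$Lpraw[1, (i - 1) * sp$dtri + seq_len(sp$dtri)]
    lp[didx] <- .softplus(lp[didx]) + 1e-3
    L <- matrix(0, d, d)
    L[lower.tri(L, diag = TRUE)] <- lp
    Sig <- Smat %*% tcrossprod(L) %*% Smat
    Sig <- (Sig + t(Sig)) / 2
    # tiny ridge so the factorization survives extreme head outputs
    covs[[i]] <- Sig + diag(1e-10 * (1 + max(diag(Sig))), d)
  }
  mixture_posterior(w, means, covs)
}

#' Negative-log-posterior training loss
#'
#' With the proposal equal to the prior (single-round inference, the
#' package default), the importance ratio and normalization constant
#' are unity and the loss reduces to the negative mean log mixture
#' density of the true parameters under the predicted posteriors.
#'
#' @param posts list of [mixture_posterior()] objects, one per sample.
#' @param alphas matrix of true parameter vectors (rows aligned with
#'   `posts`), natural units.
#' @param prior a [prior_spec()]; samples outside its support raise an
#'   error under the prior-proposal regime.
#' @return scalar loss.
#' @export
snpe_loss <- function(posts, alphas, prior = prior_spec()) {
  alphas <- as.matrix(alphas)
  stopifnot(length(posts) == nrow(alphas))
  std <- .alpha_standardizer(prior, ncol(alphas) / 6)
  for (j in seq_len(nrow(alphas))) {
    a <- alphas[j, ]
    if (any(a < std$lo - 1e-9) || any(a > std$hi + 1e-9))
      stop("alpha outside prior support (sample ", j, ")")
  }
  ll <- vapply(seq_along(posts), function(j)
    mdn_density(posts[[j]], alphas[j, ], log = TRUE), numeric(1))
  -mean(ll)
}

#' Posterior network configuration
#'
#' The posterior estimator shares the classifier's convolutional trunk
#' family and stacks seven fully connected layers. The `"full"` scale
#' preset follows the reference training recipe (hidden width 1000,
#' batch size 100, learning rate 5e-5, early-stopping patience of 30
#' epochs, 10% validation split); the `"desk"` preset shrinks the
#' hidden width and trunk and raises the learning rate so that training
#' completes in minutes on one CPU while preserving the architecture
#' family (see the methods vignette).
#'
#' @param n_fibers fiber count this network is trained for (1-3).
#' @param m mixture components; defaults to 5 for n in (1,2) and 10
#'   for n = 3 (at least n! is required).
#' @param scale `"desk"` or `"full"` preset.
#' @param hidden hidden width of the fully connected chain.
#' @param n_fc number of fully connected layers (7).
#' @param dropout dropout rate between hidden layers.
#' @param trunk `"classifier"` (padding-4 conv trunk) or `"compact"`
#'   (padding-0 conv trunk, smaller flatten).
#' @param lr learning rate (Adam).
#' @param batch_size minibatch size.
#' @param patience early-stopping patience, epochs.
#' @param max_epochs hard epoch cap.
#' @param train_size simulated training-set size.
#' @param val_fraction validation fraction.
#' @param seed integer seed.
#' @return object of class `posterior_net_config`.
#' @export
posterior_net_config <- function(n_fibers, m = NULL,
                                 scale = c("desk", "full"),
                                 hidden = NULL, n_fc = 7,
                                 dropout = 0.1, trunk = NULL,
                                 lr = NULL, batch_size = 100,
                                 patience = NULL, max_epochs = NULL,
                                 train_size = NULL,
                                 val_fraction = 0.1, seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(n_fibers %in% 1:3)
  if (is.null(m)) m <- if (n_fibers == 3) 10 else 5
  if (m < factorial(n_fibers))
    stop("need at least n! mixture components")
  if (is.null(hidden)) hidden <- if (scale == "full") 1000 else 128
  if (is.null(trunk)) trunk <- if (scale == "full") "classifier"
  else "compact"
  if (is.null(lr)) lr <- if (scale == "full") 5e-5 else 1e-3
  if (is.null(patience)) patience <- if (scale == "full") 30 else 8
  if (is.null(max_epochs)) max_epochs <- if (scale == "full") 1000
  else 40
  if (is.null(train_size)) train_size <- if (scale == "full") 2e6
  else 5e4
  d <- 6L * n_fibers
  structure(list(n_fibers = n_fibers, m = m, d = d, scale = scale,
                 hidden = hidden, n_fc = n_fc, dropout = dropout,
                 trunk = trunk, lr = lr, batch_size = batch_size,
                 patience = patience, max_epochs = max_epochs,
                 train_size = train_size, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "posterior_net_config")
}

#' Build the posterior mixture-density network
#'
#' @param cfg a [posterior_net_config()].
#' @return object of class `posterior_net` (untrained).
#' @export
build_posterior_net <- function(cfg) {
  stopifnot(inherits(cfg, "posterior_net_config"))
  P <- if (cfg$trunk == "classifier") 4 else 0
  spec <- list(
    list("conv", F = 6, K = 5, P = P), list("relu"), list("pool"),
    list("conv", F = 6, K = 5, P = P), list("relu"), list("pool"))
  for (i in seq_len(cfg$n_fc - 1L)) {
    spec <- c(spec, list(list("dense", n = cfg$hidden), list("relu")))
    if (cfg$dropout > 0)
      spec <- c(spec, list(list("dropout", rate = cfg$dropout)))
  }
  dtri <- cfg$d * (cfg$d + 1) / 2
  head_dim <- cfg$m * (1 + cfg$d + dtri)
  spec <- c(spec, list(list("dense", n = head_dim)))
  net <- nn_build(spec, input_dim = c(32, 32, 3), seed = cfg$seed)
  # keep the initial mixture broad: shrink the head layer
  ih <- length(net$layers)
  net$layers[[ih]]$W_ <- net$layers[[ih]]$W_ * 0.01
  structure(list(net = net, cfg = cfg, trained = FALSE, log = NULL),
            class = "posterior_net")
}

# apply the softplus diagonal transform to a raw head batch and
# compute the training loss + gradient w.r.t. the raw head
.mdn_batch_loss <- function(raw, alpha_std, m, d, want_grad = TRUE) {
  sp <- .head_split(raw, m, d)
  didx <- .tri_diag_idx(d)
  dcols <- as.vector(outer(didx, (seq_len(m) - 1) * sp$dtri, "+"))
  Lp <- sp$Lpraw
  Lp[, dcols] <- .softplus(Lp[, dcols]) + 1e-3
  r <- mdn_nll_grad_cpp(alpha_std, sp$logits, sp$Mu, Lp, m, want_grad)
  out <- list(nll = mean(r$nll))
  if (want_grad) {
    n <- nrow(raw)
    dLp <- r$dLp
    # chain rule through softplus on the diagonal entries
    sig <- 1 / (1 + exp(-sp$Lpraw[, dcols, drop = FALSE]))
    dLp[, dcols] <- dLp[, dcols, drop = FALSE] * sig
    out$draw <- cbind(r$dlogits, r$dMu, dLp) / n
  }
  out
}

#' Train a posterior network on simulated data
#'
#' Single-round likelihood-free training: parameters are drawn from the
#' prior, signals simulated, ODF maps rendered, and the network is fit
#' by minimizing the negative log mixture density (Adam optimizer).
#' Training stops when the validation loss has not reached a new
#' minimum for `cfg$patience` epochs; the best-validation parameters
#' are restored.
#'
#' @param cfg a [posterior_net_config()].
#' @param data list with elements `maps` (n x 3072 matrix) and `alpha`
#'   (n x 6 n_fibers matrix, natural units); typically from
#'   [make_fixture()]. If NULL, data are simulated from `prior` and
#'   `scheme` at size `cfg$train_size`.
#' @param prior a [prior_spec()].
#' @param scheme acquisition scheme used when simulating.
#' @param noise_sigma noise level of the simulated training signals;
#'   defaults to `prior$sigma`. Use 0 for noiseless training sets.
#' @param verbose print per-epoch progress.
#' @return trained `posterior_net` with a `log` data.frame.
#' @export
train_posterior <- function(cfg, data = NULL, prior = prior_spec(),
                            scheme = hcp_scheme(),
                            noise_sigma = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "posterior_net_config"))
  if (is.null(data)) {
    if (is.null(noise_sigma)) noise_sigma <- prior$sigma
    fx <- make_fixture(prior, scheme,
                       counts = setNames(cfg$train_size,
                                         cfg$n_fibers),
                       noise_sigma = noise_sigma,
                       seed = cfg$seed + 17L)
    data <- list(maps = fx$maps, alpha = fx$alpha[[as.character(
      cfg$n_fibers)]])
  }
  maps <- data$maps
  alpha <- as.matrix(data$alpha)
  if (nrow(maps) == 0 || nrow(maps) != nrow(alpha))
    stop("empty or misaligned training data")
  std <- .alpha_standardizer(prior, cfg$n_fibers)
  A <- sweep(sweep(alpha, 2, std$center), 2, std$scale, "/")
  model <- build_posterior_net(cfg)
  net <- model$net
  set.seed(cfg$seed + 2L)
  n <- nrow(maps)
  perm <- sample.int(n)
  n_val <- max(1L, round(cfg$val_fraction * n))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  opt <- nn_opt_init(net, "adam", lr = cfg$lr)
  best <- list(loss = Inf, net = net, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  val_nll <- function(net) {
    tot <- 0
    for (start in seq(1, length(val_idx), by = 500)) {
      bi <- val_idx[start:min(start + 499, length(val_idx))]
      fw <- nn_forward(net, maps[bi, , drop = FALSE])
      ls <- .mdn_batch_loss(fw$out, A[bi, , drop = FALSE],
                            cfg$m, cfg$d, want_grad = FALSE)
      tot <- tot + ls$nll * length(bi)
    }
    tot / length(val_idx)
  }
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      fw <- nn_forward(net, maps[bi, , drop = FALSE], train = TRUE)
      ls <- .mdn_batch_loss(fw$out, A[bi, , drop = FALSE],
                            cfg$m, cfg$d)
      if (!is.finite(ls$nll)) stop("divergent training loss")
      grads <- nn_backward(net, fw$caches, ls$draw)
      stp <- nn_opt_step(net, grads, opt)
      net <- stp$net; opt <- stp$opt
      tl <- tl + ls$nll * length(bi); nb <- nb + length(bi)
    }
    vl <- val_nll(net)
    log <- rbind(log, data.frame(epoch = ep, train_loss = tl / nb,
                                 val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f", ep, tl / nb, vl))
    if (vl < best$loss) best <- list(loss = vl, net = net, epoch = ep)
    if (ep - best$epoch >= cfg$patience) break
  }
  model$net <- best$net
  model$trained <- TRUE
  model$log <- log
  model$std <- std
  model
}

#' Predict mixture posteriors for a batch of ODF maps
#'
#' @param model a trained `posterior_net`.
#' @param maps an `odf_map` or nvox x 3072 matrix.
#' @return list of [mixture_posterior()] objects (natural units).
#' @export
posterior_predict <- function(model, maps) {
  stopifnot(inherits(model, "posterior_net"))
  if (!isTRUE(model$trained))
    warning("posterior network has not been trained")
  X <- .as_map_batch(maps)
  raw <- nn_forward(model$net, X)$out
  std <- model$std
  if (is.null(std))
    std <- .alpha_standardizer(prior_spec(), model$cfg$n_fibers)
  lapply(seq_len(nrow(raw)), function(j)
    network_head_to_mixture(raw[j, ], model$cfg$m, model$cfg$d, std))
}

#' Select the dominant mixture component
#'
#' Computes delta_i = w_i * trace(Sigma_i^(1/2)) with the principal
#' matrix square root and selects the component with the largest delta
#' (the `"delta"` rule, the package default). The alternative
#' `"inverse"` rule selects the largest w_i / trace(Sigma_i^(1/2)),
#' which penalizes rather than rewards large variance; both rules
#' coincide with argmax w_i when all covariances are equal.
#'
#' @param post a [mixture_posterior()].
#' @param rule `"delta"` or `"inverse"`.
#' @param prior optional [prior_spec()] used to flag estimates outside
#'   the prior support.
#' @return object of class `parameter_estimate`: list(component,
#'   alpha_hat, sd, cov, delta, out_of_support).
#' @export
select_dominant_component <- function(post, rule = c("delta",
                                                     "inverse"),
                                      prior = NULL) {
  stopifnot(inherits(post, "mixture_posterior"))
  rule <- match.arg(rule)
  tr_root <- vapply(post$covs, function(S) {
    e <- eigen(S, symmetric = TRUE)
    sum(sqrt(pmax(0, e$values)))
  }, numeric(1))
  delta <- switch(rule,
                  delta = post$weights * tr_root,
                  inverse = post$weights / tr_root)
  i <- which.max(delta)
  alpha_hat <- post$means[i, ]
  oos <- rep(FALSE, length(alpha_hat))
  if (!is.null(prior)) {
    std <- .alpha_standardizer(prior, length(alpha_hat) / 6)
    oos <- alpha_hat < std$lo | alpha_hat > std$hi
  }
  structure(list(component = i, alpha_hat = alpha_hat,
                 sd = sqrt(diag(post$covs[[i]])),
                 cov = post$covs[[i]], delta = delta,
                 out_of_support = oos),
            class = "parameter_estimate")
}

#' Draw samples from a mixture posterior
#'
#' Ancestral sampling: a component is drawn by its weight, then a
#' Gaussian draw from that component.
#'
#' @param post a [mixture_posterior()].
#' @param k number of samples.
#' @param seed optional integer seed.
#' @return k x d matrix of samples; the drawn component index is
#'   attached as attribute `"component"`.
#' @export
sample_posterior <- function(post, k, seed = NULL) {
  stopifnot(inherits(post, "mixture_posterior"), k >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(post$m, k, replace = TRUE, prob = post$weights)
  out <- matrix(0, k, post$d)
  for (i in unique(comp)) {
    sel <- comp == i
    Rch <- chol(post$covs[[i]])
    Z <- matrix(rnorm(sum(sel) * post$d), ncol = post$d)
    out[sel, ] <- sweep(Z %*% Rch, 2, post$means[i, ], "+")
  }
  attr(out, "component") <- comp
  out
}
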