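# Convolutional classifier for the number of crossing fibers (1-3)
# from 32 x 32 x 3 ODF maps.

#' Classifier configuration
#'
#' Architecture and training recipe of the fiber-count classifier: two
#' convolution stages (5 x 5 kernel, 6 feature maps, zero-padding 4,
#' each followed by rectification and 2 x 2 max pooling of stride 2),
#' fully connected widths 1000, 500, 84, then a four-layer head
#' (64, 32, 16, 3). Training uses stochastic gradient descent with
#' momentum 0.95 and learning rate 1e-4 on a cross-entropy loss. The
#' head widths and the rectifier nonlinearity are package defaults;
#' only the layer counts and the output arity are architectural
#' requirements.
#'
#' @param conv_maps feature maps per conv stage.
#' @param kernel,padding conv kernel size and zero padding.
#' @param fc_widths widths of the fully connected stack.
#' @param head_widths widths of the four-layer head (last must be 3).
#' @param lr,momentum optimizer hyper-parameters (momentum applies to
#'   SGD only).
#' @param optimizer `"sgd"` (the reference recipe: momentum 0.95,
#'   learning rate 1e-4) or `"adam"`, which converges in far fewer
#'   epochs and is the practical choice for short desk-scale runs.
#' @param epochs,batch_size training schedule.
#' @param val_fraction held-out fraction for model selection.
#' @param seed integer seed (initialization, shuffling).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(conv_maps = 6, kernel = 5, padding = 4,
                              fc_widths = c(1000, 500, 84),
                              head_widths = c(64, 32, 16, 3),
                              lr = 1e-4, momentum = 0.95,
                              optimizer = c("sgd", "adam"),
                              epochs = 30, batch_size = 100,
                              val_fraction = 0.1, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (tail_n(head_widths) != 3)
    stop("classifier output dimension must be 3")
  structure(list(conv_maps = conv_maps, kernel = kernel,
                 padding = padding, fc_widths = fc_widths,
                 head_widths = head_widths, lr = lr,
                 momentum = momentum, optimizer = optimizer,
                 epochs = epochs,
                 batch_size = batch_size, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

tail_n <- function(x) x[length(x)]

#' Build the fiber-count classifier network
#'
#' @param cfg a [classifier_config()].
#' @return object of class `fiber_classifier` (untrained).
#' @export
build_classifier <- function(cfg = classifier_config()) {
  spec <- list(
    list("conv", F = cfg$conv_maps, K = cfg$kernel, P = cfg$padding),
    list("relu"), list("pool"),
    list("conv", F = cfg$conv_maps, K = cfg$kernel, P = cfg$padding),
    list("relu"), list("pool"))
  for (wd in cfg$fc_widths)
    spec <- c(spec, list(list("dense", n = wd), list("relu")))
  hw <- cfg$head_widths
  for (i in seq_along(hw)) {
    spec <- c(spec, list(list("dense", n = hw[i])))
    if (i < length(hw)) spec <- c(spec, list(list("relu")))
  }
  net <- nn_build(spec, input_dim = c(32, 32, 3), seed = cfg$seed)
  structure(list(net = net, cfg = cfg, trained = FALSE,
                 log = NULL), class = "fiber_classifier")
}

# coerce odf_map input to an engine batch matrix
.as_map_batch <- function(maps) {
  if (is.matrix(maps)) return(maps)
  if (inherits(maps, "odf_map") ||
      (is.array(maps) && length(dim(maps)) == 3))
    return(matrix(as.vector(maps), nrow = 1))
  stop("maps must be an odf_map or an nvox x 3072 matrix")
}

#' Train the fiber-count classifier
#'
#' Minimizes the cross-entropy loss by SGD with momentum; a held-out
#' split is scored each epoch and the parameters with the lowest
#' held-out loss are returned.
#'
#' @param model a `fiber_classifier` from [build_classifier()].
#' @param maps nvox x 3072 matrix of flattened ODF maps.
#' @param labels integer fiber counts (1-3), one per row.
#' @return trained `fiber_classifier` with a `log` data.frame of
#'   per-epoch train/validation loss.
#' @export
train_classifier <- function(model, maps, labels) {
  stopifnot(inherits(model, "fiber_classifier"))
  maps <- .as_map_batch(maps)
  labels <- as.integer(labels)
  if (!all(sort(unique(labels)) %in% 1:3) ||
      length(unique(labels)) < 3)
    stop("training data must contain all three classes")
  cfg <- model$cfg
  set.seed(cfg$seed + 1L)
  n <- nrow(maps)
  perm <- sample.int(n)
  n_val <- max(1L, round(cfg$val_fraction * n))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  net <- model$net
  opt <- nn_opt_init(net, if (is.null(cfg$optimizer)) "sgd"
                     else cfg$optimizer,
                     lr = cfg$lr, momentum = cfg$momentum)
  best <- list(loss = Inf, net = net)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_acc = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    tl <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      fw <- nn_forward(net, maps[bi, , drop = FALSE], train = TRUE)
      ls <- nn_softmax_ce(fw$out, labels[bi])
      if (!is.finite(ls$loss)) stop("non-finite training loss")
      grads <- nn_backward(net, fw$caches, ls$dlogits)
      stp <- nn_opt_step(net, grads, opt)
      net <- stp$net; opt <- stp$opt
      tl <- tl + ls$loss * length(bi); nb <- nb + length(bi)
    }
    vf <- nn_forward(net, maps[val_idx, , drop = FALSE])
    vls <- nn_softmax_ce(vf$out, labels[val_idx])
    vacc <- mean(max.col(vf$out) == labels[val_idx])
    log <- rbind(log, data.frame(epoch = ep, train_loss = tl / nb,
                                 val_loss = vls$loss, val_acc = vacc))
    if (vls$loss < best$loss) best <- list(loss = vls$loss, net = net)
  }
  model$net <- best$net
  model$trained <- TRUE
  model$log <- log
  model
}

#' Predict the number of crossing fibers
#'
#' @param model a trained `fiber_classifier`.
#' @param maps an `odf_map` or an nvox x 3072 batch matrix.
#' @return list with `label` (integer vector in 1..3) and
#'   `probabilities` (nvox x 3 matrix, rows sum to 1).
#' @export
predict_fiber_count <- function(model, maps) {
  stopifnot(inherits(model, "fiber_classifier"))
  if (!isTRUE(model$trained))
    warning("classifier has not been trained")
  X <- .as_map_batch(maps)
  logits <- nn_forward(model$net, X)$out
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  list(label = max.col(p), probabilities = p)
}

#' Per-class misclassification table
#'
#' Fraction of voxels whose predicted fiber count differs from the
#' ground truth, reported per true class with the evaluated counts.
#'
#' @param predict_fun function(maps_matrix) -> integer labels; pass
#'   e.g. `function(m) predict_fiber_count(model, m)$label`.
#' @param maps nvox x 3072 matrix of ODF maps.
#' @param labels true fiber counts.
#' @return data.frame with columns class, n, errors, error_rate.
#' @export
misclassification_table <- function(predict_fun, maps, labels) {
  pred <- predict_fun(maps)
  out <- do.call(rbind, lapply(1:3, function(k) {
    sel <- labels == k
    data.frame(class = k, n = sum(sel),
               errors = sum(pred[sel] != k),
               error_rate = if (any(sel)) mean(pred[sel] != k) else NA_real_)
  }))
  out
}
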