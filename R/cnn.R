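#' CNN configuration
#'
#' Hyperparameters of the one-dimensional CNN for two-class spectral
#' classification. Defaults follow the published architecture: two
#' convolution blocks (32 then 64 filters of length 20, stride 1, no
#' padding), each followed by batch normalization and ReLU; a flattening
#' layer; one hidden fully-connected layer (width 100) with ReLU and dropout
#' 0.10; a two-neuron output layer with softmax. Training uses Adam
#' (learning rate 1e-4, beta1 0.9, beta2 0.999, epsilon 1e-8), cross-entropy
#' loss with L2 penalty 1e-4 on the weights, and mini-batches of 175.
#'
#' @param input_length spectrum length (default 582).
#' @param conv_blocks list of blocks, each a list with `n_filters`,
#'   `filter_length`, `stride`, `padding`.
#' @param fc_widths widths of hidden fully-connected layers before the
#'   output layer.
#' @param dropout_rate inactivation probability after each hidden FC layer.
#' @param n_classes number of output classes.
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param l2_weight L2 regularization factor on conv/FC weights.
#' @param minibatch_size training mini-batch size.
#' @param max_epochs,patience training length and early-stopping patience
#'   (epochs without validation-accuracy improvement).
#' @param seed integer seed controlling weight init, shuffling and dropout.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(input_length = 582L,
                       conv_blocks = list(
                         list(n_filters = 32L, filter_length = 20L,
                              stride = 1L, padding = 0L),
                         list(n_filters = 64L, filter_length = 20L,
                              stride = 1L, padding = 0L)),
                       fc_widths = 100L,
                       dropout_rate = 0.10,
                       n_classes = 2L,
                       learning_rate = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       l2_weight = 1e-4,
                       minibatch_size = 175L,
                       max_epochs = 200L,
                       patience = 10L,
                       seed = 1L) {
  cfg <- list(input_length = as.integer(input_length),
              conv_blocks = conv_blocks,
              fc_widths = as.integer(fc_widths),
              dropout_rate = dropout_rate,
              n_classes = as.integer(n_classes),
              learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
              epsilon = epsilon, l2_weight = l2_weight,
              minibatch_size = as.integer(minibatch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              seed = as.integer(seed))
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop_config("dropout_rate", "must be in [0, 1)")
  }
  for (f in c("input_length", "n_classes", "minibatch_size", "max_epochs",
              "patience")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop_config(f, "must be >= 1")
  }
  for (b in cfg$conv_blocks) {
    if (!all(c("n_filters", "filter_length", "stride", "padding") %in%
             names(b))) {
      stop_config("conv_blocks",
                  "blocks need n_filters, filter_length, stride, padding")
    }
  }
  class(cfg) <- "cnn_config"
  cfg
}

#' Convolution output length
#'
#' The one-dimensional convolution output-size formula
#' `O = (I - K + 2P) / S + 1`. Refuses configurations where the numerator is
#' negative or not divisible by the stride (no silent flooring).
#'
#' @param input_length input size `I`.
#' @param filter_length filter size `K`.
#' @param padding zero-padding `P` (default 0).
#' @param stride stride `S` (default 1).
#' @return integer output length.
#' @export
#' @examples
#' conv_output_length(582, 20) # 563
#' conv_output_length(563, 20) # 544
conv_output_length <- function(input_length, filter_length, padding = 0L,
                               stride = 1L) {
  numer <- input_length - filter_length + 2 * padding
  if (numer < 0) {
    stop(sprintf("shape error: filter (%d) wider than padded input (%d)",
                 filter_length, input_length + 2 * padding), call. = FALSE)
  }
  if (numer %% stride != 0) {
    stop(sprintf(
      "shape error: (I - K + 2P) = %d not divisible by stride %d",
      numer, stride), call. = FALSE)
  }
  as.integer(numer / stride + 1L)
}

he_init <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

#' Build an untrained CNN
#'
#' Instantiates the layer stack
#' `input -> [conv -> batch-norm -> ReLU] x n_blocks -> flatten ->
#' [FC -> ReLU -> dropout] x length(fc_widths) -> FC(n_classes) -> softmax`
#' with He-initialized weights drawn from `config$seed`. Per-layer output
#' sizes are derived with [conv_output_length()] and stored in
#' `model$shapes`; a shape-incompatible configuration fails naming the
#' offending block.
#'
#' @param config a [cnn_config()].
#' @return an object of class `cnn_model`.
#' @export
build_model <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  lengths <- integer(0)
  channels <- integer(0)
  L <- config$input_length
  C <- 1L
  for (i in seq_along(config$conv_blocks)) {
    b <- config$conv_blocks[[i]]
    L <- tryCatch(
      conv_output_length(L, b$filter_length, b$padding, b$stride),
      error = function(e) {
        stop(sprintf("conv block %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      })
    C <- as.integer(b$n_filters)
    lengths[i] <- L
    channels[i] <- C
  }
  flatten_dim <- L * C
  fc_dims <- c(flatten_dim, config$fc_widths, config$n_classes)

  params <- with_seed(config$seed, {
    conv <- vector("list", length(config$conv_blocks))
    Cin <- 1L
    for (i in seq_along(conv)) {
      b <- config$conv_blocks[[i]]
      K <- as.integer(b$filter_length)
      Cout <- as.integer(b$n_filters)
      conv[[i]] <- list(
        W = array(he_init(K * Cin * Cout, K * Cin), dim = c(K, Cin, Cout)),
        b = numeric(Cout),
        gamma = rep(1, Cout),
        beta = numeric(Cout))
      Cin <- Cout
    }
    fc <- vector("list", length(fc_dims) - 1L)
    for (j in seq_along(fc)) {
      fc[[j]] <- list(
        W = matrix(he_init(fc_dims[j] * fc_dims[j + 1], fc_dims[j]),
                   fc_dims[j], fc_dims[j + 1]),
        b = numeric(fc_dims[j + 1]))
    }
    list(conv = conv, fc = fc)
  })

  # Running BN statistics start uninitialized: the first training batch
  # seeds them directly (area-normalized spectra give activations orders of
  # magnitude away from the usual unit-variance init, which would otherwise
  # take hundreds of momentum updates to forget).
  bn_state <- lapply(channels, function(C) {
    list(mean = numeric(C), var = rep(1, C), initialized = FALSE)
  })

  structure(list(config = config, params = params, bn_state = bn_state,
                 shapes = list(conv_lengths = lengths,
                               conv_channels = channels,
                               flatten_dim = flatten_dim,
                               fc_dims = fc_dims),
                 class_order = c("nonirradiated", "irradiated"),
                 trained = FALSE, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$shapes
  cat(sprintf("<cnn_model>%s input %d -> conv %s -> flatten %d -> fc %s\n",
              if (x$trained) " (trained)" else "", x$config$input_length,
              paste(sprintf("(%d x %d)", s$conv_lengths, s$conv_channels),
                    collapse = " -> "),
              s$flatten_dim,
              paste(s$fc_dims[-1], collapse = " -> ")))
  invisible(x)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Forward pass over a batch. X is B x input_length. When `training`, batch
# statistics are used for BN and dropout masks are drawn from the current
# RNG; otherwise running BN statistics are used and dropout is inactive.
# Returns probs plus (optionally) the cache needed for the backward pass and
# the observed per-layer output shapes.
cnn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  B <- nrow(X)
  x <- array(t(X), dim = c(cfg$input_length, 1L, B))
  cache <- list(conv = vector("list", length(model$params$conv)),
                fc = vector("list", length(model$params$fc)))
  observed <- list()
  new_bn <- model$bn_state

  for (i in seq_along(model$params$conv)) {
    p <- model$params$conv[[i]]
    blk <- cfg$conv_blocks[[i]]
    out <- conv1d_fwd(x, p$W, p$b, blk$stride, blk$padding)
    dims <- dim(out)
    observed[[paste0("conv", i)]] <- dims[1:2]
    Lo <- dims[1]; C <- dims[2]
    xm <- matrix(aperm(out, c(1, 3, 2)), ncol = C) # (Lo*B) x C
    if (training) {
      mu <- colMeans(xm)
      v <- pmax(colMeans(xm^2) - mu^2, 0)
      if (!isTRUE(new_bn[[i]]$initialized)) {
        new_bn[[i]]$mean <- mu
        new_bn[[i]]$var <- v
        new_bn[[i]]$initialized <- TRUE
      } else {
        new_bn[[i]]$mean <- (1 - BN_MOMENTUM) * new_bn[[i]]$mean +
          BN_MOMENTUM * mu
        new_bn[[i]]$var <- (1 - BN_MOMENTUM) * new_bn[[i]]$var +
          BN_MOMENTUM * v
      }
    } else {
      mu <- model$bn_state[[i]]$mean
      v <- model$bn_state[[i]]$var
    }
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
    ym <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
    relu_mask <- ym > 0
    act <- ym * relu_mask
    if (keep_cache) {
      cache$conv[[i]] <- list(x_in = x, xhat = xhat, istd = istd,
                              relu_mask = relu_mask, Lo = Lo, C = C)
    }
    x <- aperm(array(act, dim = c(Lo, B, C)), c(1, 3, 2))
  }

  Fdim <- dim(x)[1] * dim(x)[2]
  flat <- t(matrix(x, nrow = Fdim))               # B x F
  observed$flatten <- Fdim
  a <- flat
  nh <- length(model$params$fc) - 1L
  for (j in seq_len(nh)) {
    p <- model$params$fc[[j]]
    z <- sweep(a %*% p$W, 2, p$b, "+")
    mask <- z > 0
    h <- z * mask
    if (training && cfg$dropout_rate > 0) {
      drop_mask <- matrix(
        (runif(length(h)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
        nrow(h), ncol(h))
      h2 <- h * drop_mask
    } else {
      drop_mask <- NULL
      h2 <- h
    }
    if (keep_cache) {
      cache$fc[[j]] <- list(input = a, relu_mask = mask,
                            drop_mask = drop_mask)
    }
    a <- h2
    observed[[paste0("fc", j)]] <- ncol(a)
  }
  pout <- model$params$fc[[nh + 1L]]
  logits <- sweep(a %*% pout$W, 2, pout$b, "+")
  observed$output <- ncol(logits)
  if (keep_cache) cache$fc[[nh + 1L]] <- list(input = a)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, cache = if (keep_cache) cache,
       observed = observed, bn_state = new_bn, flat_dims = dim(x))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Loss, accuracy and gradients on one minibatch. y01 is 0/1 with
# 1 = irradiated (second class). L2 penalty 0.5 * l2 * ||W||^2 applies to
# conv and FC weights only.
cnn_loss_grad <- function(model, X, y01) {
  cfg <- model$config
  B <- nrow(X)
  fw <- cnn_forward(model, X, training = TRUE, keep_cache = TRUE)
  probs <- fw$probs
  eps <- 1e-12
  ce <- -mean(log(pmax(probs[cbind(seq_len(B), y01 + 1L)], eps)))
  l2 <- 0
  for (p in model$params$conv) l2 <- l2 + sum(p$W^2)
  for (p in model$params$fc) l2 <- l2 + sum(p$W^2)
  loss <- ce + 0.5 * cfg$l2_weight * l2
  acc <- mean((probs[, 2] > probs[, 1]) == (y01 == 1L))

  Y <- matrix(0, B, cfg$n_classes)
  Y[cbind(seq_len(B), y01 + 1L)] <- 1
  dlogits <- (probs - Y) / B

  grads <- list(conv = vector("list", length(model$params$conv)),
                fc = vector("list", length(model$params$fc)))
  nh <- length(model$params$fc) - 1L

  p <- model$params$fc[[nh + 1L]]
  cin <- fw$cache$fc[[nh + 1L]]$input
  grads$fc[[nh + 1L]] <- list(
    W = crossprod(cin, dlogits) + cfg$l2_weight * p$W,
    b = colSums(dlogits))
  dA <- dlogits %*% t(p$W)

  for (j in rev(seq_len(nh))) {
    cc <- fw$cache$fc[[j]]
    if (!is.null(cc$drop_mask)) dA <- dA * cc$drop_mask
    dz <- dA * cc$relu_mask
    p <- model$params$fc[[j]]
    grads$fc[[j]] <- list(W = crossprod(cc$input, dz) + cfg$l2_weight * p$W,
                          b = colSums(dz))
    dA <- dz %*% t(p$W)
  }

  # dA is B x F; back to (Lo, C, B)
  dims <- fw$flat_dims
  dxarr <- array(t(dA), dim = dims)
  for (i in rev(seq_along(model$params$conv))) {
    cc <- fw$cache$conv[[i]]
    p <- model$params$conv[[i]]
    blk <- cfg$conv_blocks[[i]]
    C <- cc$C
    N <- cc$Lo * dim(dxarr)[3]
    dym <- matrix(aperm(dxarr, c(1, 3, 2)), ncol = C) * cc$relu_mask
    dgamma <- colSums(dym * cc$xhat)
    dbeta <- colSums(dym)
    dxhat <- sweep(dym, 2, p$gamma, "*")
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * cc$xhat)
    dxm <- sweep(sweep(dxhat, 2, s1, "-") -
                   sweep(cc$xhat, 2, s2, "*"), 2, cc$istd, "*")
    dconv <- aperm(array(dxm, dim = c(cc$Lo, dim(dxarr)[3], C)), c(1, 3, 2))
    bw <- conv1d_bwd(cc$x_in, p$W, dconv, blk$stride, blk$padding)
    grads$conv[[i]] <- list(W = bw$dW + cfg$l2_weight * p$W, b = bw$db,
                            gamma = dgamma, beta = dbeta)
    dxarr <- bw$dX
  }

  list(loss = loss, acc = acc, grads = grads, bn_state = fw$bn_state)
}

# Elementwise Adam over the nested parameter list.
adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, opt, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- cfg$beta1 * m + (1 - cfg$beta1) * g
      v2 <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
      p2 <- p - cfg$learning_rate * (m2 / bc1) /
        (sqrt(v2 / bc2) + cfg$epsilon)
      list(p = p2, m = m2, v = v2)
    }
  }
  r <- upd(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

dataset_xy <- function(ds, input_length) {
  if (inherits(ds, "spectral_dataset")) {
    X <- ds$intensities
    y <- as.integer(ds$meta$label == "irradiated")
  } else {
    stop("expected a spectral_dataset", call. = FALSE)
  }
  if (ncol(X) != input_length) {
    stop(sprintf("shape error: spectra have %d points, model expects %d",
                 ncol(X), input_length), call. = FALSE)
  }
  list(X = X, y = y)
}

#' Train the CNN
#'
#' Minimizes cross-entropy (plus L2 penalty) with Adam in mini-batches,
#' recording per-epoch mean training accuracy/loss and validation accuracy.
#' Training stops after `patience` epochs without validation-accuracy
#' improvement or at `max_epochs`; the returned model carries the weights
#' and batch-norm statistics of the best validation epoch (first occurrence
#' on ties).
#'
#' @param model an untrained [build_model()] result.
#' @param train_set,val_set [spectral_dataset()]s containing both classes
#'   (train) on the model's grid length.
#' @param config optional [cnn_config()] override (defaults to the model's).
#' @return the trained `cnn_model` with a `history` element
#'   (`train_accuracy`, `validation_accuracy`, `train_loss`, `best_epoch`).
#' @export
train_cnn <- function(model, train_set, val_set, config = model$config) {
  stopifnot(inherits(model, "cnn_model"))
  tr <- dataset_xy(train_set, config$input_length)
  va <- dataset_xy(val_set, config$input_length)
  if (nrow(tr$X) == 0 || nrow(va$X) == 0) {
    stop("training error: empty training or validation set", call. = FALSE)
  }
  if (length(unique(tr$y)) < 2L) {
    stop("training error: training set contains a single class",
         call. = FALSE)
  }

  opt <- adam_init(model$params)
  n <- nrow(tr$X)
  best_acc <- -Inf
  best_epoch <- 0L
  best_params <- model$params
  best_bn <- model$bn_state
  hist_tr_acc <- hist_val_acc <- hist_loss <- numeric(0)

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$minibatch_size)
      ep_loss <- ep_acc <- 0
      for (s in starts) {
        b_idx <- idx[s:min(s + config$minibatch_size - 1L, n)]
        fg <- cnn_loss_grad(model, tr$X[b_idx, , drop = FALSE],
                            tr$y[b_idx])
        if (!is.finite(fg$loss)) {
          stop(sprintf("divergence error: non-finite loss at epoch %d",
                       epoch), call. = FALSE)
        }
        model$bn_state <- fg$bn_state
        st <- adam_step(model$params, fg$grads, opt, config)
        model$params <- st$params
        opt <- st$opt
        w <- length(b_idx) / n
        ep_loss <- ep_loss + w * fg$loss
        ep_acc <- ep_acc + w * fg$acc
      }
      val_probs <- cnn_forward(model, va$X)$probs
      val_acc <- mean((val_probs[, 2] > val_probs[, 1]) == (va$y == 1L))
      hist_tr_acc[epoch] <- ep_acc
      hist_loss[epoch] <- ep_loss
      hist_val_acc[epoch] <- val_acc
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_epoch <- epoch
        best_params <- model$params
        best_bn <- model$bn_state
      }
      if (epoch - best_epoch >= config$patience) break
    }
  })

  model$params <- best_params
  model$bn_state <- best_bn
  model$trained <- TRUE
  model$config <- config
  model$history <- list(train_accuracy = hist_tr_acc,
                        validation_accuracy = hist_val_acc,
                        train_loss = hist_loss,
                        best_epoch = best_epoch)
  model
}

#' Class probabilities for new spectra
#'
#' Deterministic inference pass: dropout inactive, batch normalization in
#' inference mode (running statistics). Each row of the result sums to 1.
#'
#' @param model a trained `cnn_model`.
#' @param ds a [spectral_dataset()] or intensity matrix on the model grid.
#' @return `n x n_classes` matrix of probabilities, columns named by
#'   `model$class_order`.
#' @export
predict_proba <- function(model, ds) {
  stopifnot(inherits(model, "cnn_model"))
  X <- if (inherits(ds, "spectral_dataset")) ds$intensities else
    as.matrix(ds)
  if (ncol(X) != model$config$input_length) {
    stop(sprintf("shape error: spectra have %d points, model expects %d",
                 ncol(X), model$config$input_length), call. = FALSE)
  }
  probs <- cnn_forward(model, X)$probs
  colnames(probs) <- model$class_order
  probs
}

#' Classify spectra
#'
#' Picks the class of highest probability; exact ties go to
#' `"nonirradiated"`.
#'
#' @inheritParams predict_proba
#' @return factor of predicted labels with levels
#'   `c("nonirradiated", "irradiated")`.
#' @export
classify <- function(model, ds) {
  probs <- predict_proba(model, ds)
  factor(ifelse(probs[, 2] > probs[, 1], "irradiated", "nonirradiated"),
         levels = model$class_order)
}

#' Observed per-layer output shapes
#'
#' Runs an actual forward pass and reports each layer's observed output
#' size, independently of the [conv_output_length()] arithmetic, so the two
#' can be cross-checked.
#'
#' @param model a `cnn_model`.
#' @param X optional intensity matrix (defaults to one zero spectrum).
#' @return named list: per conv block `c(length, channels)`, then
#'   `flatten`, hidden `fc*` widths and `output` width.
#' @export
layer_output_shapes <- function(model, X = NULL) {
  if (is.null(X)) {
    X <- matrix(0, 1, model$config$input_length)
  }
  cnn_forward(model, X)$observed
}
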