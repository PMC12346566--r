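# The hybrid CNN-LSTM-attention eight-class diagnoser: two 1-D convolutions
# (each batch-normalized), max-pooling, a sequence LSTM, softmax attention
# over time feeding an attention-weighted sequence to a second LSTM whose
# final state drives the dense classification head.

#' Diagnoser configuration
#'
#' Defaults mirror the canonical architecture: 52 x 926 MFCC input,
#' Conv1D(64, k5) + BN, Conv1D(128, k3) + BN, MaxPool(2), LSTM(128,
#' sequences), attention (64 tanh scoring units), LSTM(64, final state),
#' Dropout(0.5), Dense(128, ReLU), softmax over 8 classes; Adam (lr 0.001,
#' beta1 0.9, beta2 0.999), L2 0.001, 100 epochs, batch 32, validation split
#' 0.2, early-stopping patience 10.
#'
#' @param input_frames,n_mfcc Input shape (time steps, coefficients).
#' @param conv1_filters,conv1_kernel,conv2_filters,conv2_kernel Conv stack.
#' @param bn_momentum Batch-norm running-statistics momentum.
#' @param lstm1_units,attention_units,lstm2_units,dense_units Recurrent and
#'   dense sizes.
#' @param extra_dense_units Optional second ReLU dense layer (`NULL` = off).
#' @param n_classes Output classes (8).
#' @param dropout,l2 Regularization.
#' @param lr,beta1,beta2 Adam settings.
#' @param clipnorm Global gradient-norm clipping threshold (`Inf` = off).
#' @param epochs,batch_size,val_split,patience Training settings.
#' @param variant `"full"`, `"no_attention"` (uniform time weighting), or
#'   `"cnn_only"` (recurrent layers removed; global average pooling).
#' @return A `diagnoser_config` list.
#' @export
diagnoser_config <- function(input_frames = 926, n_mfcc = 52,
                             conv1_filters = 64, conv1_kernel = 5,
                             conv2_filters = 128, conv2_kernel = 3,
                             bn_momentum = 0.99,
                             lstm1_units = 128, attention_units = 64,
                             lstm2_units = 64, dense_units = 128,
                             extra_dense_units = NULL,
                             n_classes = 8, dropout = 0.5, l2 = 0.001,
                             lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                             clipnorm = 5,
                             epochs = 100, batch_size = 32, val_split = 0.2,
                             patience = 10, variant = "full") {
  variant <- match.arg(variant, c("full", "no_attention", "cnn_only"))
  cfg <- as.list(environment())
  stopifnot(input_frames >= 2, n_mfcc >= 1, dropout >= 0, dropout < 1,
            conv1_kernel %% 2 == 1, conv2_kernel %% 2 == 1)
  structure(cfg, class = "diagnoser_config")
}

.init_diagnoser <- function(config, seed) {
  with_seed(seed, {
    C1 <- config$conv1_filters; C2 <- config$conv2_filters
    params <- list(
      conv1 = list(W = .glorot(config$conv1_kernel * config$n_mfcc, C1),
                   b = numeric(C1)),
      bn1 = list(gamma = rep(1, C1), beta = numeric(C1)),
      conv2 = list(W = .glorot(config$conv2_kernel * C1, C2), b = numeric(C2)),
      bn2 = list(gamma = rep(1, C2), beta = numeric(C2))
    )
    if (config$variant != "cnn_only") {
      params$lstm1 <- lstm_init(C2, config$lstm1_units)
      if (config$variant == "full") {
        params$att <- list(W1 = .glorot(config$lstm1_units, config$attention_units),
                           b1 = numeric(config$attention_units),
                           v = as.numeric(.glorot(config$attention_units, 1)))
      }
      params$lstm2 <- lstm_init(config$lstm1_units, config$lstm2_units)
      head_in <- config$lstm2_units
    } else {
      head_in <- C2
    }
    params$dense1 <- list(W = .glorot(head_in, config$dense_units),
                          b = numeric(config$dense_units))
    prev <- config$dense_units
    if (!is.null(config$extra_dense_units)) {
      params$dense2 <- list(W = .glorot(prev, config$extra_dense_units),
                            b = numeric(config$extra_dense_units))
      prev <- config$extra_dense_units
    }
    params$out <- list(W = .glorot(prev, config$n_classes),
                       b = numeric(config$n_classes))
    state <- list(
      bn1_mean = numeric(C1), bn1_var = rep(1, C1),
      bn2_mean = numeric(C2), bn2_var = rep(1, C2))
    list(params = params, state = state)
  })
}

# Full forward pass over a batch. X: (N, T, F). Returns logits, probs, alpha,
# latent (penultimate activations), layer caches, and updated BN state.
.forward_diagnoser <- function(params, state, X, config, train = FALSE) {
  ca <- list()
  c1 <- conv1d_forward(X, params$conv1$W, params$conv1$b, config$conv1_kernel)
  r1 <- relu_forward(c1$out)
  b1 <- batchnorm_forward(r1$out, params$bn1$gamma, params$bn1$beta,
                          state$bn1_mean, state$bn1_var,
                          momentum = config$bn_momentum, train = train)
  c2 <- conv1d_forward(b1$out, params$conv2$W, params$conv2$b, config$conv2_kernel)
  r2 <- relu_forward(c2$out)
  b2 <- batchnorm_forward(r2$out, params$bn2$gamma, params$bn2$beta,
                          state$bn2_mean, state$bn2_var,
                          momentum = config$bn_momentum, train = train)
  pl <- maxpool_forward(b2$out)
  state$bn1_mean <- b1$running_mean; state$bn1_var <- b1$running_var
  state$bn2_mean <- b2$running_mean; state$bn2_var <- b2$running_var
  ca[c("c1", "r1", "b1", "c2", "r2", "b2", "pl")] <-
    list(c1$cache, r1$cache, b1$cache, c2$cache, r2$cache, b2$cache, pl$cache)

  alpha <- NULL
  if (config$variant == "cnn_only") {
    Tn <- dim(pl$out)[2]
    feat <- matrix(0, dim(pl$out)[1], dim(pl$out)[3])
    for (u in seq_len(dim(pl$out)[3])) feat[, u] <- rowMeans(matrix(pl$out[, , u], dim(pl$out)[1]))
    ca$gap_T <- Tn
    ca$gap_dim <- dim(pl$out)
  } else {
    l1 <- lstm_forward(pl$out, params$lstm1)
    ca$l1 <- l1$cache
    ca$l1_X <- pl$out
    if (config$variant == "full") {
      at <- attention_forward(l1$out, params$att)
      alpha <- at$alpha
      S <- at$out
      ca$at <- at$cache
    } else {
      # uniform attention under the rescaled convention is the identity
      Tn <- dim(l1$out)[2]
      S <- l1$out
      alpha <- matrix(1 / Tn, dim(l1$out)[1], Tn)
    }
    l2_ <- lstm_forward(S, params$lstm2)
    ca$l2 <- l2_$cache
    ca$l2_X <- S
    feat <- l2_$h_final
  }
  dp <- dropout_forward(feat, config$dropout, train)
  d1 <- dense_forward(dp$out, params$dense1$W, params$dense1$b, "relu")
  ca[c("dp", "d1")] <- list(dp$cache, d1$cache)
  h <- d1$out
  if (!is.null(params$dense2)) {
    d2 <- dense_forward(h, params$dense2$W, params$dense2$b, "relu")
    ca$d2 <- d2$cache
    h <- d2$out
  }
  o <- dense_forward(h, params$out$W, params$out$b, "linear")
  ca$o <- o$cache
  list(logits = o$out, probs = softmax_rows(o$out), alpha = alpha,
       latent = h, caches = ca, state = state)
}

.backward_diagnoser <- function(dlogits, fw, params, config) {
  ca <- fw$caches
  g <- list()
  bo <- dense_backward(dlogits, ca$o)
  g$out <- list(W = bo$dW, b = bo$db)
  dh <- bo$dX
  if (!is.null(params$dense2)) {
    b2d <- dense_backward(dh, ca$d2)
    g$dense2 <- list(W = b2d$dW, b = b2d$db)
    dh <- b2d$dX
  }
  b1d <- dense_backward(dh, ca$d1)
  g$dense1 <- list(W = b1d$dW, b = b1d$db)
  dfeat <- dropout_backward(b1d$dX, ca$dp)

  if (config$variant == "cnn_only") {
    # broadcast dfeat/T over the time axis of the pooled map
    d <- ca$gap_dim
    dpool <- array(0, d)
    for (u in seq_len(d[3])) dpool[, , u] <- matrix(dfeat[, u] / ca$gap_T, d[1], d[2])
  } else {
    # final-state-only consumer: route gradient through the last step
    dS_dim <- dim(ca$l2_X)
    dH2 <- array(0, c(dS_dim[1], dS_dim[2], nrow(params$lstm2$Wh)))
    dH2[, dS_dim[2], ] <- dfeat
    bl2 <- lstm_backward(dH2, ca$l2_X, params$lstm2, ca$l2)
    g$lstm2 <- list(Wx = bl2$dWx, Wh = bl2$dWh, b = bl2$db)
    dS <- bl2$dX
    if (config$variant == "full") {
      bat <- attention_backward(dS, ca$at, params$att)
      g$att <- list(W1 = bat$dW1, b1 = bat$db1, v = bat$dv)
      dH1 <- bat$dH
    } else {
      dH1 <- dS
    }
    bl1 <- lstm_backward(dH1, ca$l1_X, params$lstm1, ca$l1)
    g$lstm1 <- list(Wx = bl1$dWx, Wh = bl1$dWh, b = bl1$db)
    dpool <- bl1$dX
  }
  dmp <- maxpool_backward(dpool, ca$pl)
  bb2 <- batchnorm_backward(dmp, ca$b2)
  g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
  dr2 <- relu_backward(bb2$dX, ca$r2)
  bc2 <- conv1d_backward(dr2, ca$c2)
  g$conv2 <- list(W = bc2$dW, b = bc2$db)
  bb1 <- batchnorm_backward(bc2$dX, ca$b1)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  dr1 <- relu_backward(bb1$dX, ca$r1)
  bc1 <- conv1d_backward(dr1, ca$c1)
  g$conv1 <- list(W = bc1$dW, b = bc1$db)
  g[names(params)]                             # order like params
}

# weight matrices subject to L2 decay (biases, BN affine excluded)
.l2_keys <- list(c("conv1", "W"), c("conv2", "W"), c("lstm1", "Wx"),
                 c("lstm1", "Wh"), c("att", "W1"), c("att", "v"),
                 c("lstm2", "Wx"), c("lstm2", "Wh"), c("dense1", "W"),
                 c("dense2", "W"), c("out", "W"))

.l2_penalty <- function(params, l2) {
  s <- 0
  for (k in .l2_keys) {
    p <- params[[k[1]]][[k[2]]]
    if (!is.null(p)) s <- s + sum(p^2)
  }
  l2 * s
}

.add_l2_grads <- function(grads, params, l2) {
  for (k in .l2_keys) {
    p <- params[[k[1]]][[k[2]]]
    if (!is.null(p) && !is.null(grads[[k[1]]][[k[2]]])) {
      grads[[k[1]]][[k[2]]] <- grads[[k[1]]][[k[2]]] + 2 * l2 * p
    }
  }
  grads
}

#' Early-stopping bookkeeping over a validation-loss sequence
#'
#' Strict-improvement rule: training stops once the validation loss has
#' failed to beat the best value seen for `patience` consecutive epochs; the
#' kept weights are those of the best epoch.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return List with `stop_epoch` (last epoch run) and `best_epoch`.
#' @export
early_stop_schedule <- function(val_losses, patience = 10) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

# features: list of mfcc_matrix (or F x T matrices) -> (N, T, F) array
.stack_features <- function(features, config) {
  mats <- lapply(features, function(m) if (inherits(m, "mfcc_matrix")) m$values else m)
  bad <- which(vapply(mats, function(v) nrow(v) != config$n_mfcc ||
                        ncol(v) != config$input_frames, TRUE))
  if (length(bad) > 0) {
    stop("feature ", bad[1], " has shape ", nrow(mats[[bad[1]]]), "x",
         ncol(mats[[bad[1]]]), "; expected ", config$n_mfcc, "x",
         config$input_frames)
  }
  X <- array(0, c(length(mats), config$input_frames, config$n_mfcc))
  for (n in seq_along(mats)) X[n, , ] <- t(mats[[n]])
  X
}

# Recompute BN running statistics as population statistics of the training
# set under the final weights, so evaluation-mode normalization matches the
# trained data distribution.
.recalibrate_bn <- function(params, state, X, config, max_n = 512) {
  if (dim(X)[1] > max_n) X <- X[seq_len(max_n), , , drop = FALSE]
  c1 <- conv1d_forward(X, params$conv1$W, params$conv1$b, config$conv1_kernel)
  a1 <- pmax(c1$out, 0)
  m1 <- matrix(a1, prod(dim(a1)[1:2]), dim(a1)[3])
  state$bn1_mean <- colMeans(m1)
  state$bn1_var <- colMeans(sweep(m1, 2, state$bn1_mean)^2)
  b1 <- batchnorm_forward(a1, params$bn1$gamma, params$bn1$beta,
                          state$bn1_mean, state$bn1_var, train = FALSE)
  c2 <- conv1d_forward(b1$out, params$conv2$W, params$conv2$b, config$conv2_kernel)
  a2 <- pmax(c2$out, 0)
  m2 <- matrix(a2, prod(dim(a2)[1:2]), dim(a2)[3])
  state$bn2_mean <- colMeans(m2)
  state$bn2_var <- colMeans(sweep(m2, 2, state$bn2_mean)^2)
  state
}

#' Train the hybrid diagnoser
#'
#' Minimizes categorical cross-entropy with L2 weight decay using Adam on
#' shuffled mini-batches; a stratified validation split drives early stopping
#' (strict improvement, `patience` epochs), and the weights from the
#' best-validation-loss epoch are kept. Batch-norm running statistics are
#' recalibrated on the training set after weight restoration.
#'
#' @param features List of [mfcc_matrix()] objects (each `n_mfcc` x
#'   `input_frames`).
#' @param labels Character vector of diagnosis classes, one per feature.
#' @param config A [diagnoser_config()].
#' @param seed Integer seed controlling weight init, shuffling, dropout, and
#'   the validation split.
#' @param verbose Print per-epoch losses.
#' @return A `trained_diagnoser`: list with `params`, `state`, `config`,
#'   `codec`, `history` (epoch/loss/val_loss), `best_epoch`.
#' @export
train_diagnoser <- function(features, labels, config = diagnoser_config(),
                            seed = 0, verbose = FALSE) {
  if (length(unique(labels)) < 2) {
    stop("train_diagnoser: need at least 2 classes, got ",
         length(unique(labels)))
  }
  enc <- encode_labels(labels)
  X <- .stack_features(features, config)
  N <- dim(X)[1]

  with_seed(seed * 10007L + 17L, {
    # stratified validation split (first-appearance class order keeps the
    # split independent of the collation locale)
    val_idx <- unlist(lapply(split(seq_len(N), factor(labels, levels = unique(labels))),
                             function(ix) {
      k <- floor(length(ix) * config$val_split)
      if (k < 1 || length(ix) - k < 1) return(integer(0))
      sample(ix, k)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(N), val_idx)

    init <- .init_diagnoser(config, seed)
    params <- init$params
    state <- init$state
    opt <- adam_init(params)
    Y <- enc$onehot
    best <- list(loss = Inf, epoch = 0L, params = params, state = state)
    wait <- 0L
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_loss = numeric(0))

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        fw <- .forward_diagnoser(params, state, X[bi, , , drop = FALSE],
                                 config, train = TRUE)
        state <- fw$state
        sx <- softmax_xent(fw$logits, Y[bi, , drop = FALSE])
        grads <- .backward_diagnoser(sx$dlogits, fw, params, config)
        grads <- .add_l2_grads(grads, params, config$l2)
        grads <- clip_global_norm(grads, config$clipnorm)
        up <- adam_update(params, grads, opt, lr = config$lr,
                          beta1 = config$beta1, beta2 = config$beta2)
        params <- up$params
        opt <- up$state
        ep_loss <- ep_loss + sx$loss + .l2_penalty(params, config$l2)
        nb <- nb + 1L
      }
      # validation in evaluation mode
      if (length(val_idx) > 0) {
        fv <- .forward_diagnoser(params, state, X[val_idx, , , drop = FALSE],
                                 config, train = FALSE)
        vl <- softmax_xent(fv$logits, Y[val_idx, , drop = FALSE])$loss
      } else {
        vl <- ep_loss / nb
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss / nb,
                                           val_loss = vl))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val_loss %.4f", epoch,
                        ep_loss / nb, vl))
      }
      if (vl < best$loss) {
        best <- list(loss = vl, epoch = epoch, params = params, state = state)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    state <- .recalibrate_bn(best$params, best$state,
                             X[train_idx, , , drop = FALSE], config)
    structure(list(params = best$params, state = state, config = config,
                   codec = enc$codec, history = history,
                   best_epoch = best$epoch),
              class = "trained_diagnoser")
  })
}

#' @export
print.trained_diagnoser <- function(x, ...) {
  cat(sprintf("<trained_diagnoser> variant=%s, %d epochs run, best epoch %d\n",
              x$config$variant, nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Predict diagnosis for one or more MFCC matrices
#'
#' @param model A `trained_diagnoser`.
#' @param m An [mfcc_matrix()] (or plain matrix) shaped `n_mfcc` x
#'   `input_frames`, or a list of them.
#' @return For a single input: list with `label`, `probs` (named 8-vector
#'   summing to 1), `alpha` (attention weights over pooled time steps), and
#'   `latent` (penultimate activations). For a list input: list with `labels`
#'   and `probs` matrix.
#' @export
predict_diagnoser <- function(model, m) {
  single <- !is.list(m) || inherits(m, "mfcc_matrix")
  feats <- if (single) list(m) else m
  X <- .stack_features(feats, model$config)
  fw <- .forward_diagnoser(model$params, model$state, X, model$config,
                           train = FALSE)
  labels <- decode_labels(model$codec, fw$probs)
  if (single) {
    list(label = labels[1],
         probs = stats::setNames(fw$probs[1, ], model$codec$classes),
         alpha = if (!is.null(fw$alpha)) fw$alpha[1, ],
         latent = fw$latent[1, ])
  } else {
    list(labels = labels,
         probs = `colnames<-`(fw$probs, model$codec$classes),
         alpha = fw$alpha, latent = fw$latent)
  }
}

#' Build an untrained diagnoser (initialized weights)
#'
#' @param config A [diagnoser_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `trained_diagnoser`-shaped object with freshly initialized
#'   weights (no history).
#' @export
build_diagnoser <- function(config = diagnoser_config(), seed = 0) {
  init <- .init_diagnoser(config, seed)
  structure(list(params = init$params, state = init$state, config = config,
                 codec = label_codec(), history = NULL, best_epoch = NA_integer_),
            class = "trained_diagnoser")
}
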