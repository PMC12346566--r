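# Neural-network primitives for the hybrid diagnoser, written against base R
# matrix algebra. Every layer exposes a forward pass returning (output, cache)
# and a backward pass returning (d_input, parameter gradients); the test suite
# checks all of them against independent transcriptions and central-difference
# numerical gradients.
#
# Batched tensors use dim (N, T, F): sample, time step, feature/channel.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(n_in, n_out) {
  l <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -l, l), n_in, n_out)
}

# ---- Conv1D (same padding, time axis) --------------------------------------

# W: (K*F) x C_out with row order (k-1)*F + f; b: length C_out
conv1d_forward <- function(X, W, b, kernel) {
  d <- dim(X); N <- d[1]; Tn <- d[2]; Fn <- d[3]
  stopifnot(nrow(W) == kernel * Fn, kernel %% 2 == 1)
  pad <- (kernel - 1L) %/% 2L
  Xp <- array(0, c(N, Tn + 2L * pad, Fn))
  Xp[, pad + seq_len(Tn), ] <- X
  cols <- matrix(0, N * Tn, kernel * Fn)
  for (k in seq_len(kernel)) {
    cols[, (k - 1L) * Fn + seq_len(Fn)] <- matrix(Xp[, k:(k + Tn - 1L), ], N * Tn, Fn)
  }
  Y <- cols %*% W
  Y <- sweep(Y, 2, b, `+`)
  list(out = array(Y, c(N, Tn, ncol(W))), cache = list(cols = cols, dims = d,
       kernel = kernel, W = W))
}

conv1d_backward <- function(dY, cache) {
  d <- cache$dims; N <- d[1]; Tn <- d[2]; Fn <- d[3]
  kernel <- cache$kernel
  pad <- (kernel - 1L) %/% 2L
  dY_mat <- matrix(dY, N * Tn, dim(dY)[3])
  dW <- crossprod(cache$cols, dY_mat)
  db <- colSums(dY_mat)
  dcols <- tcrossprod(dY_mat, cache$W)
  dXp <- array(0, c(N, Tn + 2L * pad, Fn))
  for (k in seq_len(kernel)) {
    dXp[, k:(k + Tn - 1L), ] <- dXp[, k:(k + Tn - 1L), ] +
      array(dcols[, (k - 1L) * Fn + seq_len(Fn)], c(N, Tn, Fn))
  }
  list(dX = dXp[, pad + seq_len(Tn), , drop = FALSE], dW = dW, db = db)
}

# ---- ReLU ------------------------------------------------------------------

relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_backward <- function(dY, cache) dY * cache

# ---- Batch normalization (per channel over samples and time) ---------------

batchnorm_forward <- function(X, gamma, beta, running_mean, running_var,
                              momentum = 0.99, eps = 1e-3, train = TRUE) {
  d <- dim(X); N <- d[1]; Tn <- d[2]; Cn <- d[3]
  Xm <- matrix(X, N * Tn, Cn)
  if (train) {
    mu <- colMeans(Xm)
    v <- colMeans(sweep(Xm, 2, mu)^2)          # biased, as in batch norm
    running_mean <- momentum * running_mean + (1 - momentum) * mu
    running_var <- momentum * running_var + (1 - momentum) * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, invstd, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = array(Y, d),
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    train = train),
       running_mean = running_mean, running_var = running_var)
}

batchnorm_backward <- function(dY, cache) {
  d <- cache$d
  m <- d[1] * d[2]
  dYm <- matrix(dY, m, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, cache$gamma, `*`)
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dXm <- sweep(dxhat, 2, s1 / m) - sweep(cache$xhat, 2, s2 / m, `*`)
    dXm <- sweep(dXm, 2, cache$invstd, `*`)
  } else {
    dXm <- sweep(dxhat, 2, cache$invstd, `*`)
  }
  list(dX = array(dXm, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- MaxPooling1D (window 2, stride 2) -------------------------------------

maxpool_forward <- function(X) {
  d <- dim(X); To <- d[2] %/% 2L
  A <- X[, seq.int(1L, 2L * To, 2L), , drop = FALSE]
  B <- X[, seq.int(2L, 2L * To, 2L), , drop = FALSE]
  mask <- A >= B                               # ties keep the earlier frame
  list(out = pmax(A, B), cache = list(mask = mask, d = d, To = To))
}

maxpool_backward <- function(dY, cache) {
  d <- cache$d; To <- cache$To
  dX <- array(0, d)
  dX[, seq.int(1L, 2L * To, 2L), ] <- dY * cache$mask
  dX[, seq.int(2L, 2L * To, 2L), ] <- dY * !cache$mask
  dX
}

# ---- LSTM ------------------------------------------------------------------
# Gate block order in the fused weight matrices: forget, input, candidate,
# output -- mirroring the forget/input/candidate/output reading of the cell:
#   f = sigmoid(.), i = sigmoid(.), g = tanh(.), o = sigmoid(.)
#   C = f*C_prev + i*g ;  h = o*tanh(C)

lstm_init <- function(input_dim, units) {
  b <- numeric(4 * units)
  b[seq_len(units)] <- 1                       # forget-gate bias at 1
  list(Wx = .glorot(input_dim, 4 * units),
       Wh = .glorot(units, 4 * units),
       b = b)
}

#' One LSTM cell step
#'
#' The canonical gated recurrence: forget, input, and output gates squash
#' affine maps of `[h_prev, x_t]` through the logistic function, the candidate
#' through tanh; the cell state is `f*C_prev + i*g` and the hidden state
#' `o*tanh(C)`.
#'
#' @param x_t Input vector at this step.
#' @param h_prev,C_prev Previous hidden and cell state vectors (length
#'   `units`).
#' @param weights List with `Wx` (`length(x_t)` x `4*units`), `Wh` (`units` x
#'   `4*units`), `b` (length `4*units`); gate block order forget, input,
#'   candidate, output.
#' @return List with `h` and `C`.
#' @export
lstm_cell_step <- function(x_t, h_prev, C_prev, weights) {
  U <- length(h_prev)
  if (length(C_prev) != U) stop("lstm_cell_step: h_prev/C_prev length mismatch")
  if (nrow(weights$Wx) != length(x_t) || ncol(weights$Wx) != 4 * U ||
      nrow(weights$Wh) != U || length(weights$b) != 4 * U) {
    stop("lstm_cell_step: weight dimensions inconsistent with state size")
  }
  z <- as.numeric(x_t %*% weights$Wx + h_prev %*% weights$Wh) + weights$b
  f <- .sigmoid(z[seq_len(U)])
  i <- .sigmoid(z[U + seq_len(U)])
  g <- tanh(z[2 * U + seq_len(U)])
  o <- .sigmoid(z[3 * U + seq_len(U)])
  C <- f * C_prev + i * g
  list(h = o * tanh(C), C = C)
}

lstm_forward <- function(X, params) {
  d <- dim(X); N <- d[1]; Tn <- d[2]
  U <- nrow(params$Wh)
  H <- array(0, c(N, Tn, U))
  h <- matrix(0, N, U); C <- matrix(0, N, U)
  cache <- vector("list", Tn)
  iU <- seq_len(U)
  for (t in seq_len(Tn)) {
    x_t <- matrix(X[, t, ], N)
    z <- x_t %*% params$Wx + h %*% params$Wh
    z <- sweep(z, 2, params$b, `+`)
    f <- .sigmoid(z[, iU, drop = FALSE])
    i <- .sigmoid(z[, U + iU, drop = FALSE])
    g <- tanh(z[, 2 * U + iU, drop = FALSE])
    o <- .sigmoid(z[, 3 * U + iU, drop = FALSE])
    C_new <- f * C + i * g
    tC <- tanh(C_new)
    cache[[t]] <- list(x = x_t, h_prev = h, C_prev = C, f = f, i = i, g = g,
                       o = o, tC = tC)
    C <- C_new
    h <- o * tC
    H[, t, ] <- h
  }
  list(out = H, cache = cache, h_final = h)
}

# dH_seq: gradient w.r.t. every hidden state (N, T, U); pass zeros except the
# last step for a final-state-only consumer.
lstm_backward <- function(dH_seq, X, params, cache) {
  d <- dim(X); N <- d[1]; Tn <- d[2]
  U <- nrow(params$Wh)
  dWx <- matrix(0, nrow(params$Wx), 4 * U)
  dWh <- matrix(0, U, 4 * U)
  db <- numeric(4 * U)
  dX <- array(0, d)
  dh_next <- matrix(0, N, U)
  dC_next <- matrix(0, N, U)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- matrix(dH_seq[, t, ], N) + dh_next
    dC <- dh * cc$o * (1 - cc$tC^2) + dC_next
    df <- dC * cc$C_prev
    di <- dC * cc$g
    dg <- dC * cc$i
    do_ <- dh * cc$tC
    dC_next <- dC * cc$f
    dz <- cbind(df * cc$f * (1 - cc$f),
                di * cc$i * (1 - cc$i),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- tcrossprod(dz, params$Wx)
    dh_next <- tcrossprod(dz, params$Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- Attention -------------------------------------------------------------
# Two-stage scoring: 64 tanh units then a linear score per step;
# alpha = softmax over time; the attention-weighted sequence {alpha_t h_t}
# is what the second LSTM consumes.

attention_forward <- function(H, params) {
  d <- dim(H); N <- d[1]; Tn <- d[2]; U <- d[3]
  Hm <- matrix(H, N * Tn, U)
  P <- sweep(Hm %*% params$W1, 2, params$b1, `+`)
  Q <- tanh(P)
  e <- matrix(Q %*% params$v, N, Tn)
  e_shift <- e - apply(e, 1, max)
  ex <- exp(e_shift)
  alpha <- ex / rowSums(ex)
  # The second LSTM consumes the attention-weighted sequence {alpha_t h_t},
  # rescaled by T so that uniform attention preserves the sequence's scale
  # (softmax weighting redistributes mass instead of shrinking it by 1/T).
  S <- H * array(rep(Tn * alpha, times = U), c(N, Tn, U))
  list(out = S, alpha = alpha,
       cache = list(H = H, Hm = Hm, Q = Q, alpha = alpha, d = d))
}

attention_backward <- function(dS, cache, params) {
  d <- cache$d; N <- d[1]; Tn <- d[2]; U <- d[3]
  alpha <- cache$alpha
  H <- cache$H
  dalpha <- matrix(0, N, Tn)
  for (u in seq_len(U)) {
    dalpha <- dalpha + Tn * matrix(dS[, , u], N) * matrix(H[, , u], N)
  }
  dH <- dS * array(rep(Tn * alpha, times = U), c(N, Tn, U))
  # softmax backward per row
  de <- alpha * (dalpha - rowSums(alpha * dalpha))
  de_vec <- as.vector(de)                      # (N*Tn), row-major consistent with Hm
  dQ <- outer(de_vec, params$v)
  dv <- as.numeric(crossprod(cache$Q, de_vec))
  dP <- dQ * (1 - cache$Q^2)
  dW1 <- crossprod(cache$Hm, dP)
  db1 <- colSums(dP)
  dH <- dH + array(tcrossprod(dP, params$W1), d)
  list(dH = dH, dW1 = dW1, db1 = db1, dv = dv)
}

#' Attention pooling over a hidden-state sequence
#'
#' Scores each step through a tanh hidden layer and a linear read-out,
#' softmax-normalizes the scores over time, and returns both the weights and
#' the context vector (the alpha-weighted sum of hidden states).
#'
#' @param H Numeric matrix, `T` x `U` (one sequence).
#' @param W_e Scoring weights, `U` x `A`.
#' @param b_e Scoring bias, length `A`.
#' @param v Read-out vector, length `A`.
#' @return List with `alpha` (length `T`, nonnegative, summing to 1) and `c`
#'   (context vector, length `U`).
#' @export
attention_pool <- function(H, W_e, b_e, v) {
  if (nrow(H) == 0) stop("attention_pool: empty sequence")
  e <- as.numeric(tanh(sweep(H %*% W_e, 2, b_e, `+`)) %*% v)
  ex <- exp(e - max(e))
  alpha <- ex / sum(ex)
  list(alpha = alpha, c = as.numeric(alpha %*% H))
}

# ---- Dense / dropout / softmax --------------------------------------------

dense_forward <- function(X, W, b, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  Z <- sweep(X %*% W, 2, b, `+`)
  out <- if (activation == "relu") pmax(Z, 0) else Z
  list(out = out, cache = list(X = X, W = W, mask = if (activation == "relu") Z > 0))
}

dense_backward <- function(dY, cache) {
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  list(dX = tcrossprod(dY, cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

dropout_forward <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, cache = NULL))
  mask <- (matrix(stats::runif(length(X)), nrow(X)) >= p) / (1 - p)
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

softmax_rows <- function(Z) {
  ex <- exp(Z - apply(Z, 1, max))
  ex / rowSums(ex)
}

# cross-entropy on one-hot targets; returns mean loss and dlogits
softmax_xent <- function(logits, Y_onehot) {
  P <- softmax_rows(logits)
  loss <- -mean(rowSums(Y_onehot * log(pmax(P, 1e-12))))
  list(loss = loss, probs = P, dlogits = (P - Y_onehot) / nrow(logits))
}

# Rescale an entire gradient structure so its global L2 norm is at most
# `max_norm` -- the usual stabilizer for recurrent nets.
clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(unlist(rapply(grads, function(g) sum(g^2), how = "list"))))
  if (total <= max_norm) return(grads)
  rapply(grads, function(g) g * (max_norm / total), how = "replace")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

# grads mirrors params structure; returns list(params, state)
adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(walk, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"), v = lapply(out, `[[`, "v"),
                    t = state$t))
}
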