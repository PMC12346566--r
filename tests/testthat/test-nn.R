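test_that("conv1d forward matches a brute-force sliding-window oracle", {
  set.seed(11)
  Tn <- 9; Fn <- 4; K <- 5; Cout <- 3; N <- 2
  X <- array(rnorm(N * Tn * Fn), c(N, Tn, Fn))
  W <- matrix(rnorm(K * Fn * Cout), K * Fn, Cout)
  b <- rnorm(Cout)
  out <- conv1d_forward(X, W, b, K)$out
  for (n in 1:N) {
    expect_equal(matrix(out[n, , ], Tn), oracle_conv1d(matrix(X[n, , ], Tn), W, b, K),
                 tolerance = 1e-6)
  }
})

test_that("batch normalization maps a constant input to zero (gamma 1, beta 0)", {
  X <- array(3.7, c(2, 5, 4))
  bn <- batchnorm_forward(X, gamma = rep(1, 4), beta = rep(0, 4),
                          running_mean = rep(0, 4), running_var = rep(1, 4),
                          train = TRUE)
  expect_lt(max(abs(bn$out)), 1e-6)
  # and standardizes a random batch per channel
  set.seed(2)
  Y <- array(rnorm(2 * 50 * 3, mean = 5, sd = 2), c(2, 50, 3))
  bn2 <- batchnorm_forward(Y, rep(1, 3), rep(0, 3), rep(0, 3), rep(1, 3))
  Ym <- matrix(bn2$out, 100, 3)
  expect_equal(colMeans(Ym), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(Ym, 2, function(v) mean(v^2)), rep(1, 3), tolerance = 1e-2)
})

test_that("max pooling takes pairwise maxima with window 2", {
  set.seed(3)
  X <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
  out <- maxpool_forward(X)$out
  for (n in 1:2) for (t in 1:4) for (c in 1:3) {
    expect_equal(out[n, t, c], max(X[n, 2 * t - 1, c], X[n, 2 * t, c]))
  }
})

test_that("lstm_cell_step reproduces the gated recurrence analytically", {
  U <- 3
  zero_w <- list(Wx = matrix(0, 2, 4 * U), Wh = matrix(0, U, 4 * U),
                 b = numeric(4 * U))
  cp <- c(0.4, -1, 2)
  st <- lstm_cell_step(c(1, -1), numeric(U), cp, zero_w)
  # all-zero weights: every gate sigmoid(0)=0.5, candidate tanh(0)=0
  expect_equal(st$C, 0.5 * cp)
  expect_equal(st$h, 0.5 * tanh(0.5 * cp))

  # zero cell and zero candidate weights annihilate the state
  st0 <- lstm_cell_step(c(1, -1), numeric(U), numeric(U), zero_w)
  expect_equal(st0$C, rep(0, U))
  expect_equal(st0$h, rep(0, U))

  # random small weights vs an independent transcription
  set.seed(5)
  w <- list(Wx = matrix(rnorm(2 * 4 * U, sd = 0.3), 2),
            Wh = matrix(rnorm(U * 4 * U, sd = 0.3), U),
            b = rnorm(4 * U, sd = 0.1))
  h <- rnorm(U); C <- rnorm(U); x <- rnorm(2)
  got <- lstm_cell_step(x, h, C, w)
  want <- oracle_lstm_cell(x, h, C, w$Wx, w$Wh, w$b)
  expect_equal(got$h, want$h, tolerance = 1e-6)
  expect_equal(got$C, want$C, tolerance = 1e-6)

  expect_error(lstm_cell_step(c(1, 2, 3), h, C, w), "dimensions")
})

test_that("batched lstm_forward agrees with stepwise lstm_cell_step", {
  set.seed(6)
  U <- 4; D <- 3; Tn <- 6
  params <- lstm_init(D, U)
  X <- array(rnorm(1 * Tn * D), c(1, Tn, D))
  fw <- lstm_forward(X, params)
  h <- numeric(U); C <- numeric(U)
  for (t in 1:Tn) {
    st <- lstm_cell_step(X[1, t, ], h, C, params)
    h <- st$h; C <- st$C
    expect_equal(as.numeric(fw$out[1, t, ]), h, tolerance = 1e-10)
  }
})

test_that("attention_pool normalizes and reduces correctly", {
  U <- 3; A <- 2
  W <- matrix(0, U, A); b <- c(0, 0); v <- c(1, 1)
  H <- matrix(rnorm(5 * U), 5, U)
  ap <- attention_pool(H, W, b, v)          # all scores equal -> uniform
  expect_equal(ap$alpha, rep(1 / 5, 5))
  expect_equal(ap$c, colMeans(H))

  one <- attention_pool(H[1, , drop = FALSE], W, b, v)
  expect_equal(one$alpha, 1)
  expect_equal(one$c, H[1, ])

  # hand-set scores e = (0, log 3) -> alpha = (0.25, 0.75)
  H2 <- matrix(c(0, 20), 2, 1)              # tanh saturates to (0, 1)
  ap2 <- attention_pool(H2, W_e = matrix(1), b_e = 0, v = log(3))
  expect_equal(ap2$alpha, c(0.25, 0.75), tolerance = 1e-8)
  expect_error(attention_pool(H2[0, , drop = FALSE], matrix(1), 0, 1), "empty")
})

test_that("every parameter gradient matches central differences", {
  cfg <- diagnoser_config(input_frames = 8, n_mfcc = 3, conv1_filters = 4,
                          conv1_kernel = 3, conv2_filters = 6, conv2_kernel = 3,
                          lstm1_units = 5, attention_units = 3, lstm2_units = 4,
                          dense_units = 7, n_classes = 3, dropout = 0, l2 = 0)
  init <- lungrx:::.init_diagnoser(cfg, 1)
  params <- init$params; state <- init$state
  set.seed(12)
  X <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
  Y <- matrix(0, 2, 3); Y[cbind(1:2, c(2, 3))] <- 1
  lossfun <- function(p) {
    fw <- lungrx:::.forward_diagnoser(p, state, X, cfg, train = TRUE)
    lungrx:::softmax_xent(fw$logits, Y)$loss
  }
  fw <- lungrx:::.forward_diagnoser(params, state, X, cfg, train = TRUE)
  grads <- lungrx:::.backward_diagnoser(
    lungrx:::softmax_xent(fw$logits, Y)$dlogits, fw, params, cfg)
  eps <- 1e-4
  for (blk in names(params)) for (nm in names(params[[blk]])) {
    p <- params[[blk]][[nm]]
    idx <- sample(length(p), min(4, length(p)))
    for (i in idx) {
      pp <- params; pp[[blk]][[nm]][i] <- p[i] + eps
      pm <- params; pm[[blk]][[nm]][i] <- p[i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(grads[[blk]][[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", blk, nm, i))
    }
  }
})

test_that("adam takes the textbook first step and clipping caps the norm", {
  params <- list(w = c(1, 2))
  grads <- list(w = c(0.5, -0.5))
  st <- adam_init(params)
  up <- adam_update(params, grads, st, lr = 0.1)
  # first Adam step moves each coordinate by ~lr * sign(g)
  expect_equal(up$params$w, c(1, 2) - 0.1 * sign(c(0.5, -0.5)), tolerance = 1e-6)

  g <- list(a = c(3, 4), b = matrix(0, 1, 1))
  cg <- clip_global_norm(g, 1)
  expect_equal(sqrt(sum(unlist(cg)^2)), 1, tolerance = 1e-12)
  expect_identical(clip_global_norm(g, 100), g)
})
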