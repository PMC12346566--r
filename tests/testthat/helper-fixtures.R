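# Shared helpers: small deterministic fixtures and independent oracles used
# across test files. Everything here is cheap; expensive trained models are
# built (and cached per session) via the lazy accessors at the bottom.

quick_recipes <- function(duration = 2) default_recipes(duration = duration)

tone_clip <- function(freq = 440, duration = 2, sr = 22050) {
  audio_clip(sin(2 * pi * freq * seq_len(duration * sr) / sr), sr)
}

# dominant FFT frequency of a waveform (independent spectral oracle)
fft_peak_hz <- function(x, sr) {
  P <- Mod(stats::fft(x))^2
  half <- seq_len(floor(length(x) / 2))
  (which.max(P[half]) - 1) * sr / length(x)
}

# independent transcription of the LSTM cell recurrence (gates on [h, x])
oracle_lstm_cell <- function(x, h, C, Wx, Wh, b) {
  U <- length(h)
  z <- as.numeric(x %*% Wx) + as.numeric(h %*% Wh) + b
  sg <- function(v) 1 / (1 + exp(-v))
  f <- sg(z[1:U]); i <- sg(z[U + 1:U]); g <- tanh(z[2 * U + 1:U])
  o <- sg(z[3 * U + 1:U])
  Cn <- f * C + i * g
  list(h = o * tanh(Cn), C = Cn)
}

# brute-force 1-D same-padded convolution (independent of im2col)
oracle_conv1d <- function(x_tf, W, b, kernel) {
  Tn <- nrow(x_tf); Fn <- ncol(x_tf); Cout <- ncol(W)
  pad <- (kernel - 1) %/% 2
  xp <- rbind(matrix(0, pad, Fn), x_tf, matrix(0, pad, Fn))
  out <- matrix(0, Tn, Cout)
  for (t in seq_len(Tn)) for (co in seq_len(Cout)) {
    acc <- b[co]
    for (k in seq_len(kernel)) for (f in seq_len(Fn)) {
      acc <- acc + xp[t + k - 1, f] * W[(k - 1) * Fn + f, co]
    }
    out[t, co] <- acc
  }
  out
}

# closed-form Wilson interval (independent transcription)
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}

# exhaustive-count kappa for two label vectors (no marginal algebra shared
# with the implementation)
oracle_kappa <- function(a, b) {
  lev <- union(a, b)
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(a == l) / n) * (sum(b == l) / n)
  (po - pe) / (1 - pe)
}

# reduced-scale training protocol shared by the diagnoser tests: an
# 8-class balanced fixture (25 clips x 5 subjects per class, 3 s clips),
# 26 MFCCs over 128 frames, standardized on the training subjects.
reduced_config <- function(variant = "full") {
  diagnoser_config(input_frames = 128, n_mfcc = 26, conv1_filters = 24,
                   conv2_filters = 48, lstm1_units = 48, attention_units = 24,
                   lstm2_units = 24, dense_units = 48, epochs = 15,
                   batch_size = 8, dropout = 0.2, lr = 0.005,
                   variant = variant)
}

.cache <- new.env(parent = emptyenv())

# the reduced-scale fixture benchmark: features, labels, subjects, and the
# train/test subject split (subject s05 of each class held out)
reduced_benchmark <- function() {
  if (!is.null(.cache$bench)) return(.cache$bench)
  counts <- stats::setNames(rep(25L, 8), diagnosis_classes())
  set <- synth_cohort(counts, subjects_per_class = 5, seed = 0,
                      recipes = quick_recipes(duration = 3))
  raw <- lapply(set$clips, function(cl) {
    normalize_length(extract_mfcc(cl, n_mfcc = 26), 128)
  })
  labs <- vapply(set$clips, `[[`, "", "label")
  subs <- vapply(set$clips, `[[`, "", "subject_id")
  test_i <- grepl("_s05$", subs)
  scaler <- fit_mfcc_scaler(raw[!test_i])
  feats <- lapply(raw, scale_mfcc, scaler = scaler)
  .cache$bench <- list(set = set, feats = feats, labels = labs,
                       subjects = subs, test = test_i, scaler = scaler)
  .cache$bench
}

# one trained full-variant model on the reduced benchmark (seed 0), reused
# by the diagnoser, explainability, and acceptance tests
trained_reduced_model <- function() {
  if (!is.null(.cache$model)) return(.cache$model)
  b <- reduced_benchmark()
  .cache$model <- train_diagnoser(b$feats[!b$test], b$labels[!b$test],
                                  reduced_config(), seed = 0)
  .cache$model
}

# small labelled prescribing dataset + split, reused across prescribe /
# explain tests
small_rx_split <- function(n = 600, seed = 1) {
  key <- paste0("rx", n, "_", seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  ds <- generate_prescribing_dataset(cohort_config(n = n), seed = seed)
  sp <- split_prescribing_dataset(ds, seed = seed)
  .cache[[key]] <- list(data = ds, train = sp$train, test = sp$test)
  .cache[[key]]
}
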