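test_that("load_audio is identity on silence and resamples by the rate ratio", {
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(numeric(22050), 22050, f)
  clip <- load_audio(f)
  expect_length(clip$samples, 22050)
  expect_true(all(clip$samples == 0))
  expect_equal(clip$sample_rate, 22050)

  # oracle: output length = input length * target / source
  write_wav(numeric(22050), 44100, f)
  half <- load_audio(f, target_rate = 22050)
  expect_length(half$samples, 22050 * 22050 / 44100)

  # the pipeline's default loading rate
  expect_equal(eval(formals(load_audio)$target_rate), 22050)
})

test_that("multichannel input is average-downmixed before resampling", {
  f <- withr::local_tempfile(fileext = ".wav")
  left <- rep(0.5, 4000); right <- rep(-0.25, 4000)
  write_wav(cbind(left, right), 8000, f)
  clip <- load_audio(f, target_rate = 8000)
  expect_equal(mean(clip$samples[100:3900]), 0.125, tolerance = 1e-3)
})

test_that("extract_mfcc yields the contracted shape and frame count", {
  clip <- tone_clip(300, duration = 2)
  m <- extract_mfcc(clip, n_mfcc = 52)
  expect_s3_class(m, "mfcc_matrix")
  expect_equal(m$n_mfcc, 52)
  # independent frame-count oracle for centered frames
  expect_equal(m$n_frames, 1 + floor(length(clip$samples) / 512))

  # 10 s at the default rate and hop
  clip10 <- audio_clip(stats::rnorm(10 * 22050), 22050)
  expect_equal(extract_mfcc(clip10, 52)$n_frames, 1 + floor(220500 / 512))
})

test_that("a stationary clip gives identical interior MFCC columns", {
  clip <- audio_clip(rep(0.3, 22050), 22050)
  m <- extract_mfcc(clip, n_mfcc = 13)
  inner <- m$values[, 5:(m$n_frames - 4)]       # edge frames touch padding
  expect_lt(max(apply(inner, 1, stats::sd)), 1e-8)
})

test_that("extract_mfcc rejects degenerate inputs", {
  expect_error(extract_mfcc(audio_clip(numeric(0), 22050)), "empty")
  expect_error(extract_mfcc(tone_clip(), n_mfcc = 100, n_mels = 64),
               "exceeds filterbank")
})

test_that("normalize_length pads with zeros, truncates to the prefix, and is
           identity at target", {
  m <- mfcc_matrix(matrix(rnorm(52 * 100), 52))
  p <- normalize_length(m, 926)
  expect_equal(dim(p$values), c(52, 926))
  expect_true(all(p$values[, 101:926] == 0))
  expect_equal(p$values[, 1:100], m$values)
  # zero-padding conservation: padded region contributes nothing
  expect_equal(rowSums(p$values), rowSums(m$values))

  long <- mfcc_matrix(matrix(rnorm(52 * 1000), 52))
  tr <- normalize_length(long, 926)
  expect_equal(tr$values, long$values[, 1:926])

  same <- normalize_length(p, 926)
  expect_identical(same$values, p$values)
})

test_that("shape contract holds end to end for varying clip lengths", {
  for (dur in c(0.5, 2, 25)) {
    clip <- audio_clip(stats::rnorm(round(dur * 22050)), 22050)
    out <- normalize_length(extract_mfcc(clip, 52), 926)
    expect_equal(dim(out$values), c(52, 926))
  }
})

test_that("label codec is bijective over the 8 sorted classes", {
  codec <- label_codec()
  expect_length(codec$classes, 8)
  # ordering oracle: case-insensitive lexicographic sort
  expect_equal(codec$classes,
               codec$classes[order(tolower(codec$classes))])
  enc <- encode_labels(codec$classes)
  expect_true(all(rowSums(enc$onehot) == 1))
  expect_equal(decode_labels(codec, enc$onehot), codec$classes)

  two <- encode_labels(c("COPD", "asthma"))
  expect_equal(rowSums(two$onehot), c(1, 1), ignore_attr = TRUE)
  expect_error(encode_labels(c("COPD", "flu")), "flu")
})

test_that("feature matrices roundtrip through the binary container", {
  m <- mfcc_matrix(matrix(rnorm(52 * 30), 52))
  f <- withr::local_tempfile(fileext = ".bin")
  write_features(m, f, source = "clip.wav")
  m2 <- read_features(f)
  expect_equal(m2$values, m$values)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$n_mfcc, 52)
  expect_equal(unlist(meta$classes), diagnosis_classes())
})

test_that("the RSDB-style layout reader joins clips to diagnoses", {
  dir <- withr::local_tempdir()
  write_wav(numeric(1000), 8000, file.path(dir, "101_1b1_Al.wav"))
  write_wav(numeric(1000), 8000, file.path(dir, "102_2b2_Pr.wav"))
  diagf <- file.path(dir, "diagnosis.txt")
  writeLines(c("101 COPD", "102 asthma"), diagf)
  man <- read_rsdb_manifest(dir, diagf)
  expect_equal(nrow(man), 2)
  expect_equal(man$label[man$subject_id == "101"], "COPD")
  expect_equal(man$label[man$subject_id == "102"], "asthma")
})

test_that("the optional z-score scaler standardizes per coefficient", {
  feats <- lapply(1:5, function(i) mfcc_matrix(matrix(rnorm(10 * 40, mean = i), 10)))
  sc <- fit_mfcc_scaler(feats)
  scaled <- do.call(cbind, lapply(feats, function(m) scale_mfcc(m, sc)$values))
  expect_equal(rowMeans(scaled), rep(0, 10), tolerance = 1e-10)
  expect_equal(apply(scaled, 1, stats::sd), rep(1, 10), tolerance = 1e-10)
})
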