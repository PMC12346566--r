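test_that("augment_op enforces the documented parameter ranges", {
  expect_error(augment_op("pitch_shift", pitch = 3), "\\[-2, 2\\]")
  expect_error(augment_op("time_stretch", stretch = 0.5), "\\[0.8, 1.2\\]")
  expect_error(augment_op("noise_inject", snr = 40), "\\[5, 30\\]")
  expect_error(augment_op("gain", gain = 10), "\\[-6, 6\\]")
  expect_s3_class(augment_op("pitch_shift", pitch = -2), "augment_op")
})

test_that("inject_noise hits the requested SNR exactly", {
  clip <- tone_clip(300, 1)
  for (snr in c(0, 10, 23.5)) {
    noisy <- inject_noise(clip, snr, seed = 4)
    p_noise <- mean((noisy$samples - clip$samples)^2)
    achieved <- 10 * log10(mean(clip$samples^2) / p_noise)
    expect_equal(achieved, snr, tolerance = 0.1)
  }
  # power-ratio oracle: snr 10 dB on (near) unit-power signal -> noise power 0.1
  unitp <- audio_clip(clip$samples / sqrt(mean(clip$samples^2)), 22050)
  n10 <- inject_noise(unitp, 10, seed = 1)
  expect_equal(mean((n10$samples - unitp$samples)^2), 0.1, tolerance = 1e-6)
  # large-SNR limit: output converges to the input
  hi <- inject_noise(clip, 80, seed = 4)
  expect_lt(max(abs(hi$samples - clip$samples)), 1e-3)
  expect_error(inject_noise(audio_clip(numeric(100), 22050), 10, 1),
               "SNR undefined")
})

test_that("pink noise concentrates power at low frequencies", {
  clip <- tone_clip(1000, 1)
  pink <- inject_noise(clip, 0, seed = 2, color = "pink")$samples - clip$samples
  P <- Mod(stats::fft(pink))^2
  half <- floor(length(P) / 2)
  lo <- sum(P[2:floor(half / 8)])
  hi <- sum(P[(half - floor(half / 8)):half])
  expect_gt(lo / hi, 5)
})

test_that("gain, stretch and pitch ops meet their analytic contracts", {
  clip <- tone_clip(440, 2)
  same <- apply_op(clip, augment_op("gain", gain = 0))
  expect_equal(same$samples, clip$samples)
  half_db <- apply_op(clip, augment_op("gain", gain = -6))
  expect_equal(mean(half_db$samples^2) / mean(clip$samples^2),
               10^(-6 / 10), tolerance = 1e-6)

  # duration oracle: factor 0.8 lengthens by 1/0.8
  st <- apply_op(clip, augment_op("time_stretch", stretch = 0.8))
  expect_length(st$samples, round(length(clip$samples) / 0.8))
  st2 <- time_stretch(clip, 1.2)
  expect_length(st2$samples, round(length(clip$samples) / 1.2))

  # pitch oracle: +2 semitones moves 440 Hz to 440 * 2^(2/12) = 493.88
  ps <- apply_op(clip, augment_op("pitch_shift", pitch = 2))
  expect_length(ps$samples, length(clip$samples))
  expect_equal(fft_peak_hz(ps$samples, 22050), 440 * 2^(2 / 12), tolerance = 2)
})

test_that("the fidelity gate accepts self-comparison and rejects noise", {
  clip <- synth_clip(quick_recipes()$COPD, seed = 5)
  self <- validate_augmented(clip, clip)
  expect_equal(self$r, 1, tolerance = 1e-9)
  expect_true(self$accepted)
  expect_equal(self$threshold, 0.85)

  wn <- audio_clip(stats::rnorm(length(clip$samples)), 22050)
  tone <- tone_clip(300, 2)
  rej <- validate_augmented(tone, wn)
  expect_lt(rej$r, 0.5)
  expect_false(rej$accepted)
  expect_error(validate_augmented(clip, audio_clip(numeric(0), 22050)), "empty")
})

test_that("surrogate generation stays same-class, bounded, and parent-tagged", {
  clips <- lapply(1:3, function(i) {
    cl <- synth_clip(quick_recipes()$pneumonia, seed = i)
    cl$id <- paste0("p", i); cl
  })
  out <- surrogate_generate(clips, seed = 9)
  expect_equal(out$label, "pneumonia")
  expect_true(attr(out, "parent") %in% 1:3)
  expect_equal(out$subject_id, clips[[attr(out, "parent")]]$subject_id)
  # RMS bound: convex mixture then one classical op (max +6 dB gain, noise
  # at >= 5 dB SNR) cannot triple the parents' RMS
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$samples), 3 * max(vapply(clips, function(c) rms(c$samples), 0)))

  # single-clip fallback routes through a classical op
  solo <- surrogate_generate(clips[1], seed = 2)
  expect_equal(attr(solo, "parent"), 1L)
  expect_true(all(is.finite(solo$samples)))
})

test_that("balance_classes reaches targets with only gated, subject-tagged
           clips and flattens the class distribution", {
  set <- synth_cohort(c(asthma = 1, LRTI = 2, healthy = 6, pneumonia = 4),
                      subjects_per_class = 2, seed = 0,
                      recipes = quick_recipes(2))
  plan <- augment_plan(per_class_target = c(asthma = 15, LRTI = 15,
                                            healthy = 6, pneumonia = 10))
  out <- balance_classes(set, plan, seed = 0)
  counts <- attr(out, "retained_counts")
  expect_gte(counts[["asthma"]], 15)
  expect_gte(counts[["LRTI"]], 15)
  expect_gte(counts[["pneumonia"]], 10)
  expect_equal(counts[["healthy"]], 6)          # already at target: untouched

  audit <- attr(out, "validation")
  expect_true(all(audit$r[audit$accepted] > 0.85))
  # extreme minorities route through the 25x stage first
  expect_true(all(audit$stage[audit$class == "asthma" & audit$accepted] ==
                    "minority25x"))
  # every augmented clip inherits a source subject of its own class
  aug <- out$clips[vapply(out$clips, function(cl) isTRUE(attr(cl, "augmented")), TRUE)]
  for (cl in aug) {
    expect_equal(unname(set$subjects[cl$subject_id]), cl$label)
  }
  # class-distribution flattening (direction only)
  expect_lt(class_kl_uniform(counts), class_kl_uniform(set$per_class_counts))
})

test_that("an unreachable fidelity threshold exhausts the retry budget", {
  set <- synth_cohort(c(asthma = 2), subjects_per_class = 1, seed = 0,
                      recipes = quick_recipes(1))
  plan <- augment_plan(per_class_target = c(asthma = 6), threshold = 0.99999)
  expect_error(balance_classes(set, plan, seed = 0, retry_budget = 2),
               "retry budget exhausted.*asthma")
})
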