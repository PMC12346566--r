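# Three-stage class-balancing augmentation: classical waveform transforms and
# a deterministic parametric surrogate generator, every candidate gated by a
# spectrogram cross-correlation fidelity check (r > 0.85), with augmented
# clips inheriting their source subject so patient-level splits stay clean.

AUGMENT_KINDS <- c("pitch_shift", "time_stretch", "gain", "noise_inject",
                   "surrogate_synthesis")

#' Construct an augmentation operation
#'
#' Parameter ranges follow the pipeline's contract: pitch within +/-2
#' semitones, stretch factor 0.8-1.2, injected noise at 5-30 dB SNR, gain
#' within +/-6 dB.
#'
#' @param kind One of `pitch_shift`, `time_stretch`, `gain`, `noise_inject`,
#'   `surrogate_synthesis`.
#' @param pitch Semitones in `[-2, 2]` (pitch_shift).
#' @param stretch Stretch factor in `[0.8, 1.2]` (time_stretch).
#' @param gain Gain in dB, `[-6, 6]` (gain).
#' @param snr SNR in dB, `[5, 30]` (noise_inject).
#' @return An `augment_op` list.
#' @export
augment_op <- function(kind, pitch = NULL, stretch = NULL, gain = NULL,
                       snr = NULL) {
  kind <- match.arg(kind, AUGMENT_KINDS)
  if (kind == "pitch_shift") {
    if (is.null(pitch) || abs(pitch) > 2) stop("pitch must lie in [-2, 2] semitones")
  }
  if (kind == "time_stretch") {
    if (is.null(stretch) || stretch < 0.8 || stretch > 1.2) {
      stop("stretch must lie in [0.8, 1.2]")
    }
  }
  if (kind == "gain") {
    if (is.null(gain) || abs(gain) > 6) stop("gain must lie in [-6, 6] dB")
  }
  if (kind == "noise_inject") {
    if (is.null(snr) || snr < 5 || snr > 30) stop("snr must lie in [5, 30] dB")
  }
  structure(list(kind = kind, pitch = pitch, stretch = stretch, gain = gain,
                 snr = snr), class = "augment_op")
}

#' Inject noise at an exact signal-to-noise ratio
#'
#' The noise is scaled so that `10*log10(P_signal / P_noise)` equals `snr_db`
#' exactly. White Gaussian by default; a pink (1/f) option approximates
#' low-frequency-weighted device noise.
#'
#' @param clip An [audio_clip()] with nonzero power.
#' @param snr_db Target SNR in dB.
#' @param seed Integer seed.
#' @param color `"white"` or `"pink"`.
#' @return The noisy [audio_clip()].
#' @export
inject_noise <- function(clip, snr_db, seed, color = c("white", "pink")) {
  color <- match.arg(color)
  p_sig <- mean(clip$samples^2)
  if (p_sig == 0) stop("inject_noise: all-zero clip, SNR undefined")
  n <- length(clip$samples)
  noise <- with_seed(seed, {
    z <- stats::rnorm(n)
    if (color == "pink") {
      Z <- stats::fft(z)
      k <- c(1, seq_len(n - 1))                # DC kept flat
      shape <- 1 / sqrt(pmin(k, n - k + 1))
      z <- Re(stats::fft(Z * shape, inverse = TRUE)) / n
    }
    z
  })
  noise <- noise / sqrt(mean(noise^2))         # unit power
  scale <- sqrt(p_sig / 10^(snr_db / 10))
  out <- clip
  out$samples <- clip$samples + scale * noise
  out
}

# Phase vocoder: stretch the time axis by `rate` (output duration =
# input duration / rate) while preserving pitch. Fully vectorized: the phase
# recurrence is a cumulative sum of per-step principal-value deviations.
.phase_vocoder <- function(x, rate, n_fft = 1024, hop = 256) {
  S <- stft(x, n_fft = n_fft, hop = hop)
  n_bins <- nrow(S)
  T_in <- ncol(S)
  steps <- seq(1, T_in, by = rate)
  n_steps <- length(steps)
  omega <- 2 * pi * (seq_len(n_bins) - 1) / n_fft    # rad/sample
  phi_adv <- omega * hop                             # expected advance per hop
  t0 <- pmin(floor(steps), T_in)
  t1 <- pmin(t0 + 1L, T_in)
  frac <- rep(steps - t0, each = n_bins)
  M <- Mod(S); A <- Arg(S)
  mag <- (1 - frac) * M[, t0, drop = FALSE] + frac * M[, t1, drop = FALSE]
  dphi <- A[, t1, drop = FALSE] - A[, t0, drop = FALSE] - phi_adv
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))     # principal value
  step_adv <- dphi + phi_adv
  phase <- matrix(0, n_bins, n_steps)
  acc <- A[, 1]
  for (j in seq_len(n_steps)) {                      # cheap running sum
    phase[, j] <- acc
    acc <- acc + step_adv[, j]
  }
  istft(mag * exp(1i * phase), n_fft = n_fft, hop = hop,
        n_out = round(length(x) / rate))
}

#' Time-stretch a clip (pitch preserved)
#'
#' Phase-vocoder stretch: `factor` 0.8 turns a 10 s clip into a 12.5 s clip
#' (duration scales by `1/factor`).
#'
#' @param clip An [audio_clip()].
#' @param factor Stretch factor in `[0.8, 1.2]`.
#' @return The stretched [audio_clip()].
#' @export
time_stretch <- function(clip, factor) {
  out <- clip
  out$samples <- .phase_vocoder(clip$samples, rate = factor)
  out
}

#' Pitch-shift a clip (duration preserved)
#'
#' Vocoder stretch by `2^(-semitones/12)` followed by resampling back to the
#' original length, shifting all frequencies by `2^(semitones/12)`.
#'
#' @param clip An [audio_clip()].
#' @param semitones Shift in semitones, `[-2, 2]`.
#' @return The shifted [audio_clip()].
#' @export
pitch_shift <- function(clip, semitones) {
  k <- 2^(semitones / 12)
  y <- .phase_vocoder(clip$samples, rate = 1 / k)    # duration x k
  n <- length(clip$samples)
  # compress the time axis by k: dense linear resampling is adequate here
  # because fixture content sits far below Nyquist
  y <- stats::approx(seq_along(y), y, xout = seq(1, length(y), length.out = n))$y
  out <- clip
  out$samples <- y
  out
}

#' Apply one augmentation operation
#'
#' @param clip An [audio_clip()].
#' @param op An [augment_op()].
#' @param seed Integer seed (used by stochastic ops).
#' @return The transformed [audio_clip()].
#' @export
apply_op <- function(clip, op, seed = 0) {
  out <- switch(op$kind,
    pitch_shift  = pitch_shift(clip, op$pitch),
    time_stretch = time_stretch(clip, op$stretch),
    gain         = { o <- clip; o$samples <- clip$samples * 10^(op$gain / 20); o },
    noise_inject = inject_noise(clip, op$snr, seed = seed),
    stop("apply_op does not dispatch kind ", op$kind)
  )
  if (any(!is.finite(out$samples))) stop("augmentation produced non-finite samples")
  out
}

#' Draw a random classical operation with in-range parameters
#' @param seed Integer seed.
#' @return An [augment_op()].
#' @export
random_classical_op <- function(seed) {
  with_seed(seed, {
    kind <- sample(c("pitch_shift", "time_stretch", "gain", "noise_inject"), 1)
    switch(kind,
      pitch_shift  = augment_op("pitch_shift", pitch = stats::runif(1, -2, 2)),
      time_stretch = augment_op("time_stretch", stretch = stats::runif(1, 0.8, 1.2)),
      gain         = augment_op("gain", gain = stats::runif(1, -6, 6)),
      noise_inject = augment_op("noise_inject", snr = stats::runif(1, 5, 30)))
  })
}

# Smoothed mel-band log spectrogram over the adventitious-sound band
# (50-2500 Hz). Boxcar smoothing along time (~0.25 s) and frequency keeps the
# slow spectro-temporal envelope -- breath cycles, wheeze ridges, crackle
# showers -- and discards stochastic fine texture, which is what a fidelity
# judgment should ignore.
.fidelity_spectrogram <- function(x, sample_rate, n_mels = 32, fmin = 50,
                                  fmax = 2500, floor_db = 60, tw = 21, fw = 3) {
  p <- Mod(stft(x, n_fft = 1024, hop = 256))^2
  fb <- mel_filterbank(n_mels, 1024, sample_rate, fmin, min(fmax, sample_rate / 2))
  m <- fb %*% p
  db <- pmax(10 * log10(pmax(m, 1e-20) / max(m, 1e-20)), -floor_db)
  smooth1 <- function(v, w) {
    f <- stats::filter(v, rep(1 / w, w), sides = 2)
    f[is.na(f)] <- v[is.na(f)]
    as.numeric(f)
  }
  db <- t(apply(db, 1, smooth1, w = tw))
  apply(db, 2, smooth1, w = fw)
}

#' Validate an augmented clip against its source
#'
#' Fidelity statistic: peak normalized cross-correlation (Pearson, maximized
#' over small time- and mel-band lags) between smoothed mel-scaled
#' log-magnitude spectrograms of source and augmentation, restricted to the
#' 50-2500 Hz band where adventitious lung sounds live. Stretched clips have
#' their spectrogram time axis linearly re-gridded to the source frame count
#' first. Accepted iff `r > threshold`.
#'
#' @param source,augmented [audio_clip()] objects.
#' @param threshold Acceptance threshold (default 0.85).
#' @param max_lag Time-frame lags searched on each side (default 6).
#' @param max_band_lag Mel-band lags searched on each side (default 2;
#'   absorbs in-range pitch shifts).
#' @return A `validation_report`: list with `r`, `accepted`, `threshold`.
#' @export
validate_augmented <- function(source, augmented, threshold = 0.85,
                               max_lag = 6, max_band_lag = 2) {
  if (length(source$samples) == 0 || length(augmented$samples) == 0) {
    stop("validate_augmented: empty clip")
  }
  S1 <- .fidelity_spectrogram(source$samples, source$sample_rate)
  .validate_against(S1, augmented, threshold, max_lag, max_band_lag)
}

# Validation against a precomputed source fidelity spectrogram (lets the
# balance loop cache spectrograms for reused sources).
.validate_against <- function(S1, augmented, threshold = 0.85,
                              max_lag = 6, max_band_lag = 2) {
  S2 <- .fidelity_spectrogram(augmented$samples, augmented$sample_rate)
  if (ncol(S2) != ncol(S1)) {                  # re-grid the time axis
    xi <- seq(1, ncol(S2), length.out = ncol(S1))
    S2 <- t(apply(S2, 1, function(row) stats::approx(seq_along(row), row, xout = xi)$y))
  }
  Tn <- ncol(S1); Fn <- nrow(S1)
  r_best <- -1
  for (lf in -max_band_lag:max_band_lag) {
    for (lt in seq(-max_lag, max_lag, by = 2L)) {
      a <- S1[max(1, 1 + lf):min(Fn, Fn + lf), max(1, 1 + lt):min(Tn, Tn + lt), drop = FALSE]
      b <- S2[max(1, 1 - lf):min(Fn, Fn - lf), max(1, 1 - lt):min(Tn, Tn - lt), drop = FALSE]
      r <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
      if (is.finite(r) && r > r_best) r_best <- r
    }
  }
  structure(list(r = r_best, accepted = r_best > threshold,
                 threshold = threshold), class = "validation_report")
}

#' Surrogate generative augmentation
#'
#' Deterministic parametric stand-in for a learned generator: a convex
#' time-domain mixture of two same-class clips (weight in `[0.3, 0.7]`)
#' followed by one random classical transform. The fidelity gate downstream —
#' not the generator — enforces pathological plausibility.
#'
#' @param class_clips List of same-class [audio_clip()] objects.
#' @param seed Integer seed.
#' @return An [audio_clip()]; attribute `"parent"` names the dominant parent's
#'   position in `class_clips`.
#' @export
surrogate_generate <- function(class_clips, seed) {
  if (length(class_clips) < 2) {               # fall back to classical ops
    out <- apply_op(class_clips[[1]], random_classical_op(seed), seed = seed + 1L)
    attr(out, "parent") <- 1L
    return(out)
  }
  with_seed(seed, {
    ij <- sample(length(class_clips), 2)
    u <- stats::runif(1, 0.3, 0.7)
    a <- class_clips[[ij[1]]]; b <- class_clips[[ij[2]]]
    n <- min(length(a$samples), length(b$samples))
    mixed <- u * a$samples[seq_len(n)] + (1 - u) * b$samples[seq_len(n)]
    dominant <- if (u >= 0.5) ij[1] else ij[2]
    parent <- class_clips[[dominant]]
    out <- audio_clip(mixed, a$sample_rate, subject_id = parent$subject_id,
                      label = parent$label)
    op_seed <- sample.int(1e6, 1)
    out <- apply_op(out, random_classical_op(op_seed), seed = op_seed + 1L)
    attr(out, "parent") <- dominant
    out
  })
}

#' Balancing plan for the augmentation pipeline
#'
#' Per-class targets default to a fresh uniform draw on `[720, 760]` at
#' balancing time (reproducing the ">= 720, mean ~738" regime); classes already
#' above 760 are left untouched. Extreme-minority classes are routed through a
#' 25x up-sampling stage first.
#'
#' @param per_class_target Named class -> count map, or `NULL` to draw.
#' @param classical_fraction Share of candidates from classical transforms
#'   (default 0.6; the remainder uses the surrogate generator).
#' @param extreme_minority_factor First-stage up-sampling multiplier (default 25).
#' @param extreme_minority_classes Classes routed through the first stage.
#' @param threshold Fidelity acceptance threshold (default 0.85).
#' @return An `augment_plan` list.
#' @export
augment_plan <- function(per_class_target = NULL, classical_fraction = 0.6,
                         extreme_minority_factor = 25,
                         extreme_minority_classes = c("LRTI", "asthma", "bronchiolitis"),
                         threshold = 0.85) {
  stopifnot(classical_fraction >= 0, classical_fraction <= 1)
  structure(list(per_class_target = per_class_target,
                 classical_fraction = classical_fraction,
                 extreme_minority_factor = extreme_minority_factor,
                 extreme_minority_classes = extreme_minority_classes,
                 threshold = threshold), class = "augment_plan")
}

#' Balance class counts by gated augmentation
#'
#' Candidates are generated from the growing same-class pool (60/40
#' classical/surrogate mix), validated against their source, and retained only
#' when `r > threshold`; rejected candidates are regenerated up to
#' `retry_budget` attempts each. Every retained clip inherits its source
#' clip's subject id.
#'
#' @param set A `fixture_set`.
#' @param plan An [augment_plan()].
#' @param seed Integer seed.
#' @param retry_budget Regeneration attempts per needed clip (default 8).
#' @param keep_audio Keep augmented waveforms in the returned set. With
#'   `FALSE` (bulk balancing runs) waveforms are discarded after validation
#'   and only the originals plus the audit trail are returned.
#' @param out_dir Optional directory: augmented WAVs and an updated manifest
#'   are written there.
#' @return The balanced `fixture_set`; attribute `"validation"` holds the
#'   per-sample audit data frame (id, class, subject, source, kind, stage, r,
#'   accepted) including rejected candidates, and `"retained_counts"` the
#'   final per-class counts.
#' @export
balance_classes <- function(set, plan = augment_plan(), seed = 0,
                            retry_budget = 8, keep_audio = TRUE,
                            out_dir = NULL) {
  labels <- vapply(set$clips, `[[`, "", "label")
  counts <- table(labels)
  targets <- plan$per_class_target
  if (is.null(targets)) {
    targets <- with_seed(seed, {
      stats::setNames(round(stats::runif(length(counts), 720, 760)), names(counts))
    })
  }
  missing_cls <- setdiff(names(targets), names(counts))
  if (length(missing_cls) > 0) {
    stop("plan targets classes absent from the set: ",
         paste(missing_cls, collapse = ", "))
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  audit <- list()
  new_clips <- list()
  retained <- stats::setNames(as.integer(counts), names(counts))
  rng <- as.integer(seed) %% 100000L
  spec_cache <- new.env(parent = emptyenv())
  cached_spec <- function(clip) {
    key <- clip$id
    if (is.null(key)) {
      return(.fidelity_spectrogram(clip$samples, clip$sample_rate))
    }
    if (!exists(key, envir = spec_cache)) {
      assign(key, .fidelity_spectrogram(clip$samples, clip$sample_rate),
             envir = spec_cache)
    }
    get(key, envir = spec_cache)
  }

  for (cls in names(targets)) {
    target <- max(targets[[cls]], counts[[cls]])
    needed <- target - counts[[cls]]
    if (needed <= 0) next
    pool <- set$clips[labels == cls]
    rm(list = ls(envir = spec_cache), envir = spec_cache)
    stage1_quota <- if (cls %in% plan$extreme_minority_classes) {
      min(needed, (plan$extreme_minority_factor - 1L) * counts[[cls]])
    } else 0L
    made <- 0L
    attempts <- 0L
    max_attempts <- retry_budget * needed
    while (made < needed) {
      if (attempts >= max_attempts) {
        stop("augmentation retry budget exhausted for class ", cls,
             " (", made, "/", needed, " accepted)")
      }
      attempts <- attempts + 1L
      s <- rng * 100000L %% 2000000000L + attempts * 7L +
        match(cls, diagnosis_classes()) * 131L
      use_classical <- with_seed(s, stats::runif(1)) < plan$classical_fraction
      if (use_classical || length(pool) < 2) {
        src_i <- with_seed(s + 1L, sample.int(length(pool), 1))
        src <- pool[[src_i]]
        op <- random_classical_op(s + 2L)
        cand <- apply_op(src, op, seed = s + 3L)
        kind <- op$kind
      } else {
        cand <- surrogate_generate(pool, seed = s + 4L)
        src <- pool[[attr(cand, "parent")]]
        kind <- "surrogate_synthesis"
      }
      rep_ <- .validate_against(cached_spec(src), cand, threshold = plan$threshold)
      stage <- if (made < stage1_quota) "minority25x" else "balance"
      id <- sprintf("%s_aug%04d", cls, made + 1L)
      audit[[length(audit) + 1L]] <- data.frame(
        id = id, class = cls, subject_id = src$subject_id,
        source = if (is.null(src$id)) NA_character_ else src$id,
        kind = kind, stage = stage, r = rep_$r, accepted = rep_$accepted,
        stringsAsFactors = FALSE)
      if (!rep_$accepted) next
      made <- made + 1L
      cand$id <- id
      cand$subject_id <- src$subject_id      # leakage guard: inherit subject
      attr(cand, "augmented") <- TRUE
      if (!is.null(out_dir)) {
        write_wav(cand$samples, cand$sample_rate, file.path(out_dir, paste0(id, ".wav")))
      }
      pool[[id]] <- cand
      if (keep_audio) new_clips[[id]] <- cand
    }
    retained[cls] <- retained[cls] + made
  }

  out <- set
  if (keep_audio) out$clips <- c(set$clips, new_clips)
  out$per_class_counts <- retained
  audit_df <- do.call(rbind, audit)
  attr(out, "validation") <- audit_df
  attr(out, "retained_counts") <- retained
  if (!is.null(out_dir)) {
    utils::write.csv(audit_df, file.path(out_dir, "validation_report.csv"),
                     row.names = FALSE)
    rows <- lapply(if (keep_audio) out$clips else set$clips, function(cl) {
      data.frame(path = if (isTRUE(attr(cl, "augmented")))
                   file.path(out_dir, paste0(cl$id, ".wav")) else NA_character_,
                 subject_id = cl$subject_id, label = cl$label,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  out
}

#' KL divergence of a class distribution from uniform
#'
#' @param counts Named per-class counts.
#' @return `sum(p * log(p / u))` with `u = 1/K`.
#' @export
class_kl_uniform <- function(counts) {
  p <- counts / sum(counts)
  u <- 1 / length(p)
  sum(ifelse(p > 0, p * log(p / u), 0))
}
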