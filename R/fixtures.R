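# Class-conditional synthetic auscultation audio. Wheezes are sustained
# narrowband tones (horizontal spectrogram ridges); crackles are transient
# broadband clicks (vertical spikes). Each class gets a distinct,
# overlapping-but-separable parameterization so downstream learners have
# signal without the generator trivially encoding the label.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded synthesis never
#' perturbs surrounding randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Sound recipe for one diagnosis class
#'
#' @param label Diagnosis class name.
#' @param wheeze_band Two-element Hz interval within (50, 2000), or `NULL`.
#' @param wheeze_fraction Proportion of the clip carrying wheeze tone segments.
#' @param crackle_rate Crackle events per second (>= 0).
#' @param crackle_width Crackle click width in milliseconds.
#' @param breath_noise_level Relative amplitude of broadband breath noise.
#' @param duration Clip duration in seconds (> 0).
#' @return A `sound_recipe` list.
#' @export
sound_recipe <- function(label, wheeze_band = NULL, wheeze_fraction = 0,
                         crackle_rate = 0, crackle_width = 5,
                         breath_noise_level = 0.3, duration = 10) {
  if (!is.null(wheeze_band)) {
    stopifnot(length(wheeze_band) == 2, wheeze_band[1] > 50, wheeze_band[2] < 2000,
              wheeze_band[1] < wheeze_band[2])
  }
  stopifnot(crackle_rate >= 0, wheeze_fraction >= 0, wheeze_fraction <= 1,
            duration > 0)
  structure(list(label = label, wheeze_band = wheeze_band,
                 wheeze_fraction = wheeze_fraction, crackle_rate = crackle_rate,
                 crackle_width = crackle_width,
                 breath_noise_level = breath_noise_level, duration = duration),
            class = "sound_recipe")
}

#' Default class-to-recipe table
#'
#' Distinct wheeze bands and crackle regimes per class; COPD and LRTI share
#' neighbouring low-frequency wheeze bands to mimic their clinical confusion.
#'
#' @param duration Clip duration in seconds applied to every recipe (default 10).
#' @return Named list of [sound_recipe()] objects, one per diagnosis class.
#' @export
default_recipes <- function(duration = 10) {
  r <- list(
    asthma         = sound_recipe("asthma", c(400, 700), 0.6, 0, 5, 0.25, duration),
    bronchiectasis = sound_recipe("bronchiectasis", NULL, 0, 16, 12, 0.30, duration),
    bronchiolitis  = sound_recipe("bronchiolitis", c(1000, 1400), 0.5, 6, 4, 0.30, duration),
    COPD           = sound_recipe("COPD", c(150, 300), 0.5, 2, 6, 0.30, duration),
    healthy        = sound_recipe("healthy", NULL, 0, 0, 5, 0.30, duration),
    LRTI           = sound_recipe("LRTI", c(650, 900), 0.35, 5, 8, 0.35, duration),
    pneumonia      = sound_recipe("pneumonia", NULL, 0, 10, 5, 0.35, duration),
    URTI           = sound_recipe("URTI", c(1500, 1900), 0.4, 0, 5, 0.40, duration)
  )
  r[diagnosis_classes()]
}

#' Per-class clip counts of the reference imbalanced dataset
#'
#' The severely imbalanced eight-class distribution the augmentation pipeline
#' is designed around (920 clips in total).
#'
#' @return Named integer vector (class -> clip count).
#' @export
reference_class_counts <- function() {
  c(asthma = 1L, bronchiectasis = 16L, bronchiolitis = 13L, COPD = 793L,
    healthy = 35L, LRTI = 2L, pneumonia = 37L, URTI = 23L)
}

#' Synthesize one class-conditional clip
#'
#' Breath noise is amplitude-modulated broadband noise; wheezes are slowly
#' frequency-wandering tones confined to the recipe band and to a fraction of
#' the clip; crackles are exponentially damped broadband clicks at
#' approximately `crackle_rate` events per second.
#'
#' @param recipe A [sound_recipe()].
#' @param seed Integer seed; output is deterministic in `(recipe, seed)`.
#' @param sample_rate Sampling rate in Hz (default 22050).
#' @param subject_id Optional subject id for the clip.
#' @return An [audio_clip()]; attribute `"events"` records wheeze segment and
#'   crackle onset times (seconds).
#' @export
synth_clip <- function(recipe, seed, sample_rate = 22050,
                       subject_id = NA_character_) {
  with_seed(seed, {
    n <- round(recipe$duration * sample_rate)
    tt <- seq_len(n) / sample_rate

    # breath noise: white noise smoothed (3-tap) and modulated at ~0.25 Hz
    noise <- stats::rnorm(n)
    noise <- stats::filter(noise, rep(1 / 3, 3), sides = 2)
    noise[is.na(noise)] <- 0
    breath <- 0.6 + 0.4 * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))^2
    x <- recipe$breath_noise_level * as.numeric(noise) * breath

    wheeze_segments <- NULL
    if (!is.null(recipe$wheeze_band) && recipe$wheeze_fraction > 0) {
      n_seg <- max(1L, round(recipe$duration / 2.5))
      seg_len <- recipe$wheeze_fraction * recipe$duration / n_seg
      starts <- sort(stats::runif(n_seg, 0, recipe$duration - seg_len))
      env <- numeric(n)
      for (s in starts) {
        i0 <- max(1L, round(s * sample_rate)); i1 <- min(n, round((s + seg_len) * sample_rate))
        ramp <- round(0.02 * sample_rate)
        seg <- rep(1, i1 - i0 + 1L)
        k <- min(ramp, length(seg) %/% 2L)
        if (k > 1) {
          seg[seq_len(k)] <- seq(0, 1, length.out = k)
          seg[(length(seg) - k + 1L):length(seg)] <- seq(1, 0, length.out = k)
        }
        env[i0:i1] <- pmax(env[i0:i1], seg)
      }
      f0 <- stats::runif(1, recipe$wheeze_band[1], recipe$wheeze_band[2])
      # slow wander, clipped to the band
      drift <- cumsum(stats::rnorm(n, 0, 0.3)) / sample_rate * 50
      f <- pmin(recipe$wheeze_band[2], pmax(recipe$wheeze_band[1], f0 + drift))
      phase <- 2 * pi * cumsum(f) / sample_rate
      tone <- sin(phase) + 0.3 * sin(2 * phase)   # mild second harmonic
      x <- x + 0.8 * env * tone
      wheeze_segments <- cbind(start = starts, end = starts + seg_len)
    }

    crackle_times <- numeric(0)
    if (recipe$crackle_rate > 0) {
      n_ev <- max(1L, stats::rpois(1, recipe$crackle_rate * recipe$duration))
      crackle_times <- sort(stats::runif(n_ev, 0, recipe$duration))
      w <- max(2L, round(recipe$crackle_width / 1000 * sample_rate))
      burst_t <- seq_len(w)
      for (ct in crackle_times) {
        i0 <- round(ct * sample_rate) + 1L
        if (i0 + w - 1L > n) next
        burst <- stats::rnorm(w) * exp(-5 * burst_t / w)
        x[i0:(i0 + w - 1L)] <- x[i0:(i0 + w - 1L)] + 1.2 * burst
      }
    }

    x <- x / max(abs(x), 1e-9) * 0.9            # headroom-normalized
    clip <- audio_clip(x, sample_rate, subject_id = subject_id,
                       label = recipe$label)
    attr(clip, "events") <- list(wheeze_segments = wheeze_segments,
                                 crackle_times = crackle_times)
    clip
  })
}

#' Synthesize a multi-subject fixture cohort
#'
#' Clips are assigned round-robin to `subjects_per_class` subjects per class;
#' a subject never appears under two classes, so subject-level splits are
#' leakage-safe by construction.
#'
#' @param per_class_counts Named integer vector (class -> clip count); defaults
#'   to [reference_class_counts()].
#' @param subjects_per_class Subjects per class (clips per class permitting).
#' @param seed Integer seed.
#' @param recipes Recipe table, defaults to [default_recipes()].
#' @param sample_rate Sampling rate in Hz.
#' @return A `fixture_set`: list with `clips` (list of [audio_clip()]),
#'   `per_class_counts`, and `subjects` (named map subject -> class).
#' @export
synth_cohort <- function(per_class_counts = reference_class_counts(),
                         subjects_per_class = 5, seed = 0,
                         recipes = default_recipes(), sample_rate = 22050) {
  stopifnot(all(per_class_counts >= 0), subjects_per_class >= 1)
  clips <- list()
  subjects <- character(0)
  for (cls in names(per_class_counts)) {
    cnt <- per_class_counts[[cls]]
    if (cnt == 0) next
    if (is.null(recipes[[cls]])) stop("no recipe for class ", cls)
    n_subj <- min(subjects_per_class, cnt)
    sids <- sprintf("%s_s%02d", cls, seq_len(n_subj))
    subjects[sids] <- cls
    for (i in seq_len(cnt)) {
      sid <- sids[((i - 1L) %% n_subj) + 1L]
      clip_seed <- (as.integer(seed) %% 100000L) * 10000L +
        (match(cls, diagnosis_classes()) * 1000L + i) %% 10000L
      clip <- synth_clip(recipes[[cls]], seed = clip_seed,
                         sample_rate = sample_rate, subject_id = sid)
      clip$id <- sprintf("%s_%04d", cls, i)
      clips[[clip$id]] <- clip
    }
  }
  structure(list(clips = clips,
                 per_class_counts = vapply(split(
                   names(clips), vapply(clips, `[[`, "", "label")), length, 0L),
                 subjects = subjects),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("<fixture_set>", length(x$clips), "clips,",
      length(x$subjects), "subjects\n")
  print(x$per_class_counts)
  invisible(x)
}

#' Write a fixture set as WAV files plus a manifest CSV
#'
#' @param set A `fixture_set`.
#' @param dir Output directory (created if missing).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_fixture_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(set$clips, function(clip) {
    fn <- file.path(dir, paste0(clip$id, ".wav"))
    write_wav(clip$samples, clip$sample_rate, fn)
    data.frame(path = fn, subject_id = clip$subject_id, label = clip$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a manifest CSV into a fixture set
#'
#' @param manifest_path Path to a manifest CSV with `path`, `subject_id`,
#'   `label` columns.
#' @param target_rate Resampling target in Hz.
#' @return A `fixture_set`.
#' @export
read_fixture_set <- function(manifest_path, target_rate = 22050) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  clips <- list()
  subjects <- character(0)
  for (i in seq_len(nrow(manifest))) {
    clip <- load_audio(manifest$path[i], target_rate = target_rate,
                       subject_id = manifest$subject_id[i],
                       label = manifest$label[i])
    clip$id <- tools::file_path_sans_ext(basename(manifest$path[i]))
    clips[[clip$id]] <- clip
    subjects[manifest$subject_id[i]] <- manifest$label[i]
  }
  structure(list(clips = clips,
                 per_class_counts = vapply(split(
                   names(clips), vapply(clips, `[[`, "", "label")), length, 0L),
                 subjects = subjects),
            class = "fixture_set")
}
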