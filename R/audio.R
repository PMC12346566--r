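#' Construct an audio clip
#'
#' The basic container moved through the pipeline: a finite mono waveform with
#' its sampling rate, plus the subject id and diagnosis label used by the
#' leakage-safe evaluation protocols.
#'
#' @param samples Numeric vector, finite amplitudes (dimensionless).
#' @param sample_rate Sampling rate in Hz, positive.
#' @param subject_id Opaque subject identifier (or `NA`).
#' @param label One of the eight diagnosis classes (or `NA`).
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, subject_id = NA_character_,
                       label = NA_character_) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("audio_clip: samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("audio_clip: sample_rate must be a positive scalar")
  }
  if (!is.na(label)) label <- match.arg(label, diagnosis_classes())
  structure(
    list(samples = samples, sample_rate = sample_rate,
         subject_id = as.character(subject_id), label = label),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.2f s @ %d Hz, subject=%s, label=%s\n",
              length(x$samples) / x$sample_rate, as.integer(x$sample_rate),
              x$subject_id, x$label))
  invisible(x)
}

#' Clip duration in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Load an audio file as a mono clip at a target rate
#'
#' Reads a WAV container, average-downmixes multichannel recordings to mono,
#' and resamples to `target_rate` with a polyphase filter. The default rate of
#' 22,050 Hz balances spectral detail against compute for auscultation audio.
#'
#' @param path Path to an audio file (WAV).
#' @param target_rate Target sampling rate in Hz (default 22050).
#' @param subject_id,label Optional metadata attached to the clip.
#' @return An `audio_clip` at `target_rate`.
#' @export
load_audio <- function(path, target_rate = 22050, subject_id = NA_character_,
                       label = NA_character_) {
  w <- read_wav(path)
  x <- rowMeans(w$samples)                      # average-downmix to mono
  x <- resample_audio(x, w$sample_rate, target_rate)
  audio_clip(x, target_rate, subject_id = subject_id, label = label)
}

#' Resample a waveform between two rates
#'
#' Polyphase resampling by the reduced integer ratio `target/source`.
#' Output length is `round(n * target/source)`, preserving duration to within
#' one sample period.
#'
#' @param x Numeric waveform.
#' @param source_rate,target_rate Rates in Hz.
#' @return Resampled numeric vector.
#' @export
resample_audio <- function(x, source_rate, target_rate) {
  if (source_rate == target_rate) return(x)
  g <- .gcd(round(source_rate), round(target_rate))
  p <- round(target_rate) / g
  q <- round(source_rate) / g
  y <- signal::resample(x, p, q)
  n_out <- round(length(x) * target_rate / source_rate)
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, numeric(n_out - length(y)))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
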