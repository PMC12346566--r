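# MFCC extraction: STFT power -> mel filterbank -> log -> DCT-II (orthonormal).
# Fifty-two coefficients retained by default; the deep classifier consumes a
# fixed (52 x 926) matrix after length normalization.

#' Construct an MFCC matrix object
#' @param values Real matrix, `n_mfcc` rows x `n_frames` columns, finite.
#' @return An object of class `mfcc_matrix`.
#' @export
mfcc_matrix <- function(values) {
  stopifnot(is.matrix(values))
  if (any(!is.finite(values))) stop("mfcc_matrix: entries must be finite")
  structure(list(values = values, n_mfcc = nrow(values),
                 n_frames = ncol(values)), class = "mfcc_matrix")
}

#' @export
print.mfcc_matrix <- function(x, ...) {
  cat(sprintf("<mfcc_matrix> %d coefficients x %d frames\n", x$n_mfcc, x$n_frames))
  invisible(x)
}

# HTK mel scale
.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' @param n_mels Number of triangular filters.
#' @param n_fft FFT size.
#' @param sample_rate Sampling rate in Hz.
#' @param fmin,fmax Band edges in Hz (`fmax` defaults to Nyquist).
#' @return `n_mels` x `n_fft/2 + 1` weight matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 0, fmax = NULL) {
  if (is.null(fmax)) fmax <- sample_rate / 2
  n_bins <- n_fft %/% 2L + 1L
  freqs <- seq(0, sample_rate / 2, length.out = n_bins)
  mel_pts <- .mel_to_hz(seq(.hz_to_mel(fmin), .hz_to_mel(fmax), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- mel_pts[m]; ce <- mel_pts[m + 1L]; hi <- mel_pts[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in)
.dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  n <- seq_len(n_in) - 1L
  M <- sqrt(2 / n_in) * cos(outer(k, n + 0.5) * pi / n_in)
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

#' Extract MFCC features from a clip
#'
#' Standard cepstral pipeline: centered STFT (Hann window), power spectrum,
#' triangular mel filterbank, log compression, orthonormal DCT-II, keeping the
#' first `n_mfcc` coefficients. Fifty-two coefficients give a rich spectral
#' envelope for adventitious lung sounds at moderate cost.
#'
#' @param clip An [audio_clip()].
#' @param n_mfcc Number of cepstral coefficients (default 52).
#' @param n_fft STFT window (default 2048 samples).
#' @param hop STFT hop (default 512 samples).
#' @param n_mels Mel filters (default 64; must be >= `n_mfcc`).
#' @return An [mfcc_matrix()] with `n_mfcc` rows.
#' @export
extract_mfcc <- function(clip, n_mfcc = 52, n_fft = 2048, hop = 512, n_mels = 64) {
  if (length(clip$samples) == 0) stop("extract_mfcc: empty waveform")
  if (n_mfcc < 1) stop("extract_mfcc: n_mfcc must be >= 1")
  if (n_mfcc > n_mels) {
    stop("extract_mfcc: n_mfcc (", n_mfcc, ") exceeds filterbank size (", n_mels, ")")
  }
  p <- Mod(stft(clip$samples, n_fft = n_fft, hop = hop))^2
  fb <- mel_filterbank(n_mels, n_fft, clip$sample_rate)
  logmel <- log(fb %*% p + 1e-10)
  mfcc_matrix(.dct_matrix(n_mfcc, n_mels) %*% logmel)
}

#' Fit a per-coefficient z-score scaler on a feature set
#'
#' Optional standardization switch, off in the canonical pipeline (which only
#' length-normalizes). Each cepstral coefficient gets a mean and standard
#' deviation pooled over all frames of the supplied (training) clips;
#' applying the scaler removes the large dynamic-range disparity between
#' low- and high-order coefficients while preserving between-clip envelope
#' differences. Fit on training data only to keep evaluation splits clean.
#'
#' @param features List of [mfcc_matrix()] objects.
#' @return An `mfcc_scaler`: list with `mean` and `sd` (one per coefficient).
#' @export
fit_mfcc_scaler <- function(features) {
  mats <- lapply(features, function(m) if (inherits(m, "mfcc_matrix")) m$values else m)
  all_ <- do.call(cbind, mats)
  sd_ <- apply(all_, 1, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  structure(list(mean = rowMeans(all_), sd = sd_), class = "mfcc_scaler")
}

#' Apply an [fit_mfcc_scaler()] scaler to one MFCC matrix
#' @param m An [mfcc_matrix()].
#' @param scaler An `mfcc_scaler`.
#' @return The standardized [mfcc_matrix()].
#' @export
scale_mfcc <- function(m, scaler) {
  mfcc_matrix((m$values - scaler$mean) / scaler$sd)
}

#' Normalize an MFCC matrix to a fixed frame count
#'
#' Shorter inputs are right-padded with zero columns; longer inputs keep their
#' first `target_frames` columns (clip onset retained).
#'
#' @param m An [mfcc_matrix()].
#' @param target_frames Target column count (default 926).
#' @return An [mfcc_matrix()] with exactly `target_frames` columns.
#' @export
normalize_length <- function(m, target_frames = 926) {
  if (target_frames < 1) stop("normalize_length: target_frames must be >= 1")
  v <- m$values
  if (ncol(v) >= target_frames) {
    v <- v[, seq_len(target_frames), drop = FALSE]
  } else {
    v <- cbind(v, matrix(0, nrow(v), target_frames - ncol(v)))
  }
  mfcc_matrix(v)
}

#' Write a feature matrix with a JSON sidecar
#'
#' The matrix is stored as a plain binary array of little-endian doubles
#' (column-major); the sidecar records shape, class order, and provenance.
#'
#' @param m An [mfcc_matrix()].
#' @param path Output path for the array (`.bin`); sidecar at `<path>.json`.
#' @param source Optional source file recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_features <- function(m, path, source = NA_character_) {
  con <- file(path, "wb")
  writeBin(as.vector(m$values), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(n_mfcc = m$n_mfcc, n_frames = m$n_frames,
         storage = "float64-le-column-major",
         classes = diagnosis_classes(), source = source),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path Path to the `.bin` array.
#' @return An [mfcc_matrix()].
#' @export
read_features <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  con <- file(path, "rb")
  v <- readBin(con, "double", n = meta$n_mfcc * meta$n_frames, size = 8,
               endian = "little")
  close(con)
  mfcc_matrix(matrix(v, nrow = meta$n_mfcc))
}

#' Read a Respiratory Sound Database style layout
#'
#' Expects a directory of per-clip WAV files whose names begin with the patient
#' id (underscore-separated, e.g. `101_1b1_Al_sc_Meditron.wav`), plus a
#' two-column whitespace/comma-delimited diagnosis text file
#' (`patient_id diagnosis`).
#'
#' @param audio_dir Directory containing `.wav` files.
#' @param diagnosis_file Path to the two-column diagnosis table.
#' @return Data frame with `path`, `subject_id`, `label`.
#' @export
read_rsdb_manifest <- function(audio_dir, diagnosis_file) {
  diag <- utils::read.table(diagnosis_file, header = FALSE, sep = "",
                            col.names = c("subject_id", "label"),
                            colClasses = "character")
  wavs <- list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE,
                     ignore.case = TRUE)
  if (length(wavs) == 0) stop("no WAV files found under ", audio_dir)
  sid <- sub("_.*$", "", basename(wavs))
  sid <- sub("\\.wav$", "", sid, ignore.case = TRUE)
  lab <- diag$label[match(sid, diag$subject_id)]
  data.frame(path = wavs, subject_id = sid, label = lab,
             stringsAsFactors = FALSE)
}
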