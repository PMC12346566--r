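# Core short-time Fourier machinery shared by the MFCC extractor, the
# spectrogram fidelity gate, and the phase-vocoder time stretcher.

#' Periodic Hann window
#' @param n Window length.
#' @return Numeric vector of length `n`.
#' @keywords internal
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Reflect-pad a signal by `pad` samples on each side (librosa-style centering).
.reflect_pad <- function(x, pad) {
  n <- length(x)
  if (n == 1) return(rep(x, n + 2 * pad))
  left <- x[pmin(n, 1 + abs(seq(-pad, -1)))]          # x[pad+1], ..., x[2]
  right <- x[n - abs(seq.int(1, pad)) ]               # x[n-1], ..., x[n-pad]
  c(left, x, right)
}

#' Number of STFT frames for a centered analysis
#'
#' With centered frames the hop grid starts at sample 1, giving
#' `1 + floor(n / hop)` frames.
#'
#' @param n_samples Signal length.
#' @param hop Hop size in samples.
#' @return Frame count.
#' @export
stft_frame_count <- function(n_samples, hop) 1L + n_samples %/% as.integer(hop)

#' Short-time Fourier transform
#'
#' Centered frames (reflect padding), periodic Hann window. Returns the
#' one-sided spectrum.
#'
#' @param x Numeric waveform.
#' @param n_fft FFT size (default 2048).
#' @param hop Hop size in samples (default 512).
#' @return Complex matrix, `n_fft/2 + 1` rows x `stft_frame_count(length(x), hop)`
#'   columns.
#' @export
stft <- function(x, n_fft = 2048, hop = 512) {
  if (length(x) == 0) stop("stft: empty signal")
  pad <- n_fft %/% 2L
  xp <- .reflect_pad(x, pad)
  n_frames <- stft_frame_count(length(x), hop)
  w <- hann_window(n_fft)
  idx <- outer(seq_len(n_fft), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(xp[idx], nrow = n_fft) * w
  sp <- stats::mvfft(frames)
  sp[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
}

#' Inverse STFT (overlap-add with window-sum normalization)
#'
#' @param S One-sided complex spectrogram as produced by [stft()].
#' @param n_fft,hop Must match the analysis parameters.
#' @param n_out Output length; defaults to `(ncol(S) - 1) * hop`.
#' @return Numeric waveform.
#' @export
istft <- function(S, n_fft = 2048, hop = 512, n_out = NULL) {
  n_bins <- n_fft %/% 2L + 1L
  stopifnot(nrow(S) == n_bins)
  n_frames <- ncol(S)
  # reconstruct the full conjugate-symmetric spectrum
  full <- matrix(0i, n_fft, n_frames)
  full[seq_len(n_bins), ] <- S
  full[(n_bins + 1L):n_fft, ] <- Conj(S[(n_bins - 1L):2L, , drop = FALSE])
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  w <- hann_window(n_fft)
  frames <- frames * w
  total <- (n_frames - 1L) * hop + n_fft
  y <- numeric(total)
  wsum <- numeric(total)
  w2 <- w^2
  if (n_fft %% hop == 0L) {
    # frames whose indices differ by n_fft/hop tile the output without
    # overlap, so overlap-add reduces to k interleaved vector assignments
    k <- n_fft %/% hop
    for (r in seq_len(k)) {
      ts <- seq.int(r, n_frames, by = k)
      span <- as.vector(outer(seq_len(n_fft), (ts - 1L) * hop, `+`))
      y[span] <- y[span] + as.vector(frames[, ts])
      wsum[span] <- wsum[span] + rep(w2, times = length(ts))
    }
  } else {
    for (t in seq_len(n_frames)) {
      span <- ((t - 1L) * hop + 1L):((t - 1L) * hop + n_fft)
      y[span] <- y[span] + frames[, t]
      wsum[span] <- wsum[span] + w2
    }
  }
  y <- y / pmax(wsum, 1e-10)
  pad <- n_fft %/% 2L
  y <- y[(pad + 1L):length(y)]                 # undo centering
  if (is.null(n_out)) n_out <- (n_frames - 1L) * hop
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, numeric(n_out - length(y)))
}

#' Log-power spectrogram in decibels
#'
#' @param x Numeric waveform.
#' @param n_fft,hop STFT parameters.
#' @param floor_db Dynamic-range floor relative to the peak (default 80 dB).
#' @return Real matrix (bins x frames) of dB values.
#' @export
spectrogram_db <- function(x, n_fft = 1024, hop = 256, floor_db = 80) {
  p <- Mod(stft(x, n_fft = n_fft, hop = hop))^2
  ref <- max(p, 1e-20)
  db <- 10 * log10(pmax(p, 1e-20) / ref)
  pmax(db, -floor_db)
}
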