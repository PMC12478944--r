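#' Spectral-subtraction parameters
#'
#' Bundles the constants of the denoiser: over-subtraction factor `alpha`
#' (>= 1) that removes noise aggressively to suppress musical noise,
#' spectral floor `beta` (small positive gain re-injected where
#' subtraction would go negative), bias compensation `epsilon` (>= 1)
#' applied to the recursively averaged noise power, and the base
#' smoothing parameter `alpha_d` of the recursive average.
#'
#' @param alpha over-subtraction factor, default 2.
#' @param beta spectral floor gain, default 0.01.
#' @param epsilon noise-power bias compensation, default 1.47.
#' @param alpha_d recursive smoothing base, default 0.85.
#' @return list of class `subtraction_params`.
#' @export
subtraction_params <- function(alpha = 2.0, beta = 0.01, epsilon = 1.47,
                               alpha_d = 0.85) {
  if (alpha < 1) stop("alpha (over-subtraction factor) must be >= 1")
  if (beta <= 0 || beta >= 1) stop("beta (spectral floor) must be in (0, 1)")
  if (epsilon < 1) stop("epsilon (bias compensation) must be >= 1")
  if (alpha_d <= 0 || alpha_d >= 1) stop("alpha_d must be in (0, 1)")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 alpha_d = alpha_d), class = "subtraction_params")
}

#' Short-time Fourier transform of a frame matrix
#'
#' Zero-pads each (already windowed) frame to `fft_size` and returns the
#' one-sided spectra, `K = fft_size/2 + 1` bins per frame.
#'
#' @param fm a [frame_signal()] result.
#' @param fft_size FFT length, a power of two >= the frame length.
#' @return list of class `spectrum_matrix`: `complex_spectra`, `power`,
#'   `phase` (all `f_n x K`), plus the framing metadata needed for
#'   reconstruction.
#' @export
stft <- function(fm, fft_size = 256L) {
  stopifnot(inherits(fm, "frame_matrix"))
  fft_size <- as.integer(fft_size)
  L <- fm$frame_length
  if (fft_size < L) stop("fft_size must be >= frame length (", L, ")")
  if (bitwAnd(fft_size, fft_size - 1L) != 0L)
    stop("fft_size must be a power of two")
  f_n <- nrow(fm$frames)
  padded <- matrix(0, nrow = fft_size, ncol = f_n)
  padded[seq_len(L), ] <- t(fm$frames)
  spec <- stats::mvfft(padded)              # fft_size x f_n
  K <- fft_size %/% 2L + 1L
  cs <- t(spec[seq_len(K), , drop = FALSE]) # f_n x K one-sided
  structure(list(complex_spectra = cs, power = Mod(cs)^2, phase = Arg(cs),
                 fft_size = fft_size, frame_length = L,
                 frame_shift = fm$frame_shift, window = fm$window,
                 rate = fm$rate, n_frames = f_n),
            class = "spectrum_matrix")
}

#' Sound-presence probability by two-stage minima tracking
#'
#' Estimates, per frame and frequency bin, whether a sound (as opposed to
#' stationary background) is present. The noisy power is smoothed first
#' across frequency (3-bin moving average) and then across time
#' (recursive, factor 0.8); a running minimum over a sliding window of
#' `min_track_window` frames (tracked through sub-windows) provides the
#' noise floor; bins whose smoothed power exceeds `snr_threshold` times
#' the floor are flagged as sound-present, and the indicator is
#' recursively smoothed with factor `p_smooth` to give `p` in \[0, 1\].
#'
#' @param power `f_n x K` non-negative noisy power matrix.
#' @param min_track_window minimum-tracking window length in frames.
#' @param snr_threshold a-posteriori SNR ratio flagging sound presence.
#' @param p_smooth recursive smoothing factor for the presence indicator.
#' @return `f_n x K` matrix with entries in \[0, 1\].
#' @export
sound_presence_prob <- function(power, min_track_window = 40L,
                                snr_threshold = 5, p_smooth = 0.9) {
  f_n <- nrow(power); K <- ncol(power)
  # stage 1: frequency smoothing (3-bin moving average)
  sf <- power
  if (K >= 3L) {
    sf[, 2:(K - 1)] <- (power[, 1:(K - 2)] + power[, 2:(K - 1)] +
                          power[, 3:K]) / 3
  }
  # stage 2: time smoothing + sub-window minimum tracking
  n_sub <- 4L
  sub_len <- max(1L, as.integer(ceiling(min_track_window / n_sub)))
  s_prev <- sf[1L, ]
  sub_min <- s_prev                 # minimum inside the current sub-window
  stored <- matrix(Inf, n_sub, K)   # minima of completed sub-windows
  p <- matrix(0, f_n, K)
  p_prev <- rep(0, K)
  for (l in seq_len(f_n)) {
    s <- 0.8 * s_prev + 0.2 * sf[l, ]
    s_prev <- s
    sub_min <- pmin(sub_min, s)
    if (l %% sub_len == 0L) {
      stored <- rbind(stored[-1L, , drop = FALSE], sub_min)
      sub_min <- s
    }
    s_min <- pmin(apply(stored, 2L, min), sub_min)
    indicator <- as.numeric(s > snr_threshold * pmax(s_min, .Machine$double.xmin))
    # asymmetric smoothing: instantaneous rise, smoothed decay -- a lagged
    # rise would leak sound onsets into the noise estimate
    p_prev <- pmax(indicator, p_smooth * p_prev + (1 - p_smooth) * indicator)
    p[l, ] <- p_prev
  }
  p
}

#' IMCRA noise-power estimation
#'
#' Tracks the noise power spectrum by recursively averaging past noisy
#' power values, gated by the conditional sound-presence probability:
#' with per-bin smoothing `a = alpha_d + (1 - alpha_d) p(l,k)`, the
#' average updates as `lam <- a * lam + (1 - a) * |Y(l,k)|^2`, and the
#' reported estimate is `epsilon * lam` (bias compensation). Where sound
#' is confidently present (`p = 1`) the average freezes, so speech power
#' does not leak into the noise estimate.
#'
#' The average is initialised to the mean power of the first five frames.
#'
#' @param power `f_n x K` non-negative noisy power matrix (>= 2 frames).
#' @param params a [subtraction_params()].
#' @param p optional precomputed presence-probability matrix; when `NULL`
#'   it is obtained from [sound_presence_prob()].
#' @param ... passed to [sound_presence_prob()] when `p` is `NULL`.
#' @return list of class `noise_estimate`: `lambda_hat` (`f_n x K`
#'   compensated noise power) and `p_speech` (the probability used).
#' @export
imcra_noise <- function(power, params = subtraction_params(), p = NULL, ...) {
  if (!is.matrix(power) || nrow(power) < 2L)
    stop("power must be a matrix with at least 2 frames")
  if (any(power < 0)) stop("power matrix must be non-negative")
  if (is.null(p)) p <- sound_presence_prob(power, ...)
  if (!all(dim(p) == dim(power))) stop("p must match the power matrix shape")
  f_n <- nrow(power); K <- ncol(power)
  lam <- colMeans(power[seq_len(min(5L, f_n)), , drop = FALSE])
  lambda_hat <- matrix(0, f_n, K)
  for (l in seq_len(f_n)) {
    a <- params$alpha_d + (1 - params$alpha_d) * p[l, ]
    lam <- a * lam + (1 - a) * power[l, ]
    lambda_hat[l, ] <- params$epsilon * lam
  }
  structure(list(lambda_hat = lambda_hat, p_speech = p),
            class = "noise_estimate")
}

#' Over-subtraction with spectral floor
#'
#' Per frame and bin: subtract `alpha` times the estimated noise power
#' from the noisy power where the noisy power is at least that large,
#' otherwise fall back to the floor `beta` times the noise power. The
#' output is non-negative everywhere.
#'
#' @param power `f_n x K` noisy power matrix.
#' @param noise a [imcra_noise()] result, or a matrix of noise power.
#' @param params a [subtraction_params()].
#' @return clean power matrix of the same shape.
#' @export
spectral_subtract <- function(power, noise, params = subtraction_params()) {
  lam <- if (inherits(noise, "noise_estimate")) noise$lambda_hat else noise
  if (!all(dim(lam) == dim(power)))
    stop("noise estimate shape does not match the power matrix")
  sub <- params$alpha * lam
  out <- ifelse(power >= sub, power - sub, params$beta * lam)
  out
}

#' Reconstruct a waveform from modified power spectra
#'
#' Combines `sqrt(clean_power)` with the noisy phase, inverts each frame
#' by inverse FFT, and overlap-adds with window-sum normalisation (the
#' analysis window is divided out wherever the overlapped window sum is
#' nonzero), so an unmodified power matrix round-trips to the original
#' interior samples exactly.
#'
#' @param clean_power `f_n x K` non-negative power matrix.
#' @param phase `f_n x K` phase matrix (radians), usually the noisy phase.
#' @param sm the [stft()] result the spectra came from (framing metadata).
#' @param n_samples desired output length; defaults to the framed span.
#' @return a [waveform()].
#' @export
reconstruct <- function(clean_power, phase, sm, n_samples = NULL) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  if (!all(dim(clean_power) == dim(phase)) ||
      nrow(clean_power) != sm$n_frames ||
      ncol(clean_power) != sm$fft_size %/% 2L + 1L)
    stop("clean_power/phase shapes inconsistent with the analysis STFT")
  if (any(clean_power < 0)) stop("clean_power must be non-negative")
  f_n <- sm$n_frames; L <- sm$frame_length; inc <- sm$frame_shift
  nfft <- sm$fft_size; K <- ncol(clean_power)
  one_sided <- sqrt(clean_power) * complex(argument = phase)
  # conjugate-symmetric full spectrum, then per-frame inverse FFT
  full <- matrix(0 + 0i, nfft, f_n)
  full[seq_len(K), ] <- t(one_sided)
  if (nfft > 2L)
    full[seq(nfft, K + 1L), ] <- Conj(t(one_sided[, 2:(K - 1L), drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / nfft   # nfft x f_n
  span <- (f_n - 1L) * inc + L
  if (is.null(n_samples)) n_samples <- span
  out <- numeric(max(span, n_samples))
  wsum <- numeric(max(span, n_samples))
  for (i in seq_len(f_n)) {
    idx <- (i - 1L) * inc + seq_len(L)
    out[idx] <- out[idx] + frames[seq_len(L), i]
    wsum[idx] <- wsum[idx] + sm$window
  }
  nz <- wsum > 1e-8
  out[nz] <- out[nz] / wsum[nz]
  waveform(out[seq_len(n_samples)], sm$rate)
}

#' Full denoising chain
#'
#' Frames the waveform with a Hamming window, estimates the noise power
#' spectrum by IMCRA, removes it by over-subtraction with a spectral
#' floor, and reconstructs by weighted overlap-add reusing the noisy
#' phase. The output has the same length and rate as the input.
#'
#' @param w a [waveform()].
#' @param config a [pig_config()].
#' @return denoised [waveform()].
#' @export
denoise <- function(w, config = pig_config()) {
  w <- as_waveform(w)
  dn <- config$denoise
  L <- config$preprocess$frame_length
  inc <- config$preprocess$frame_shift
  fm <- frame_signal(w, L, inc, hamming_window(L))
  sm <- stft(fm, dn$fft_size)
  params <- subtraction_params(dn$alpha, dn$beta, dn$epsilon, dn$alpha_d)
  noise <- imcra_noise(sm$power, params,
                       min_track_window = dn$min_track_window,
                       snr_threshold = dn$snr_threshold,
                       p_smooth = dn$p_smooth)
  clean <- spectral_subtract(sm$power, noise, params)
  reconstruct(clean, sm$phase, sm, n_samples = length(w$samples))
}
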