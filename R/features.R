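#' Hertz to mel conversion
#'
#' `mel = 2595 log10(1 + f/700)`; strictly increasing, mel(0) = 0.
#'
#' @param f frequency in Hz (non-negative, vectorised).
#' @return mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  2595 * log10(1 + f / 700)
}

#' Mel to Hertz conversion (inverse of [hz_to_mel()])
#' @param mel mel value(s), non-negative.
#' @return frequency in Hz.
#' @export
mel_to_hz <- function(mel) {
  if (any(mel < 0)) stop("mel value must be non-negative")
  700 * (10^(mel / 2595) - 1)
}

#' Triangular mel filter bank
#'
#' Builds `M` triangular filters over one-sided FFT bins. The `M + 2`
#' edge frequencies are equally spaced on the mel axis between `f_low`
#' and `f_high` and mapped to bin indices `f(m) = round(fft_size * hz /
#' rate)`; filter `m` rises linearly from bin `f(m-1)` to a peak of 1 at
#' `f(m)` and falls to zero at `f(m+1)`.
#'
#' @param n_mels number of filters `M` (>= 2).
#' @param fft_size FFT length used by the analysis.
#' @param rate sampling rate in Hz.
#' @param f_low,f_high band edges in Hz, `f_low < f_high <= rate/2`.
#' @return list of class `mel_filterbank`: `weights` (`M x K`),
#'   `band_edges` (`M + 2` bin indices, 0-based like the FFT bins),
#'   `n_mels`, `fft_size`, `rate`.
#' @export
mel_filterbank <- function(n_mels = 24L, fft_size = 256L, rate = 8000,
                           f_low = 0, f_high = rate / 2) {
  if (n_mels < 2L) stop("at least 2 mel filters are required")
  if (!(f_low < f_high && f_high <= rate / 2))
    stop("band edges must satisfy f_low < f_high <= rate/2")
  K <- fft_size %/% 2L + 1L
  mel_edges <- seq(hz_to_mel(f_low), hz_to_mel(f_high), length.out = n_mels + 2L)
  hz_edges <- mel_to_hz(mel_edges)
  bins <- round(fft_size * hz_edges / rate)      # 0-based bin indices
  if (any(diff(bins) < 1))
    stop("infeasible mel band: adjacent filter edges collapse onto the ",
         "same FFT bin (fewer usable bins than filters)")
  k <- 0:(K - 1L)
  weights <- matrix(0, n_mels, K)
  for (m in seq_len(n_mels)) {
    lo <- bins[m]; mid <- bins[m + 1L]; hi <- bins[m + 2L]
    rising <- k >= lo & k < mid
    falling <- k >= mid & k < hi
    weights[m, rising] <- (k[rising] - lo) / (mid - lo)
    weights[m, falling] <- (hi - k[falling]) / (hi - mid)
    weights[m, mid + 1L] <- 1   # peak bin (k = f(m)), 0-based -> column mid+1
  }
  structure(list(weights = weights, band_edges = bins, n_mels = n_mels,
                 fft_size = fft_size, rate = rate,
                 f_low = f_low, f_high = f_high),
            class = "mel_filterbank")
}

#' MFCC from a power-spectrum matrix
#'
#' Filter-bank energies `S(i,m) = sum_k E(i,k) H_m(k)` are floored,
#' logged, and cosine-transformed:
#' `mfcc(i,n) = sum_m C(i,m) cos(pi n (2m+1) / (2M))`, keeping
#' coefficients `n = 1..n_coeff` (the 0th, overall-level coefficient is
#' dropped).
#'
#' @param power `f_n x K` one-sided power matrix.
#' @param bank a [mel_filterbank()].
#' @param n_coeff number of cepstral coefficients (default 12, <= M).
#' @param log_floor filter-bank energies are clamped at this value before
#'   the log, so silent frames stay finite.
#' @return `f_n x n_coeff` coefficient matrix.
#' @export
mfcc_from_power <- function(power, bank, n_coeff = 12L, log_floor = 1e-10) {
  stopifnot(inherits(bank, "mel_filterbank"))
  M <- bank$n_mels
  if (n_coeff > M) stop("n_coeff must not exceed the number of mel filters")
  if (ncol(power) != ncol(bank$weights))
    stop("power matrix has ", ncol(power), " bins but the filter bank expects ",
         ncol(bank$weights))
  S <- power %*% t(bank$weights)                 # f_n x M
  C <- log(pmax(S, log_floor))
  m <- 0:(M - 1L)
  dct_basis <- sapply(seq_len(n_coeff), function(n) cos(pi * n * (2 * m + 1) / (2 * M)))
  C %*% dct_basis                                # f_n x n_coeff
}

#' MFCC of a frame matrix
#'
#' Convenience wrapper: [stft()] power spectra piped into
#' [mfcc_from_power()].
#'
#' @inheritParams mfcc_from_power
#' @param fm a [frame_signal()] result.
#' @param fft_size FFT length (defaults to the filter bank's).
#' @return `f_n x n_coeff` coefficient matrix.
#' @export
mfcc <- function(fm, bank, n_coeff = 12L, fft_size = bank$fft_size,
                 log_floor = 1e-10) {
  sm <- stft(fm, fft_size)
  mfcc_from_power(sm$power, bank, n_coeff, log_floor)
}

#' First-order differential coefficients
#'
#' Frame-to-frame difference capturing the dynamics of the cepstral
#' trajectory: `delta(i) = c(i) - c(i-1)`, with the first frame's delta
#' set to zero. A 2-frame regression variant is available for smoother
#' derivatives.
#'
#' @param coeffs `f_n x p` coefficient matrix.
#' @param mode `"diff"` (simple first difference) or `"regression"`
#'   (least-squares slope over a +/-2 frame window).
#' @return matrix of the same shape.
#' @export
delta_coeffs <- function(coeffs, mode = c("diff", "regression")) {
  mode <- match.arg(mode)
  coeffs <- as.matrix(coeffs)
  f_n <- nrow(coeffs)
  if (f_n == 1L) return(coeffs * 0)
  if (mode == "diff") {
    rbind(matrix(0, 1L, ncol(coeffs)), diff(coeffs))
  } else {
    pad <- rbind(coeffs[1L, , drop = FALSE], coeffs[1L, , drop = FALSE],
                 coeffs,
                 coeffs[f_n, , drop = FALSE], coeffs[f_n, , drop = FALSE])
    (2 * (pad[5:(f_n + 4L), , drop = FALSE] - pad[1:f_n, , drop = FALSE]) +
        (pad[4:(f_n + 3L), , drop = FALSE] - pad[2:(f_n + 1L), , drop = FALSE])) / 10
  }
}

#' Extract the 24-dimensional feature matrix from a clip
#'
#' Runs the full front end: activity gate, spectral-subtraction
#' denoising, double-threshold endpoint detection on the denoised
#' signal, re-framing of the voiced segment, and per-frame extraction of
#' 12 MFCC plus 12 delta-MFCC.
#'
#' A clip failing the activity gate is not an error: the returned object
#' has `active = FALSE` and no features, so callers can distinguish
#' "silence" from failures. If no endpoint is found in an active clip,
#' features fall back to the whole clip (`endpoints$valid` records this).
#'
#' @param w a [waveform()]; its rate must match `config$rate`.
#' @param config a [pig_config()].
#' @return list of class `pig_features`: `features` (`f_n x 24` matrix or
#'   `NULL` when inactive), `active`, `endpoints`, `rate`.
#' @export
extract_features <- function(w, config = pig_config()) {
  w <- as_waveform(w)
  if (w$rate != config$rate)
    stop("waveform rate ", w$rate, " does not match configured rate ",
         config$rate, " (no resampling is performed)")
  inactive <- structure(list(features = NULL, active = FALSE,
                             endpoints = NULL, rate = w$rate),
                        class = "pig_features")
  if (!activity_gate(w, config$preprocess$energy_threshold)) return(inactive)

  clean <- denoise(w, config)
  L <- config$preprocess$frame_length
  inc <- config$preprocess$frame_shift
  fm <- frame_signal(clean, L, inc, hamming_window(L))
  e <- short_time_energy(fm)
  z <- zero_crossing_rate(fm)
  ep_cfg <- config$preprocess$endpoint
  ep <- detect_endpoints(
    e, z,
    high_energy = ep_cfg$high_frac * max(e),
    low_energy = ep_cfg$low_frac * max(e),
    zcr_thresh = ep_cfg$zcr_factor * mean(z[seq_len(min(5L, length(z)))]),
    min_voiced_frames = ep_cfg$min_frames
  )
  seg <- fm
  if (ep$valid) {
    lo <- (ep$start_frame - 1L) * inc + 1L
    hi <- min((ep$end_frame - 1L) * inc + L, length(clean$samples))
    if (hi - lo + 1L >= L)
      seg <- frame_signal(waveform(clean$samples[lo:hi], clean$rate),
                          L, inc, hamming_window(L))
  }
  ft <- config$features
  bank <- mel_filterbank(ft$n_mels, config$denoise$fft_size, config$rate,
                         ft$f_low, ft$f_high)
  cc <- mfcc(seg, bank, ft$n_mfcc, log_floor = ft$log_floor)
  dd <- delta_coeffs(cc, mode = ft$delta_mode)
  feats <- cbind(cc, dd)
  colnames(feats) <- c(paste0("mfcc", seq_len(ncol(cc))),
                       paste0("dmfcc", seq_len(ncol(dd))))
  structure(list(features = feats, active = TRUE, endpoints = ep,
                 rate = w$rate),
            class = "pig_features")
}

#' @export
print.pig_features <- function(x, ...) {
  if (!x$active) {
    cat("<pig_features: inactive clip (below energy gate)>\n")
  } else {
    cat(sprintf("<pig_features: %d frames x %d dims>\n",
                nrow(x$features), ncol(x$features)))
  }
  invisible(x)
}
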