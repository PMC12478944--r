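#' Total energy of a waveform
#'
#' The clip-level activity statistic: the sum of squared samples over the
#' whole recording.
#'
#' @param w a [waveform()] or numeric vector.
#' @return non-negative scalar energy.
#' @export
sound_energy <- function(w) {
  w <- as_waveform(w)
  sum(w$samples^2)
}

#' Energy-based activity gate
#'
#' Decides whether a clip contains enough acoustic activity to be worth
#' analysing. Quiet-pen background stays well below the default threshold
#' of 40 (for 1 s clips at 8 kHz on the \[-1, 1\] PCM scale), while cough
#' and scream events exceed 200. Energy exactly equal to the threshold
#' passes.
#'
#' @param w a [waveform()].
#' @param threshold non-negative energy threshold (default 40).
#' @return logical: `TRUE` if the clip is active.
#' @export
activity_gate <- function(w, threshold = 40) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single non-negative number")
  sound_energy(w) >= threshold
}

#' Hamming window
#'
#' `w(n) = 0.54 - 0.46 cos(2 pi n / (L - 1))`, `n = 0, ..., L-1`.
#'
#' @param L window length in samples (>= 1).
#' @return numeric vector of length `L`, symmetric, values in \[0.08, 1\].
#' @export
hamming_window <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != floor(L))
    stop("L must be a single integer >= 1")
  if (L == 1L) return(1)
  n <- 0:(L - 1)
  0.54 - 0.46 * cos(2 * pi * n / (L - 1))
}

#' Split a waveform into windowed overlapping frames
#'
#' Frame i (1-based) holds `x((i-1)*inc + n) * window(n)` for
#' `n = 0..L-1`; a trailing partial frame is dropped, so the frame count
#' is `floor((N - L)/inc) + 1`.
#'
#' @param w a [waveform()].
#' @param L frame length in samples; must not exceed the signal length.
#' @param inc frame shift in samples, `1 <= inc <= L`.
#' @param window length-`L` weight vector; defaults to [hamming_window()].
#' @return list of class `frame_matrix`: `frames` (`f_n x L` matrix),
#'   `frame_length`, `frame_shift`, `window`, `rate`.
#' @export
frame_signal <- function(w, L = 256L, inc = 128L,
                         window = hamming_window(L)) {
  w <- as_waveform(w)
  N <- length(w$samples)
  L <- as.integer(L); inc <- as.integer(inc)
  if (L > N) stop("signal shorter than one frame (", N, " < ", L, " samples)")
  if (inc < 1L || inc > L) stop("frame shift must satisfy 1 <= inc <= L")
  if (length(window) != L) stop("window length must equal frame length")
  f_n <- (N - L) %/% inc + 1L
  starts <- (seq_len(f_n) - 1L) * inc
  idx <- outer(starts, seq_len(L), `+`)     # f_n x L sample indices
  frames <- matrix(w$samples[idx], nrow = f_n) *
    matrix(window, nrow = f_n, ncol = L, byrow = TRUE)
  structure(list(frames = frames, frame_length = L, frame_shift = inc,
                 window = as.numeric(window), rate = w$rate),
            class = "frame_matrix")
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf("<frame_matrix: %d frames x %d samples, shift %d @ %g Hz>\n",
              nrow(x$frames), x$frame_length, x$frame_shift, x$rate))
  invisible(x)
}

#' Short-time energy per frame
#'
#' @param fm a [frame_signal()] result.
#' @return non-negative numeric vector, one energy per frame.
#' @export
short_time_energy <- function(fm) {
  stopifnot(inherits(fm, "frame_matrix"))
  rowSums(fm$frames^2)
}

#' Short-time zero-crossing rate per frame
#'
#' Counts sign changes between adjacent samples inside each frame, with
#' the sign convention `sgn(y) = 1` for `y >= 0`, `-1` otherwise. The
#' result is integer-valued in `[0, L-1]` and invariant under positive
#' rescaling of the signal.
#'
#' @param fm a [frame_signal()] result.
#' @return numeric vector, one count per frame.
#' @export
zero_crossing_rate <- function(fm) {
  stopifnot(inherits(fm, "frame_matrix"))
  s <- ifelse(fm$frames >= 0, 1, -1)
  L <- ncol(s)
  if (L < 2L) return(rep(0, nrow(s)))
  0.5 * rowSums(abs(s[, -1L, drop = FALSE] - s[, -L, drop = FALSE]))
}

#' Double-threshold endpoint detection
#'
#' Locates the voiced segment of a clip from its short-time energy and
#' zero-crossing rate. The earliest run of at least `min_voiced_frames`
#' consecutive frames with energy >= `high_energy` anchors the segment;
#' its start is extended backward and its end forward while energy stays
#' above `low_energy` or the zero-crossing rate stays above `zcr_thresh`
#' (the ZCR term recovers low-energy fricative-like onsets and tails).
#'
#' When a threshold is `NULL` it defaults to the conventional VAD values:
#' `high = 0.25 * max(energy)`, `low = 0.05 * max(energy)`,
#' `zcr_thresh = 1.5 *` mean ZCR of the first five frames.
#'
#' @param energy per-frame short-time energies.
#' @param zcr per-frame zero-crossing rates (same length).
#' @param high_energy,low_energy energy thresholds, `high >= low >= 0`.
#' @param zcr_thresh zero-crossing-rate threshold.
#' @param min_voiced_frames minimum run length above `high_energy`.
#' @return list of class `endpoint_result`: `start_frame`, `end_frame`
#'   (1-based, inclusive) and `valid`. When no qualifying run exists,
#'   `valid` is `FALSE` and the frame fields are `NA`.
#' @export
detect_endpoints <- function(energy, zcr,
                             high_energy = NULL, low_energy = NULL,
                             zcr_thresh = NULL, min_voiced_frames = 3L) {
  if (length(energy) != length(zcr))
    stop("energy and zcr vectors must have the same length")
  f_n <- length(energy)
  if (is.null(high_energy)) high_energy <- 0.25 * max(energy)
  if (is.null(low_energy)) low_energy <- 0.05 * max(energy)
  if (is.null(zcr_thresh))
    zcr_thresh <- 1.5 * mean(zcr[seq_len(min(5L, f_n))])
  if (low_energy < 0 || high_energy < low_energy)
    stop("thresholds must satisfy high_energy >= low_energy >= 0")

  invalid <- structure(list(start_frame = NA_integer_, end_frame = NA_integer_,
                            valid = FALSE), class = "endpoint_result")
  above <- energy >= high_energy
  if (!any(above)) return(invalid)
  r <- rle(above)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_voiced_frames)
  if (!length(ok)) return(invalid)
  start <- run_starts[ok[1L]]
  end <- run_ends[ok[1L]]
  hold <- energy > low_energy | zcr > zcr_thresh
  while (start > 1L && hold[start - 1L]) start <- start - 1L
  while (end < f_n && hold[end + 1L]) end <- end + 1L
  structure(list(start_frame = start, end_frame = end, valid = TRUE),
            class = "endpoint_result")
}

#' @export
print.endpoint_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<endpoints: frames %d..%d>\n", x$start_frame, x$end_frame))
  } else {
    cat("<endpoints: no voiced segment found>\n")
  }
  invisible(x)
}
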