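#' Construct a waveform object
#'
#' A waveform is the unit every pipeline stage consumes and produces:
#' a finite mono sample vector on the dimensionless PCM scale (nominally
#' in \[-1, 1\]) plus its sampling rate.
#'
#' @param samples numeric vector of amplitudes; must be non-empty and finite.
#' @param rate sampling rate in samples/second (default 8000).
#' @return list of class `waveform` with elements `samples` and `rate`.
#' @export
waveform <- function(samples, rate = 8000) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("sampling rate must be a single positive number")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), energy %.3g>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              sum(x$samples^2)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

as_waveform <- function(w) {
  if (inherits(w, "waveform")) return(w)
  if (is.numeric(w)) return(waveform(w))
  stop("expected a waveform or numeric vector")
}

#' Read a mono WAV file
#'
#' Parses a RIFF/WAVE file containing 16-bit integer PCM or 32-bit IEEE
#' float samples. Integer samples are normalised to \[-1, 1\] by 1/32768.
#' Stereo files and, when `expected_rate` is given, rate mismatches are
#' rejected with an explicit error: resampling is out of scope.
#'
#' @param path path to a WAV file.
#' @param expected_rate if non-NULL, the sampling rate the file must have.
#' @return a [waveform()].
#' @export
read_wav <- function(path, expected_rate = NULL) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        rate         = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$channels != 1L)
    stop("expected mono audio, got ", fmt$channels, " channels: ", path)
  if (!is.null(expected_rate) && fmt$rate != expected_rate)
    stop("sampling rate mismatch: file has ", fmt$rate,
         " Hz, expected ", expected_rate, " Hz (no resampling is performed)")

  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) %/% 4L, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits, " bits); only 16-bit PCM and 32-bit float are read")
  }
  waveform(x, fmt$rate)
}

#' Write a mono WAV file
#'
#' Inverse of [read_wav()] up to quantisation: `"float"` round-trips
#' exactly, `"pcm16"` to within 2^-15. Samples outside \[-1, 1\] are
#' clipped when writing PCM.
#'
#' @param w a [waveform()].
#' @param path output path.
#' @param format `"float"` (32-bit IEEE) or `"pcm16"` (16-bit integer).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("float", "pcm16")) {
  w <- as_waveform(w)
  format <- match.arg(format)
  n <- length(w$samples)
  bytes_per <- if (format == "float") 4L else 2L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  audio_format <- if (format == "float") 3L else 1L
  bits <- bytes_per * 8L
  writeBin(audio_format, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float") {
    writeBin(as.numeric(w$samples), con, 4, endian = "little")
  } else {
    q <- as.integer(round(pmin(pmax(w$samples, -1), 32767 / 32768) * 32768))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}

# seeded evaluation without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
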