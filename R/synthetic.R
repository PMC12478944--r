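#' Burst specification for a synthetic clip class
#'
#' Returns the default acoustic template of each synthetic class. The
#' classes emulate the spectral separation of real abnormal pig sounds —
#' cough-like events concentrate energy at low frequency with a fast
#' attack and short decay, scream-like events sit high with a longer
#' sustain — without claiming bioacoustic realism. "other" events are
#' broadband or tonal distractors.
#'
#' @param class_name one of `"cough_like"`, `"scream_like"`, `"other"`.
#' @return list: `class_name`, `band` (Hz low/high of the burst),
#'   `duration` (s range), `attack`, `decay` (s), `rms` amplitude target,
#'   `tonal` (logical: pure-tone variant allowed).
#' @export
burst_spec <- function(class_name = c("cough_like", "scream_like", "other")) {
  class_name <- match.arg(class_name)
  switch(class_name,
    cough_like = list(class_name = class_name, band = c(300, 800),
                      duration = c(0.15, 0.30), attack = 0.005, decay = 0.03,
                      rms = 0.25, tonal = FALSE),
    scream_like = list(class_name = class_name, band = c(1500, 3500),
                       duration = c(0.40, 0.70), attack = 0.02, decay = 0.03,
                       rms = 0.25, tonal = FALSE),
    other = list(class_name = class_name, band = c(100, 3900),
                 duration = c(0.20, 0.60), attack = 0.01, decay = 0.03,
                 rms = 0.25, tonal = TRUE)
  )
}

# stationary background noise of unit RMS
gen_noise <- function(n, kind = c("white", "pink", "fan_hum"), rate = 8000) {
  kind <- match.arg(kind)
  x <- switch(kind,
    white = stats::rnorm(n),
    pink = {
      # 1/f shaping by cumulative filtering of white noise (Voss-like IIR)
      w <- stats::rnorm(n)
      b <- signal::filter(signal::butter(1, 0.05, "low"), w)
      as.numeric(0.7 * b / stats::sd(b) + 0.3 * w)
    },
    fan_hum = {
      t <- (0:(n - 1)) / rate
      hum <- sin(2 * pi * 100 * t) + 0.5 * sin(2 * pi * 200 * t) +
        0.25 * sin(2 * pi * 300 * t)
      hum + 0.2 * stats::rnorm(n)
    })
  x / stats::sd(x)
}

#' Generate one synthetic 1-second clip with ground truth
#'
#' Builds silence + a band-limited burst shaped by an attack/decay
#' envelope + additive stationary background noise at a target SNR, and
#' returns the true burst interval for endpoint-detection tests. At the
#' default amplitudes a clip with a burst passes the energy gate
#' (threshold 40) and a burst-free clip fails it.
#'
#' @param class_name `"cough_like"`, `"scream_like"`, `"other"`, or
#'   `"silence"` (background floor only, no burst, fails the gate).
#' @param snr_db burst-to-noise SNR in dB; `Inf` disables the noise.
#' @param seed RNG seed (the same seed reproduces the clip exactly).
#' @param rate sampling rate (default 8000).
#' @param duration clip length in seconds (default 1).
#' @param noise_kind `"white"`, `"pink"`, or `"fan_hum"`.
#' @param spec optional [burst_spec()] override.
#' @param frame_length,frame_shift framing used to express the true burst
#'   interval in frames.
#' @return list: `wave` (a [waveform()]), `class`, `burst_samples`
#'   (first/last sample of the burst, or `NULL`), `burst_frames`
#'   (first/last frame fully determined by the burst support), `snr_db`,
#'   `seed`.
#' @export
gen_clip <- function(class_name = c("cough_like", "scream_like", "other",
                                    "silence"),
                     snr_db = 15, seed = 1L, rate = 8000, duration = 1,
                     noise_kind = c("white", "pink", "fan_hum"),
                     spec = NULL, frame_length = 256L, frame_shift = 128L) {
  class_name <- match.arg(class_name)
  noise_kind <- match.arg(noise_kind)
  n <- round(rate * duration)
  if (!is.finite(snr_db) && snr_db < 0) stop("snr_db must be finite or +Inf")
  with_seed(seed, {
    x <- numeric(n)
    burst_samples <- NULL
    if (class_name != "silence") {
      sp <- if (is.null(spec)) burst_spec(class_name) else spec
      if (any(sp$band >= rate / 2)) stop("burst band must lie below Nyquist")
      dur <- stats::runif(1, sp$duration[1], sp$duration[2])
      nb <- round(dur * rate)
      if (nb < 2L * frame_length)
        stop("burst shorter than two frames; increase its duration")
      # leading >= 0.1 s background margin: the noise tracker and the ZCR
      # baseline both take their reference from the first frames, as does a
      # triggered recorder's pre-roll
      lead <- min(round(0.1 * rate), max(0L, n - nb))
      tail_margin <- min(round(0.05 * rate), max(0L, n - nb - lead))
      start <- if (n - nb - tail_margin >= lead + 1L) {
        sample(seq.int(lead + 1L, n - nb - tail_margin + 1L), 1L)
      } else 1L
      carrier <- if (isTRUE(sp$tonal) && stats::runif(1) < 0.5) {
        f0 <- stats::runif(1, sp$band[1], sp$band[2])
        sin(2 * pi * f0 * (0:(nb - 1)) / rate + stats::runif(1, 0, 2 * pi))
      } else {
        bf <- signal::butter(4, c(sp$band[1], sp$band[2]) / (rate / 2), "pass")
        as.numeric(signal::filter(bf, stats::rnorm(nb + 200L)))[-(1:200)]
      }
      # compact-support envelope: raised-cosine attack and release around a
      # sustained body, so the declared burst interval IS the energy support
      t <- (0:(nb - 1)) / rate
      env <- rep(1, nb)
      na <- min(nb, round(sp$attack * rate))
      nr <- min(nb - na, round(sp$decay * rate))
      if (na > 0L) env[seq_len(na)] <- 0.5 * (1 - cos(pi * seq_len(na) / na))
      if (nr > 0L) env[nb - nr + seq_len(nr)] <-
          0.5 * (1 + cos(pi * seq_len(nr) / nr))
      burst <- carrier * env
      burst <- burst * sp$rms / max(stats::sd(burst), 1e-12)
      idx <- start:(start + nb - 1L)
      x[idx] <- x[idx] + burst
      burst_samples <- c(start, start + nb - 1L)
    }
    if (class_name == "silence") {
      x <- x + 0.005 * gen_noise(n, noise_kind, rate)   # energy ~ 0.2 << 40
    } else if (is.finite(snr_db)) {
      sig_pow <- mean(x[burst_samples[1]:burst_samples[2]]^2)
      noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
      x <- x + noise_sd * gen_noise(n, noise_kind, rate)
    }
    x <- pmin(pmax(x, -1), 1)
    burst_frames <- NULL
    if (!is.null(burst_samples)) {
      f_n <- (n - frame_length) %/% frame_shift + 1L
      first <- max(1L, ceiling((burst_samples[1] - frame_length) /
                                 frame_shift) + 1L)
      last <- min(f_n, (burst_samples[2] - 1L) %/% frame_shift + 1L)
      burst_frames <- c(first, last)
    }
    list(wave = waveform(x, rate), class = class_name,
         burst_samples = burst_samples, burst_frames = burst_frames,
         snr_db = snr_db, seed = seed)
  })
}

#' Generate a Gaussian feature-space fixture
#'
#' Draws labelled Gaussian clusters in `d` dimensions (default 24, the
#' MFCC + delta-MFCC feature dimension): class centres sit at distance
#' `separation` apart (placed deterministically from the seed on a
#' random direction frame), instances scatter isotropically with
#' standard deviation `spread`. Used for fast SVDD oracle and
#' label-noise robustness experiments.
#'
#' @param n_per_class instances per class (>= 2).
#' @param n_classes number of classes (default 2).
#' @param separation distance between class centres.
#' @param spread within-class standard deviation.
#' @param d dimensionality (default 24).
#' @param seed RNG seed.
#' @return list: `x` (`n x d` matrix), `labels` (integer class ids),
#'   `centers` (`n_classes x d`).
#' @export
gen_feature_set <- function(n_per_class, n_classes = 2L, separation = 6,
                            spread = 1, d = 24L, seed = 1L) {
  if (n_per_class < 2L) stop("need at least 2 instances per class")
  with_seed(seed, {
    dirs <- matrix(stats::rnorm(n_classes * d), n_classes)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    centers <- dirs * separation / sqrt(2)   # pairwise distance ~ separation
    n <- n_per_class * n_classes
    labels <- rep(seq_len(n_classes), each = n_per_class)
    x <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = spread), n)
    list(x = x, labels = labels, centers = centers)
  })
}

#' Inject label errors into a training set
#'
#' Reassigns exactly `round(fraction * q)` labels (chosen uniformly
#' without replacement) to a different class drawn uniformly from the
#' remaining classes, emulating human tagging errors. The flip mask is
#' returned for auditing.
#'
#' @param labels vector of class labels (>= 2 distinct values unless
#'   `fraction` is 0).
#' @param fraction fraction in \[0, 1\] of labels to corrupt.
#' @param seed RNG seed.
#' @return list: `labels` (corrupted), `flipped` (logical mask).
#' @export
inject_label_errors <- function(labels, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  q <- length(labels)
  n_flip <- round(fraction * q)
  flipped <- rep(FALSE, q)
  if (n_flip == 0L)
    return(list(labels = labels, flipped = flipped))
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("label errors need at least 2 distinct classes to flip between")
  with_seed(seed, {
    idx <- sample.int(q, n_flip)
    new_labels <- labels
    for (i in idx) {
      pool <- classes[classes != labels[i]]
      new_labels[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    flipped[idx] <- TRUE
    list(labels = new_labels, flipped = flipped)
  })
}

#' Write a batch of synthetic clips with a manifest
#'
#' Generates `n` clips of one class, writes them as float WAVs into
#' `dir`, and appends rows to `manifest.csv` (filename, class,
#' burst_start_frame, burst_end_frame, snr_db, seed).
#'
#' @param class_name synthetic class, see [gen_clip()].
#' @param n number of clips.
#' @param dir output directory (created if needed).
#' @param seed base seed; clip `i` uses `seed + i`.
#' @param snr_db,noise_kind passed to [gen_clip()].
#' @return the manifest data frame, invisibly.
#' @export
synth_batch <- function(class_name, n, dir, seed = 1L, snr_db = 15,
                        noise_kind = "white") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    clip <- gen_clip(class_name, snr_db = snr_db, seed = seed + i,
                     noise_kind = noise_kind)
    fn <- sprintf("%s_%04d.wav", class_name, i)
    write_wav(clip$wave, file.path(dir, fn))
    bf <- if (is.null(clip$burst_frames)) c(NA, NA) else clip$burst_frames
    rows[[i]] <- data.frame(filename = fn, class = class_name,
                            burst_start_frame = bf[1], burst_end_frame = bf[2],
                            snr_db = snr_db, seed = seed + i,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.table(manifest, mpath, sep = ",", row.names = FALSE,
                     col.names = !file.exists(mpath), append = file.exists(mpath))
  invisible(manifest)
}
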