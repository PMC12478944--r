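#' Label-noise robustness experiment
#'
#' Reproduces, on synthetic feature data, the tag-error tolerance
#' comparison between confidence-weighted and classical SVDD: a one-class
#' model is trained on `q` instances of a target class of which a
#' fraction are contaminating instances of a second class (mislabeled
#' points), then scored on held-out data from both classes (own-class
#' instances correct when inside the sphere, other-class when outside).
#'
#' Per replicate, `sigma` is fixed once from the clean training set
#' (median-heuristic) and `C` is shared by both models across all
#' contamination levels, so the curves isolate the effect of the
#' confidence weights — mirroring a deployment where hyperparameters are
#' tuned once on trusted data before errors creep into the tags.
#'
#' @param fractions contamination fractions (default 0, 5, 10, 15, 20%).
#' @param n_reps replicates per fraction (default 20).
#' @param q training-set size per replicate (default 200).
#' @param n_test_own,n_test_other held-out instances per replicate.
#' @param separation,spread,d geometry passed to [gen_feature_set()];
#'   the default separation 25 makes the contaminating class acoustically
#'   remote, as "other sounds" are from screams.
#' @param C penalty shared by both models (default 0.05, in the
#'   marginal-exclusion regime where a contaminating point's dual mass is
#'   comparable to its box bound).
#' @param seed base seed; replicate r uses `seed + 97 r`.
#' @return data frame: fraction, mean accuracy of weighted and classical
#'   models, and their gap.
#' @export
label_noise_experiment <- function(fractions = c(0, 0.05, 0.10, 0.15, 0.20),
                                   n_reps = 20L, q = 200L,
                                   n_test_own = 50L, n_test_other = 100L,
                                   separation = 25, spread = 1, d = 24L,
                                   C = 0.05, seed = 5000L) {
  acc <- array(0, c(2L, length(fractions), n_reps))
  for (r in seq_len(n_reps)) {
    n_per <- q + 150L
    fs <- gen_feature_set(n_per, 2L, separation, spread, d,
                          seed = seed + 97L * r)
    A <- fs$x[fs$labels == 1L, , drop = FALSE]
    B <- fs$x[fs$labels == 2L, , drop = FALSE]
    test <- rbind(A[q + seq_len(n_test_own), , drop = FALSE],
                  B[q + seq_len(n_test_other), , drop = FALSE])
    truth <- rep(c(1L, -1L), c(n_test_own, n_test_other))
    sg <- stats::median(stats::dist(scale(A[seq_len(q), , drop = FALSE])))
    for (fi in seq_along(fractions)) {
      k <- round(fractions[fi] * q)
      train <- rbind(A[seq_len(q - k), , drop = FALSE],
                     B[seq_len(k), , drop = FALSE])
      mw <- wsvdd(train, w = NULL, C = C, sigma = sg)
      mc <- wsvdd(train, w = 1, C = C, sigma = sg)
      acc[1L, fi, r] <- mean(decide(mw, test) == truth)
      acc[2L, fi, r] <- mean(decide(mc, test) == truth)
    }
  }
  data.frame(fraction = fractions,
             weighted = apply(acc[1L, , , drop = FALSE], 2L, mean),
             classical = apply(acc[2L, , , drop = FALSE], 2L, mean),
             gap = apply(acc[1L, , , drop = FALSE] - acc[2L, , , drop = FALSE],
                         2L, mean))
}

#' End-to-end synthetic clip benchmark
#'
#' Trains a two-sphere recogniser on synthetic cough-like and scream-like
#' clips and evaluates clip-level recognition (including "other"
#' distractor clips) through the full pipeline: gate, denoise, endpoint
#' detection, MFCC + delta-MFCC, per-frame two-sphere decisions, fusion
#' and majority vote.
#'
#' @param n_train clips per training class.
#' @param n_test clips per test class (cough, scream, other).
#' @param snr_db clip SNR for generation.
#' @param seed base seed; train/test clips use disjoint seed ranges.
#' @param config a [pig_config()].
#' @return list: `metrics` (a [evaluate_predictions()] report),
#'   `predictions`, `truth`, `model`.
#' @export
clip_benchmark <- function(n_train = 100L, n_test = 50L, snr_db = 15,
                           seed = 1L, config = pig_config()) {
  feats_of <- function(cls, n, base) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      ft <- extract_features(gen_clip(cls, snr_db = snr_db,
                                      seed = base + i)$wave, config)
      ft$features
    }))
  }
  base <- seed * 1000000L
  mm <- multi_svdd(feats_of("cough_like", n_train, base + 100000L),
                   feats_of("scream_like", n_train, base + 200000L),
                   max_train_frames = config$multisvdd$max_train_frames,
                   seed = seed)
  classes <- c(cough_like = "cough", scream_like = "scream", other = "other")
  pred <- character(0); truth <- character(0)
  for (ci in seq_along(classes)) {
    for (i in seq_len(n_test)) {
      clip <- gen_clip(names(classes)[ci], snr_db = snr_db,
                       seed = base + 300000L + 10000L * ci + i)
      pred <- c(pred, recognize_clip(mm, clip$wave, config)$label)
      truth <- c(truth, classes[[ci]])
    }
  }
  list(metrics = evaluate_predictions(pred, truth,
                                      classes = c("cough", "scream", "other")),
       predictions = pred, truth = truth, model = mm)
}
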