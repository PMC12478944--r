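#' Fuse the decisions of the two hyperspheres
#'
#' Combines the +/-1 outputs of the cough-model and scream-model SVDDs
#' into a frame label: inside exactly one sphere names the class, inside
#' neither is "other", inside both cannot be resolved ("unknown").
#'
#' @param d1 cough-sphere decision(s), each +1 or -1.
#' @param d2 scream-sphere decision(s), same length.
#' @return character vector of labels in
#'   `c("cough", "scream", "other", "unknown")`.
#' @export
fuse_decisions <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("decision vectors must have equal length")
  if (!all(d1 %in% c(-1, 1)) || !all(d2 %in% c(-1, 1)))
    stop("decisions must be +1 or -1")
  out <- character(length(d1))
  out[d1 == 1 & d2 == -1] <- "cough"
  out[d1 == -1 & d2 == 1] <- "scream"
  out[d1 == -1 & d2 == -1] <- "other"
  out[d1 == 1 & d2 == 1] <- "unknown"
  out
}

#' Majority vote over frame labels
#'
#' Returns the most frequent label in the sequence. "unknown" frames are
#' excluded from the count unless every frame is unknown. Ties are broken
#' by the priority cough > scream > other > unknown, which favours
#' flagging abnormality.
#'
#' @param frame_labels non-empty character vector of frame labels.
#' @param priority tie-break order, most preferred first.
#' @return single label.
#' @export
majority_vote <- function(frame_labels,
                          priority = c("cough", "scream", "other", "unknown")) {
  if (!length(frame_labels)) stop("cannot vote over an empty label sequence")
  labs <- frame_labels[frame_labels != "unknown"]
  if (!length(labs)) return("unknown")
  counts <- table(labs)
  top <- names(counts)[counts == max(counts)]
  priority[priority %in% top][1L]
}

#' Train the two-sphere multi-SVDD recogniser
#'
#' Trains one confidence-weighted SVDD on cough frames and one on scream
#' frames. Each model's `C` and `sigma` may be given per class (the two
#' spheres are tuned independently); `NULL` falls back to the [wsvdd()]
#' heuristics.
#'
#' @param cough_features `n1 x d` matrix of cough training frames.
#' @param scream_features `n2 x d` matrix of scream training frames.
#' @param C,sigma scalars or length-2 vectors `(cough, scream)`; `NULL`
#'   for the training-time heuristics.
#' @param weighted use subtractive-clustering confidences (`TRUE`) or
#'   unit weights, i.e. classical SVDD (`FALSE`).
#' @param max_train_frames cap per model; larger training sets are
#'   deterministically subsampled (seeded) to keep the quadratic solver
#'   tractable.
#' @param seed seed for the subsampling draw.
#' @return object of class `multi_svdd` with `model_cough`, `model_scream`.
#' @export
multi_svdd <- function(cough_features, scream_features,
                       C = NULL, sigma = NULL, weighted = TRUE,
                       max_train_frames = 2000L, seed = 1L) {
  pick <- function(par, i) {
    if (is.null(par)) NULL else if (length(par) >= 2L) par[[i]] else par
  }
  subsample <- function(x, k) {
    x <- as.matrix(x)
    if (nrow(x) <= max_train_frames) return(x)
    idx <- with_seed(seed + k, sample.int(nrow(x), max_train_frames))
    x[sort(idx), , drop = FALSE]
  }
  xc <- subsample(cough_features, 1L)
  xs <- subsample(scream_features, 2L)
  if (ncol(xc) != ncol(xs)) stop("the two training sets must share dimensionality")
  w_arg <- if (weighted) NULL else 1
  m1 <- wsvdd(xc, w = w_arg, C = pick(C, 1L), sigma = pick(sigma, 1L))
  m2 <- wsvdd(xs, w = w_arg, C = pick(C, 2L), sigma = pick(sigma, 2L))
  structure(list(model_cough = m1, model_scream = m2, weighted = weighted),
            class = "multi_svdd")
}

#' @export
print.multi_svdd <- function(x, ...) {
  cat("<multi_svdd>\n  cough : "); print(x$model_cough)
  cat("  scream: "); print(x$model_scream)
  invisible(x)
}

#' Recognise one clip
#'
#' Full inference path: feature extraction (gate, denoise, endpoints,
#' MFCC + delta-MFCC), per-frame decisions against both hyperspheres,
#' decision-table fusion, and clip-level majority vote.
#'
#' @param mm a [multi_svdd()] model.
#' @param w a [waveform()].
#' @param config a [pig_config()].
#' @return list of class `clip_recognition`: `label` (the vote; or
#'   `"inactive"` when the clip fails the energy gate), `frame_labels`,
#'   `d1`, `d2` (per-frame sphere decisions), `active`.
#' @export
recognize_clip <- function(mm, w, config = pig_config()) {
  stopifnot(inherits(mm, "multi_svdd"))
  ft <- extract_features(w, config)
  if (!ft$active)
    return(structure(list(label = "inactive", frame_labels = character(),
                          d1 = integer(), d2 = integer(), active = FALSE),
                     class = "clip_recognition"))
  d1 <- decide(mm$model_cough, ft$features)
  d2 <- decide(mm$model_scream, ft$features)
  frame_labels <- fuse_decisions(d1, d2)
  structure(list(label = majority_vote(frame_labels,
                                       config$multisvdd$vote_priority),
                 frame_labels = frame_labels, d1 = d1, d2 = d2,
                 active = TRUE),
            class = "clip_recognition")
}

#' @export
print.clip_recognition <- function(x, ...) {
  cat(sprintf("<clip_recognition: %s (%d frames: %s)>\n", x$label,
              length(x$frame_labels),
              paste(names(table(x$frame_labels)), table(x$frame_labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-class recognition metrics
#'
#' For each target class: `Accuracy = (TP + TN) / (P + N) * 100`,
#' `Precision = TP / (TP + FP) * 100`, `Recall = TP / (TP + FN) * 100`.
#' A metric whose denominator is zero is reported as `NA` (undefined)
#' rather than propagating `NaN`; macro averages skip undefined entries.
#'
#' @param predictions character vector of predicted labels.
#' @param truth character vector of true labels, same length.
#' @param classes classes to report; defaults to the classes present in
#'   `truth`.
#' @return list of class `metrics_report`: `per_class` (data frame with
#'   counts and percentage metrics) and `average` (macro means).
#' @export
evaluate_predictions <- function(predictions, truth, classes = NULL) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have the same length")
  if (is.null(classes)) classes <- sort(unique(truth))
  rows <- lapply(classes, function(cl) {
    tp <- sum(predictions == cl & truth == cl)
    fp <- sum(predictions == cl & truth != cl)
    fn <- sum(predictions != cl & truth == cl)
    tn <- sum(predictions != cl & truth != cl)
    pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
    data.frame(class = cl, tp = tp, tn = tn, fp = fp, fn = fn,
               accuracy = pct(tp + tn, tp + tn + fp + fn),
               precision = pct(tp, tp + fp),
               recall = pct(tp, tp + fn),
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  avg <- c(accuracy = mean(per_class$accuracy, na.rm = TRUE),
           precision = mean(per_class$precision, na.rm = TRUE),
           recall = mean(per_class$recall, na.rm = TRUE))
  structure(list(per_class = per_class, average = avg,
                 n = length(truth)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Recognition metrics (%):\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("Average: accuracy %.2f, precision %.2f, recall %.2f (n = %d)\n",
              x$average["accuracy"], x$average["precision"],
              x$average["recall"], x$n))
  invisible(x)
}

#' Group-aware k-fold partition
#'
#' Splits `n` indices into `k` folds of sizes differing by at most one.
#' When `groups` is given (e.g. the clip each frame came from), all
#' members of a group land in the same fold, so frames of one clip never
#' straddle the train/validation boundary.
#'
#' @param n number of instances.
#' @param k number of folds.
#' @param groups optional length-`n` group ids.
#' @param seed seed for the shuffle.
#' @return list of `k` integer index vectors (a partition of `1:n`).
#' @export
cv_folds <- function(n, k = 10L, groups = NULL, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (is.null(groups)) {
    if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
    perm <- with_seed(seed, sample.int(n))
    unname(split(perm, rep(seq_len(k), length.out = n)))
  } else {
    if (length(groups) != n) stop("groups must have length n")
    gids <- unique(groups)
    if (length(gids) < k) stop("fewer groups (", length(gids),
                               ") than folds (", k, ")")
    gperm <- with_seed(seed, sample(gids))
    gfold <- rep(seq_len(k), length.out = length(gperm))
    fold_map <- stats::setNames(gfold, as.character(gperm))
    lapply(unname(split(seq_len(n), fold_map[as.character(groups)])), unname)
  }
}

#' Cross-validated one-class fitness of a (C, sigma) pair
#'
#' The tuning criterion: negative mean k-fold recognition accuracy. Each
#' fold's model is trained on the remaining folds' instances (with
#' confidences recomputed on that training subset) and scores its
#' held-out instances; a held-out own-class instance is correct when it
#' falls inside the sphere (+1). Per fold `e_m = -N_m / N_m_total`, and
#' the fitness is their mean, so perfect recognition gives -1.
#'
#' @param x `q x d` one-class training matrix.
#' @param C,sigma hyperparameters under evaluation.
#' @param k number of folds.
#' @param weighted recompute confidences per training subset (`TRUE`) or
#'   use unit weights.
#' @param groups optional clip ids for group-aware folds.
#' @param seed fold-assignment seed.
#' @return scalar fitness in `[-1, 0]`.
#' @export
svdd_cv_fitness <- function(x, C, sigma, k = 10L, weighted = TRUE,
                            groups = NULL, seed = 1L) {
  x <- as.matrix(x)
  folds <- cv_folds(nrow(x), k, groups, seed)
  e <- vapply(folds, function(hold) {
    train <- x[-hold, , drop = FALSE]
    m <- wsvdd(train, w = if (weighted) NULL else 1, C = C, sigma = sigma)
    -mean(decide(m, x[hold, , drop = FALSE]) == 1L)
  }, numeric(1))
  mean(e)
}

#' Particle-swarm search for (C, sigma)
#'
#' Global-best PSO minimising [svdd_cv_fitness()]. Defaults follow the
#' published setting: 60 particles, 200 iterations, cognitive and social
#' accelerations 1.5 and 2.0, inertia 1.0 (no damping; a linear decay to
#' 0.4 is available via `inertia_decay`), ten folds. Velocities are
#' clamped to 20% of each search range, positions to the bounds. Fully
#' seeded and bit-reproducible.
#'
#' @param x one-class training matrix.
#' @param cfg PSO settings, e.g. `pig_config()$pso`; `swarm_size`,
#'   `max_iter`, `c1`, `c2`, `inertia`, `inertia_decay`, `folds`,
#'   `c_bounds`, `sigma_bounds`, `velocity_frac`, `seed`.
#' @param weighted,groups passed to [svdd_cv_fitness()].
#' @return list: `C`, `sigma`, `fitness`, and `trace` (best fitness per
#'   iteration, non-increasing).
#' @export
pso_tune <- function(x, cfg = pig_config()$pso, weighted = TRUE,
                     groups = NULL) {
  x <- as.matrix(x)
  lb <- c(cfg$c_bounds[1], cfg$sigma_bounds[1])
  ub <- c(cfg$c_bounds[2], cfg$sigma_bounds[2])
  if (any(lb <= 0) || any(ub <= lb)) stop("search bounds must be positive and ordered")
  n <- cfg$swarm_size
  if (n < 1L) stop("swarm_size must be >= 1")
  vmax <- cfg$velocity_frac * (ub - lb)
  # infeasible particles (box sum C*w < 1 cannot hold all the dual mass)
  # score 0, the worst possible fitness
  fit_of <- function(pos) tryCatch(
    svdd_cv_fitness(x, C = pos[1], sigma = pos[2], k = cfg$folds,
                    weighted = weighted, groups = groups, seed = cfg$seed),
    error = function(e) 0)
  with_seed(cfg$seed, {
    pos <- cbind(stats::runif(n, lb[1], ub[1]), stats::runif(n, lb[2], ub[2]))
    vel <- cbind(stats::runif(n, -vmax[1], vmax[1]),
                 stats::runif(n, -vmax[2], vmax[2]))
    if (n == 1L) vel[] <- 0   # degenerate swarm: evaluate in place
    pbest <- pos
    pbest_fit <- apply(pos, 1L, fit_of)
    g <- which.min(pbest_fit)
    gbest <- pos[g, ]; gbest_fit <- pbest_fit[g]
    trace <- numeric(cfg$max_iter)
    for (iter in seq_len(cfg$max_iter)) {
      inertia <- if (isTRUE(cfg$inertia_decay)) {
        cfg$inertia - (cfg$inertia - 0.4) * (iter - 1) / max(1L, cfg$max_iter - 1L)
      } else cfg$inertia
      r1 <- matrix(stats::runif(2L * n), n)
      r2 <- matrix(stats::runif(2L * n), n)
      vel <- inertia * vel + cfg$c1 * r1 * (pbest - pos) +
        cfg$c2 * r2 * (matrix(gbest, n, 2L, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, matrix(-vmax, n, 2L, byrow = TRUE)),
                  matrix(vmax, n, 2L, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lb, n, 2L, byrow = TRUE)),
                  matrix(ub, n, 2L, byrow = TRUE))
      fit <- apply(pos, 1L, fit_of)
      better <- fit < pbest_fit
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
      }
      trace[iter] <- gbest_fit
    }
    list(C = gbest[1], sigma = gbest[2], fitness = gbest_fit, trace = trace)
  })
}

#' Serialise a multi-SVDD model to JSON
#' @param mm a [multi_svdd()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multi_svdd <- function(mm, path) {
  stopifnot(inherits(mm, "multi_svdd"))
  strip <- function(m) {
    o <- unclass(m)
    o$support_vectors <- unname(as.matrix(o$support_vectors))
    o
  }
  jsonlite::write_json(list(format_version = 1L, weighted = mm$weighted,
                            model_cough = strip(mm$model_cough),
                            model_scream = strip(mm$model_scream)),
                       path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a multi-SVDD model written by [write_multi_svdd()]
#' @param path JSON file path.
#' @return a `multi_svdd` model.
#' @export
read_multi_svdd <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported model format version")
  fix <- function(o) {
    o$support_vectors <- as.matrix(o$support_vectors)
    o$norm_stats <- list(center = as.numeric(o$norm_stats$center),
                         scale = as.numeric(o$norm_stats$scale))
    structure(o, class = "wsvdd")
  }
  structure(list(model_cough = fix(obj$model_cough),
                 model_scream = fix(obj$model_scream),
                 weighted = obj$weighted),
            class = "multi_svdd")
}
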