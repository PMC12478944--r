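test_that("decision fusion implements the four-row lookup exactly", {
  expect_equal(fuse_decisions(1, -1), "cough")
  expect_equal(fuse_decisions(-1, 1), "scream")
  expect_equal(fuse_decisions(-1, -1), "other")
  expect_equal(fuse_decisions(1, 1), "unknown")
  # exhaustively: the mapping is total on {+1,-1}^2
  pairs <- expand.grid(d1 = c(1, -1), d2 = c(1, -1))
  labs <- fuse_decisions(pairs$d1, pairs$d2)
  expect_setequal(labs, c("cough", "scream", "other", "unknown"))
  expect_error(fuse_decisions(0, 1), "\\+1 or -1")
})

test_that("majority vote counts labels, skips unknown, breaks ties by priority", {
  expect_equal(majority_vote(c("cough", "cough", "other")), "cough")
  expect_equal(majority_vote(rep("other", 10)), "other")
  expect_equal(majority_vote(c("unknown", "unknown")), "unknown")
  expect_equal(majority_vote(c("unknown", "other")), "other")
  expect_equal(majority_vote(c("cough", "scream")), "cough")   # priority tie
  expect_error(majority_vote(character(0)), "empty")
  set.seed(51)
  for (i in 1:100) {
    labs <- sample(c("cough", "scream", "other", "unknown"),
                   sample(1:30, 1), replace = TRUE)
    expect_identical(majority_vote(labs), naive_vote(labs))
  }
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  perfect <- c("a", "b", "a")
  rep1 <- evaluate_predictions(perfect, perfect)
  expect_true(all(rep1$per_class$accuracy == 100))
  expect_true(all(rep1$per_class$precision == 100))
  expect_true(all(rep1$per_class$recall == 100))

  # TP=9, FP=1, FN=3, TN=7 for class "pos"
  truth <- c(rep("pos", 12), rep("neg", 8))
  pred <- c(rep("pos", 9), rep("neg", 3), "pos", rep("neg", 7))
  r <- evaluate_predictions(pred, truth, classes = "pos")
  expect_equal(r$per_class$tp, 9)
  expect_equal(r$per_class$fp, 1)
  expect_equal(r$per_class$fn, 3)
  expect_equal(r$per_class$tn, 7)
  expect_equal(r$per_class$precision, 90)
  expect_equal(r$per_class$recall, 75)
  expect_equal(r$per_class$accuracy, 80)

  # no predicted positives: precision undefined, not NaN
  r2 <- evaluate_predictions(rep("neg", 5), c("pos", rep("neg", 4)),
                             classes = "pos")
  expect_true(is.na(r2$per_class$precision))
  expect_false(is.nan(r2$per_class$precision))
  expect_error(evaluate_predictions("a", c("a", "b")), "same length")
})

test_that("metrics are invariant under joint permutation and self-consistent", {
  set.seed(52)
  truth <- sample(c("cough", "scream", "other"), 60, replace = TRUE)
  pred <- sample(c("cough", "scream", "other"), 60, replace = TRUE)
  r <- evaluate_predictions(pred, truth)
  perm <- sample(60)
  r_p <- evaluate_predictions(pred[perm], truth[perm])
  expect_equal(r$per_class, r_p$per_class)
  with(r$per_class, {
    expect_equal(precision, 100 * tp / (tp + fp))
    expect_equal(recall, 100 * tp / (tp + fn))
    expect_equal(tp + tn + fp + fn, rep(60, 3))
  })
})

test_that("cross-validation folds partition the data evenly", {
  folds <- cv_folds(47, 10, seed = 3)
  expect_length(folds, 10)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, 1:47)
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1)

  groups <- rep(1:12, each = 4)
  gf <- cv_folds(48, 4, groups = groups, seed = 3)
  expect_identical(sort(unname(unlist(gf))), 1:48)
  for (f in gf) {
    expect_true(all(table(groups[f]) == 4))   # whole clips stay together
  }
  expect_error(cv_folds(5, 10), "fewer samples")
})

test_that("the CV fitness equals a hand-rolled fold loop", {
  set.seed(53)
  x <- gen_feature_set(60, 1, separation = 0, spread = 1, d = 5, seed = 3)$x
  f <- svdd_cv_fitness(x, C = 0.5, sigma = 2, k = 10, weighted = FALSE,
                       seed = 9)
  manual <- mean(sapply(cv_folds(60, 10, seed = 9), function(h) {
    m <- wsvdd(x[-h, , drop = FALSE], w = 1, C = 0.5, sigma = 2)
    -mean(decide(m, x[h, , drop = FALSE]) == 1L)
  }))
  expect_equal(f, manual)
  expect_gte(f, -1); expect_lte(f, 0)
})

test_that("a single motionless particle keeps its seeded initial position", {
  x <- gen_feature_set(30, 1, separation = 0, spread = 1, d = 3, seed = 4)$x
  cfg <- pig_config()$pso
  cfg$swarm_size <- 1L; cfg$max_iter <- 3L; cfg$folds <- 5L; cfg$seed <- 17L
  res <- pso_tune(x, cfg)
  lb <- c(cfg$c_bounds[1], cfg$sigma_bounds[1])
  ub <- c(cfg$c_bounds[2], cfg$sigma_bounds[2])
  init <- withr::with_seed(17L, c(runif(1, lb[1], ub[1]), runif(1, lb[2], ub[2])))
  expect_equal(c(res$C, res$sigma), init, tolerance = 1e-12)
  expect_equal(res$fitness,
               svdd_cv_fitness(x, res$C, res$sigma, k = 5, seed = 17L))
})

test_that("swarm search is reproducible and its best trace never worsens", {
  x <- gen_feature_set(60, 1, separation = 0, spread = 1, d = 2, seed = 21)$x
  cfg <- pig_config()$pso
  cfg$swarm_size <- 12L; cfg$max_iter <- 30L; cfg$folds <- 5L; cfg$seed <- 11L
  r1 <- pso_tune(x, cfg)
  expect_true(all(diff(r1$trace) <= 0))
  expect_lte(r1$fitness, -0.9)       # easy compact landscape
  r2 <- pso_tune(x, cfg)
  expect_identical(r1, r2)
})

test_that("clip recognition is deterministic and rejects distractors", {
  feats_of <- function(cls, n, base) do.call(rbind, lapply(seq_len(n),
    function(i) extract_features(gen_clip(cls, seed = base + i)$wave)$features))
  mm <- multi_svdd(feats_of("cough_like", 15, 600),
                   feats_of("scream_like", 15, 700))
  cough <- gen_clip("cough_like", seed = 801)
  r1 <- recognize_clip(mm, cough$wave)
  r2 <- recognize_clip(mm, cough$wave)
  expect_identical(r1, r2)
  expect_equal(r1$label, "cough")
  expect_equal(recognize_clip(mm, gen_clip("scream_like", seed = 802)$wave)$label,
               "scream")
  expect_equal(recognize_clip(mm, gen_clip("other", seed = 803)$wave)$label,
               "other")
  inactive <- recognize_clip(mm, gen_clip("silence", seed = 804)$wave)
  expect_equal(inactive$label, "inactive")
  expect_false(inactive$active)
})

test_that("multi-sphere models survive a JSON round trip", {
  set.seed(54)
  mm <- multi_svdd(matrix(rnorm(40 * 24), 40), matrix(rnorm(40 * 24) + 3, 40))
  path <- tempfile(fileext = ".json")
  write_multi_svdd(mm, path)
  mm2 <- read_multi_svdd(path)
  z <- matrix(rnorm(6 * 24), 6)
  expect_equal(decide(mm$model_cough, z), decide(mm2$model_cough, z))
  expect_equal(decide(mm$model_scream, z), decide(mm2$model_scream, z))
  unlink(path)
})
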