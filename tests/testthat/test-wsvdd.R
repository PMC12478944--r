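test_that("densities for two points reduce to the closed form", {
  t_dist <- 3
  x <- rbind(c(0, 0), c(t_dist, 0))
  P <- subtractive_densities(x)
  # r_a = t/2, so both densities are 1 + exp(-t^2 / (t/4)^2) = 1 + e^-16
  expect_equal(P, rep(1 + exp(-16), 2), tolerance = 1e-15)
  expect_true(all(P >= 1))
  expect_error(subtractive_densities(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("densities on a seeded cloud match the double-loop oracle", {
  set.seed(41)
  x <- matrix(rnorm(60), 30, 2)
  expect_equal(subtractive_densities(x), naive_densities(x), tolerance = 1e-12)
  expect_true(all(subtractive_densities(x, radius_mode = "max_min") >= 1))
})

test_that("confidences map densities into (1/2, 1] with max 1", {
  expect_equal(cluster_confidences(c(4, 2)), c(1, 0.8))
  expect_equal(cluster_confidences(c(5, 5, 5)), rep(1, 3))
  expect_equal(cluster_confidences(c(10, 1e-9)), c(1, 0.5), tolerance = 1e-6)
  set.seed(42)
  P <- runif(50, 0.1, 9)
  w <- cluster_confidences(P)
  expect_true(all(w > 0.5 - 1e-12 & w <= 1))
  expect_equal(max(w), 1)
  expect_equal(which.max(w), which.max(P))
  expect_error(cluster_confidences(c(1, 0)), "positive")
})

test_that("RBF kernel has unit diagonal and the e^-1 scale point", {
  a <- c(1, 2, 3)
  expect_equal(rbf_kernel(a, a, 2), 1)
  b <- a + c(2, 0, 0)   # ||a-b||^2 = 4 = 2 sigma^2 for sigma = sqrt(2)
  expect_equal(rbf_kernel(a, b, sqrt(2)), exp(-1))
  set.seed(43)
  for (i in 1:5) {
    u <- rnorm(4); v <- rnorm(4)
    expect_equal(rbf_kernel(u, v, 1.3), rbf_kernel(v, u, 1.3))
  }
  expect_error(rbf_kernel(a, a, 0), "sigma")
  expect_error(rbf_kernel(a, c(1, 2), 1), "dimension")
})

test_that("two distinct points give the symmetric closed-form sphere", {
  x <- rbind(c(0, 0), c(3, 0))
  m <- wsvdd(x, w = 1, C = 10, sigma = 2, normalize = FALSE)
  expect_equal(m$alphas, c(0.5, 0.5), tolerance = 1e-9)
  K12 <- rbf_kernel(x[1, ], x[2, ], 2)
  expect_equal(m$r_squared, (1 - K12) / 2, tolerance = 1e-9)
  # both SVs are unbounded, so both sit numerically on the boundary
  expect_lt(max(abs(decide(m, x, value = "score"))), 1e-9)
  expect_equal(decide(m, c(100, 100)), -1L)
})

test_that("unit confidences reproduce classical SVDD from a generic QP", {
  set.seed(44)
  x <- matrix(rnorm(30 * 6), 30, 6)
  C <- 0.3; sigma <- 2.5
  m <- wsvdd(x, w = 1, C = C, sigma = sigma, normalize = FALSE)
  oracle <- ipop_svdd(x, C, sigma)
  expect_lt(max(abs(full_alpha(m, x) - oracle$alpha)), 1e-6)
  expect_lt(abs(m$r_squared - oracle$r_squared), 1e-8)
})

test_that("training satisfies the dual feasibility and KKT conditions", {
  set.seed(45)
  configs <- list(list(C = 0.2, sigma = 1.5), list(C = 0.08, sigma = 3),
                  list(C = 1, sigma = 0.8))
  for (cf in configs) {
    x <- matrix(rnorm(40 * 5), 40, 5)
    w <- cluster_confidences(subtractive_densities(scale(x)))
    m <- wsvdd(x, w = NULL, C = cf$C, sigma = cf$sigma)
    expect_equal(sum(m$alphas), 1, tolerance = 1e-8)
    expect_true(all(m$alphas >= -1e-10))
    expect_true(all(m$alphas <= cf$C * m$confidences + 1e-10))
    # every unbounded SV reports the same squared radius
    ub <- which(m$alphas > 1e-6 * cf$C &
                  m$alphas < cf$C * m$confidences - 1e-6 * cf$C)
    if (length(ub) >= 2) {
      Ksv <- outer(seq_len(nrow(m$support_vectors)),
                   seq_len(nrow(m$support_vectors)),
                   Vectorize(function(i, j)
                     rbf_kernel(m$support_vectors[i, ], m$support_vectors[j, ],
                                m$sigma)))
      r2k <- 1 - 2 * as.vector(Ksv[ub, , drop = FALSE] %*% m$alphas) + m$const
      expect_lt(diff(range(r2k)), 1e-6)
    }
  }
})

test_that("a down-weighted outlier is pinned at its box bound", {
  set.seed(46)
  inliers <- matrix(rnorm(20 * 2, sd = 0.5), 20, 2)
  outlier <- c(8, 8)
  x <- rbind(inliers, outlier)
  w <- c(rep(1, 20), 0.5)
  C <- 0.05
  m_w <- wsvdd(x, w = w, C = C, sigma = 2, normalize = FALSE)
  m_u <- wsvdd(x, w = 1, C = C, sigma = 2, normalize = FALSE)
  a_w <- full_alpha(m_w, x)
  expect_equal(a_w[21], C * 0.5, tolerance = 1e-9)
  expect_lt(m_w$r_squared, m_u$r_squared)
  expect_error(wsvdd(x, w = rep(0.9, 21), C = 0.01, sigma = 2),
               "infeasible box")
})

test_that("lowering one confidence never raises that point's dual mass", {
  set.seed(47)
  x <- rbind(matrix(rnorm(30 * 2), 30, 2), c(5, 5))
  alphas <- sapply(c(1, 0.9, 0.8, 0.7, 0.6, 0.51), function(wo) {
    m <- wsvdd(x, w = c(rep(1, 30), wo), C = 0.08, sigma = 1.5,
               normalize = FALSE)
    full_alpha(m, x)[31]
  })
  expect_true(all(diff(alphas) <= 1e-10))
})

test_that("decision signs agree with an independently solved expansion", {
  set.seed(48)
  x <- matrix(rnorm(25 * 2), 25, 2)
  C <- 0.4; sigma <- 1.2
  m <- wsvdd(x, w = 1, C = C, sigma = sigma, normalize = FALSE)
  oracle <- ipop_svdd(x, C, sigma)
  grid <- as.matrix(expand.grid(seq(-3, 3, length.out = 9),
                                seq(-3, 3, length.out = 9)))
  Kz <- exp(-(outer(rowSums(grid^2), rowSums(x^2), `+`) -
                2 * tcrossprod(grid, x)) / (2 * sigma^2))
  dist2 <- 1 - 2 * as.vector(Kz %*% oracle$alpha) + oracle$const
  inside <- ifelse(dist2 <= oracle$r_squared + 1e-9, 1L, -1L)
  got <- decide(m, grid)
  # allow disagreement only within numerical reach of the boundary
  score <- decide(m, grid, value = "score")
  mismatch <- got != inside
  expect_true(all(abs(score[mismatch]) < 1e-7))
})

test_that("models survive a JSON round trip", {
  set.seed(49)
  x <- matrix(rnorm(40 * 24), 40, 24)
  m <- wsvdd(x, C = 0.2)
  path <- tempfile(fileext = ".json")
  write_wsvdd(m, path)
  m2 <- read_wsvdd(path)
  z <- matrix(rnorm(5 * 24), 5, 24)
  expect_equal(decide(m, z, value = "score"), decide(m2, z, value = "score"),
               tolerance = 1e-12)
  unlink(path)
})
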