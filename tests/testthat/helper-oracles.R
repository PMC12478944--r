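# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# O(N^2) discrete Fourier transform, one-sided power
naive_dft_power <- function(x, nfft) {
  xp <- c(x, rep(0, nfft - length(x)))
  K <- nfft %/% 2 + 1
  sapply(seq_len(K) - 1, function(k) {
    re <- sum(xp * cos(-2 * pi * k * (seq_along(xp) - 1) / nfft))
    im <- sum(xp * sin(-2 * pi * k * (seq_along(xp) - 1) / nfft))
    re^2 + im^2
  })
}

# per-frame slice-and-multiply framing, plain double loop
naive_frames <- function(x, L, inc, window) {
  f_n <- (length(x) - L) %/% inc + 1
  out <- matrix(0, f_n, L)
  for (i in seq_len(f_n)) {
    for (n in seq_len(L)) {
      out[i, n] <- x[(i - 1) * inc + n] * window[n]
    }
  }
  out
}

# subtractive-clustering densities by explicit double loop
naive_densities <- function(x) {
  q <- nrow(x)
  cover <- sapply(seq_len(q), function(j)
    max(sapply(seq_len(q), function(i) sqrt(sum((x[i, ] - x[j, ])^2)))))
  r_a <- 0.5 * min(cover)
  P <- numeric(q)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      P[i] <- P[i] + exp(-sum((x[i, ] - x[j, ])^2) / (0.5 * r_a)^2)
    }
  }
  P
}

# classical SVDD dual via kernlab's generic interior-point QP solver
ipop_svdd <- function(x, C, sigma) {
  q <- nrow(x)
  K <- exp(-as.matrix(dist(x))^2 / (2 * sigma^2))
  sol <- kernlab::ipop(c = matrix(-diag(K)), H = 2 * K,
                       A = matrix(1, 1, q), b = 1, r = 0,
                       l = matrix(0, q), u = matrix(C, q),
                       sigf = 12, maxiter = 400)
  alpha <- kernlab::primal(sol)
  const <- as.numeric(t(alpha) %*% K %*% alpha)
  ub <- which(alpha > 1e-6 * C & alpha < C - 1e-6 * C)
  if (!length(ub)) ub <- which(alpha > 1e-6 * C)
  r2 <- mean(diag(K)[ub] - 2 * as.vector(K[ub, , drop = FALSE] %*% alpha) + const)
  list(alpha = alpha, r_squared = r2, K = K, const = const)
}

# map a wsvdd model's stored (SV, alpha) pairs back onto training rows
full_alpha <- function(model, x_normalized) {
  key <- apply(round(x_normalized, 9), 1, paste, collapse = ",")
  svk <- apply(round(model$support_vectors, 9), 1, paste, collapse = ",")
  a <- numeric(nrow(x_normalized))
  a[match(svk, key)] <- model$alphas
  a
}

# majority label by histogram argmax with the package's documented
# unknown-exclusion and priority rules, implemented independently
naive_vote <- function(labels, priority = c("cough", "scream", "other", "unknown")) {
  keep <- labels[labels != "unknown"]
  if (!length(keep)) return("unknown")
  counts <- sapply(unique(keep), function(l) sum(keep == l))
  best <- names(counts)[counts == max(counts)]
  for (p in priority) if (p %in% best) return(p)
}
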