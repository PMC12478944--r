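#' Subtractive-clustering densities
#'
#' For each training point, the sum of Gaussian affinities to every
#' training point (including itself): `P_i = sum_j exp(-||x_i - x_j||^2 /
#' (0.5 r_a)^2)`, with neighbouring radius `r_a = 0.5 min_j max_i
#' ||x_i - x_j||` — half the smallest "covering radius" over candidate
#' centres. High density marks a point deep inside its class cloud; low
#' density marks isolated (possibly mislabeled) points.
#'
#' @param x `q x d` instance matrix, `q >= 2`.
#' @param radius_mode `"min_max"` (as defined above) or `"max_min"`
#'   (`0.5 max_i min_j`, the alternative nesting, exposed for comparison).
#' @return numeric vector of densities, each in `[1, q]`.
#' @export
subtractive_densities <- function(x, radius_mode = c("min_max", "max_min")) {
  radius_mode <- match.arg(radius_mode)
  x <- as.matrix(x)
  q <- nrow(x)
  if (q < 2L) stop("at least 2 training instances are required")
  D <- as.matrix(stats::dist(x))
  r_a <- if (radius_mode == "min_max") {
    0.5 * min(apply(D, 2L, max))   # min over centres j of max over i
  } else {
    Dp <- D; diag(Dp) <- Inf
    0.5 * max(apply(Dp, 2L, min))
  }
  if (r_a <= 0)
    stop("degenerate neighbouring radius r_a = 0: all training instances ",
         "are duplicates of one another")
  unname(rowSums(exp(-D^2 / (0.5 * r_a)^2)))
}

#' Confidence weights from densities
#'
#' Maps densities to weights in (1/2, 1]:
#' `w_i = 1 / (1 + ((P_max - P_i) / P_max)^2)`. The density centre
#' (`P_i = P_max`) gets weight 1; the most isolated points approach 1/2,
#' halving their slack penalty during training.
#'
#' @param P positive density vector from [subtractive_densities()].
#' @return numeric weight vector, max exactly 1.
#' @export
cluster_confidences <- function(P) {
  if (any(P <= 0)) stop("densities must be strictly positive")
  p_max <- max(P)
  1 / (1 + ((p_max - P) / p_max)^2)
}

#' Gaussian radial basis kernel
#'
#' `K(a, b) = exp(-||a - b||^2 / (2 sigma^2))`.
#'
#' @param a,b numeric vectors of equal length.
#' @param sigma kernel width, > 0.
#' @return kernel value in (0, 1].
#' @export
rbf_kernel <- function(a, b, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(a) != length(b)) stop("vectors must have equal dimension")
  exp(-sum((a - b)^2) / (2 * sigma^2))
}

# full RBF kernel (cross-)matrix; y = NULL gives the symmetric Gram matrix
rbf_kernel_matrix <- function(x, y = NULL, sigma) {
  x <- as.matrix(x)
  if (is.null(y)) {
    sq <- rowSums(x^2)
    d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(x)
  } else {
    y <- as.matrix(y)
    d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  }
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# deterministic SMO-style solver for the SVDD dual:
#   maximize sum_i alpha_i K_ii - alpha' K alpha
#   s.t. sum alpha = 1, 0 <= alpha_i <= u_i
# Pairwise updates on the maximal-KKT-violation pair.
solve_svdd_dual <- function(K, u, tol = 1e-10, max_iter = NULL) {
  q <- nrow(K)
  if (is.null(max_iter)) max_iter <- 500L * q
  alpha <- u / sum(u)                       # feasible start
  g <- diag(K) - 2 * as.vector(K %*% alpha) # gradient of the objective
  eps_b <- 1e-12
  for (it in seq_len(max_iter)) {
    up_ok <- alpha < u - eps_b              # can increase
    dn_ok <- alpha > eps_b                  # can decrease
    if (!any(up_ok) || !any(dn_ok)) break
    i <- which(up_ok)[which.max(g[up_ok])]
    j <- which(dn_ok)[which.min(g[dn_ok])]
    viol <- g[i] - g[j]
    if (viol < tol) break
    denom <- 2 * (K[i, i] + K[j, j] - 2 * K[i, j])
    t_max <- min(u[i] - alpha[i], alpha[j])
    t_step <- if (denom > 1e-14) min(viol / denom, t_max) else t_max
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + t_step
    alpha[j] <- alpha[j] - t_step
    g <- g - 2 * t_step * (K[, i] - K[, j])
  }
  alpha
}

#' Train a confidence-weighted SVDD
#'
#' Finds the minimal hypersphere (in RBF feature space) around the
#' training data, with slack penalised by `C w_i` so that low-confidence
#' points are cheaper to leave outside. Solves the dual
#' `max sum_i a_i K_ii - sum_ij a_i a_j K_ij` subject to `sum a = 1`,
#' `0 <= a_i <= C w_i` with a deterministic pairwise coordinate (SMO)
#' solver. The squared radius is the mean of
#' `K(x_k,x_k) - 2 sum_i a_i K(x_k,x_i) + sum_ij a_i a_j K_ij` over the
#' unbounded support vectors.
#'
#' Instances are z-scored with training-set statistics before any kernel
#' evaluation (RBF distances are meaningless across raw cepstral
#' dimensions); the statistics are stored in the model and re-applied at
#' decision time. Confidences, when computed internally, use the same
#' normalised metric.
#'
#' @param x `q x d` training matrix.
#' @param w confidence vector in (0, 1] (max should be 1); `NULL` computes
#'   it via [subtractive_densities()] + [cluster_confidences()]; a scalar
#'   1 gives classical (unweighted) SVDD.
#' @param C penalty factor; `NULL` defaults to `1 / (0.05 q)` (a budget
#'   allowing roughly 5% of unit-weight points outside).
#' @param sigma RBF width; `NULL` uses the median pairwise distance of the
#'   normalised training data.
#' @param normalize z-score the instances (default `TRUE`).
#' @param radius_mode passed to [subtractive_densities()].
#' @param tol dual optimality tolerance (maximal KKT violation).
#' @return object of class `wsvdd`: `support_vectors` (normalised),
#'   `alphas`, `r_squared`, `sigma`, `C`, `confidences` (of the SVs),
#'   `norm_stats`, `const` (the quadratic-form term of the decision
#'   function), `n_train`.
#' @export
wsvdd <- function(x, w = NULL, C = NULL, sigma = NULL, normalize = TRUE,
                  radius_mode = "min_max", tol = 1e-10) {
  x <- as.matrix(x)
  q <- nrow(x)
  if (q < 2L) stop("at least 2 training instances are required")
  if (!all(is.finite(x))) stop("training instances must be finite")

  if (normalize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  }
  xn <- sweep(sweep(x, 2L, center), 2L, scale, `/`)

  if (is.null(w)) {
    w <- cluster_confidences(subtractive_densities(xn, radius_mode))
  } else if (length(w) == 1L) {
    w <- rep(w, q)
  }
  if (length(w) != q) stop("confidence vector length must equal nrow(x)")
  if (any(w <= 0 | w > 1)) stop("confidences must lie in (0, 1]")

  if (is.null(sigma)) {
    d <- stats::dist(xn)
    sigma <- stats::median(d)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(C)) C <- 1 / (0.05 * q)
  if (C <= 0) stop("C must be positive")

  u <- C * w
  if (sum(u) < 1)
    stop("infeasible box: sum(C * w) = ", format(sum(u)),
         " < 1; increase C or the confidences")

  K <- rbf_kernel_matrix(xn, sigma = sigma)
  alpha <- solve_svdd_dual(K, u, tol = tol)

  const <- as.numeric(t(alpha) %*% K %*% alpha)
  eps_tol <- 1e-6 * C
  unbounded <- which(alpha > eps_tol & alpha < u - eps_tol)
  sv_for_r <- if (length(unbounded)) unbounded else which(alpha > eps_tol)
  r2_each <- diag(K)[sv_for_r] - 2 * as.vector(K[sv_for_r, , drop = FALSE] %*% alpha) + const
  r_squared <- mean(r2_each)

  keep <- which(alpha > 1e-12)
  structure(list(
    support_vectors = xn[keep, , drop = FALSE],
    alphas = alpha[keep],
    r_squared = r_squared,
    sigma = sigma, C = C,
    confidences = w[keep],
    norm_stats = list(center = center, scale = scale),
    const = const,
    n_train = q,
    format_version = 1L
  ), class = "wsvdd")
}

#' @export
print.wsvdd <- function(x, ...) {
  cat(sprintf(
    "<wsvdd: %d SVs of %d points, d = %d, sigma = %.4g, C = %.4g, r^2 = %.4g>\n",
    nrow(x$support_vectors), x$n_train, ncol(x$support_vectors),
    x$sigma, x$C, x$r_squared))
  invisible(x)
}

#' Decision function of a weighted SVDD
#'
#' Signs `r^2 - K(z,z) + 2 sum_i a_i K(z, x_i) - sum_ij a_i a_j K_ij`:
#' `+1` when the test point falls inside or on the hypersphere, `-1`
#' outside. Exact zeros count as inside. Test points are normalised with
#' the training statistics stored in the model.
#'
#' @param model a trained [wsvdd()].
#' @param z a length-`d` vector or `n x d` matrix of test points.
#' @param value `"sign"` (default) or `"score"` for the raw decision value.
#' @return integer vector of +/-1, or numeric scores.
#' @export
decide <- function(model, z, value = c("sign", "score")) {
  stopifnot(inherits(model, "wsvdd"))
  value <- match.arg(value)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  d <- ncol(model$support_vectors)
  if (ncol(z) != d)
    stop("test point has dimension ", ncol(z), ", model expects ", d)
  zn <- sweep(sweep(z, 2L, model$norm_stats$center), 2L,
              model$norm_stats$scale, `/`)
  Kz <- rbf_kernel_matrix(zn, model$support_vectors, model$sigma)
  score <- model$r_squared - 1 + 2 * as.vector(Kz %*% model$alphas) - model$const
  if (value == "score") return(score)
  ifelse(score >= 0, 1L, -1L)
}

#' @export
predict.wsvdd <- function(object, newdata, ...) decide(object, newdata)

#' Serialise a weighted-SVDD model to JSON
#'
#' @param model a [wsvdd()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wsvdd <- function(model, path) {
  stopifnot(inherits(model, "wsvdd"))
  obj <- unclass(model)
  obj$support_vectors <- unname(as.matrix(obj$support_vectors))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a weighted-SVDD model written by [write_wsvdd()]
#' @param path JSON file path.
#' @return a `wsvdd` model.
#' @export
read_wsvdd <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported model format version: ", obj$format_version)
  obj$support_vectors <- as.matrix(obj$support_vectors)
  obj$norm_stats <- list(center = as.numeric(obj$norm_stats$center),
                         scale = as.numeric(obj$norm_stats$scale))
  structure(obj, class = "wsvdd")
}
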