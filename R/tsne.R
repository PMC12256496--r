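# Exact (dense) t-SNE. Small-n embedding used by the chemical-space
# pipeline; quadratic in the number of points, which is ample for
# benchmark-sized chemical sets.

# row-wise conditional probabilities at a perplexity, by bisection on the
# Gaussian bandwidth
tsne_input_probs <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { entropy <- 0 } else {
        p <- w / sw
        entropy <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(entropy - target) < 1e-6) break
      if (entropy > target) { lo <- beta; beta <- if (is.finite(hi))
        (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo))
        (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-distributed stochastic neighbour embedding (exact)
#'
#' Projects a numeric matrix onto two dimensions with standard t-SNE:
#' Gaussian input affinities calibrated per point to a fixed perplexity,
#' Student-t output kernel, gradient descent with momentum and early
#' exaggeration. Deterministic for a given seed.
#'
#' @param x numeric matrix (rows = items).
#' @param perplexity effective neighbourhood size; must be < (nrow - 1)/3.
#' @param n_iter gradient-descent iterations (default 500).
#' @param seed integer seed for the random initialization.
#' @return matrix nrow(x) x 2 of embedding coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, n_iter = 500, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("t-SNE needs at least 4 points")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 2) perplexity <- 2

  d2 <- as.matrix(stats::dist(x))^2
  P <- tsne_input_probs(d2, perplexity)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2); update <- matrix(0, n, 2)
  eta <- 200
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 12 else 1
    mom <- if (it <= 250) 0.5 else 0.8
    dy2 <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + dy2); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    L <- (ex * P - Q) * W
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(grad) != sign(update), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    update <- mom * update - eta * gain * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
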