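#' 2D t-SNE embedding of a feature table
#'
#' Exact (dense) t-distributed stochastic neighbor embedding for
#' quality-control visualization of contact-fraction feature sets: the
#' high-dimensional rows are mapped to 2D so that label or variant
#' structure in the data can be inspected by eye.  The embedding is
#' unsupervised and is never used by the classifiers.
#'
#' Implementation: squared Euclidean affinities with per-point bandwidths
#' calibrated to `perplexity` by binary search, symmetrized; gradient
#' descent with momentum (0.5 then 0.8), learning rate 200, and early
#' exaggeration (x12 for the first quarter of iterations).  Exact O(n^2)
#' gradients -- intended for datasets of a few thousand rows at most.
#'
#' @param features Feature table (residue-key columns; metadata columns are
#'   ignored) or a numeric matrix.
#' @param perplexity Target perplexity; default 30.  Must satisfy
#'   `3 * perplexity < n - 1`; if not, it is reduced with a warning.
#' @param n_iter Gradient-descent iterations; default 500.
#' @param seed Integer seed (random init); fixed seed gives an identical
#'   embedding.
#' @return Tibble with columns `tsne1`, `tsne2`, one row per input row.
#' @export
embed_2d <- function(features, perplexity = 30, n_iter = 500, seed = 1) {
  x <- if (is.matrix(features)) features else feature_matrix(as_tibble(features))
  n <- nrow(x)
  if (n < 2) abort("Need at least 2 rows to embed.")
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warn(paste0("Perplexity ", perplexity, " too large for ", n,
                " rows; reduced to ", signif(max_perp, 3), "."))
    perplexity <- max_perp
  }
  if (perplexity < 1) perplexity <- 1

  # PCA-reduce to at most 50 dims (standard preprocessing)
  if (ncol(x) > 50) {
    x <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 50)$x
  }

  P <- tsne_affinities(x, perplexity)
  Y <- withr::with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), ncol = 2))

  exag_iters <- max(50L, n_iter %/% 4L)
  P_run <- P * 12
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  # learning rate scaled to problem size (n / exaggeration / 4, floored at 50);
  # a fixed large rate makes small embeddings diverge
  eta <- max(n / 48, 50)
  for (it in seq_len(n_iter)) {
    if (it == exag_iters + 1L) P_run <- P
    if (it == 250L) momentum <- 0.8
    # Student-t affinities in the embedding
    d2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + d2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  tibble(tsne1 = Y[, 1], tsne2 = Y[, 2])
}

# symmetrized input affinities at the target perplexity
tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(sum_p) + beta * sum(di * p) / sum_p
        p <- p / sum_p
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  P
}
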