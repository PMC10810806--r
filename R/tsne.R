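# Exact t-SNE on a precomputed distance matrix.
#
# The disease sets analysed here are small (tens of points), so the exact
# O(K^2) gradient is used throughout: Gaussian input affinities calibrated
# per point to a target perplexity by binary search on the precision, a
# Student-t low-dimensional kernel, and the standard momentum + adaptive
# gains optimiser with early exaggeration.

# Row-conditional affinities p_{j|i} at a fixed perplexity (entropy target).
.tsne_affinities <- function(d2, perplexity, iters = 64L) {
  k <- nrow(d2)
  p <- matrix(0, k, k)
  target <- log(perplexity)
  for (i in seq_len(k)) {
    di <- d2[i, -i]
    lo <- 0
    hi <- Inf
    beta <- 1
    for (it in seq_len(iters)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) {
        h <- 0
      } else {
        # Shannon entropy of the conditional distribution, in nats
        h <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(h - target) < 1e-7) break
      if (h > target) {              # too spread out: raise precision
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    w <- exp(-di * beta)
    p[i, -i] <- if (sum(w) > 0) w / sum(w) else 1 / (k - 1)
  }
  p
}

#' Embed diseases in two dimensions by t-SNE
#'
#' Maps the K diseases of a precomputed co-occurrence distance matrix to 2-D
#' coordinates `z_k = (x_k, y_k)` with t-distributed stochastic neighbour
#' embedding, run exactly (no tree approximation) since K is small. The
#' distance matrix is used directly (its squares feed the input affinities);
#' initial coordinates are drawn from the given seed, so the result is
#' deterministic for fixed inputs, perplexity, seed and iteration count.
#'
#' @param distances Square symmetric distance matrix with disease-code
#'   dimnames, all entries finite, K >= 4.
#' @param perplexity Positive effective-neighbourhood size, at most
#'   `(K - 1)/3`; `"auto"` (default) uses `min(10, floor((K - 1)/3))`.
#' Like other non-convex stages of the pipeline, the optimisation is run
#' from several random initialisations (seeds derived from `seed`) and the
#' embedding with the lowest final Kullback-Leibler divergence -- the
#' objective t-SNE itself minimises -- is kept, which guards against the
#' occasional poor local optimum that a single start can reach.
#'
#' @param seed Integer seed for the random initialisations.
#' @param n_iter Number of gradient iterations (default 1000).
#' @param n_restarts Number of random initialisations (default 5).
#' @return K x 2 numeric matrix of coordinates (rownames = disease codes)
#'   with a `params` attribute recording perplexity, seed, iterations,
#'   restarts and the final KL divergence.
#' @export
embed_2d <- function(distances, perplexity = "auto", seed = 1L,
                     n_iter = 1000L, n_restarts = 5L) {
  d <- as.matrix(distances)
  k <- nrow(d)
  if (k < 4) stop("need at least 4 diseases to embed; got ", k)
  stopifnot(ncol(d) == k)
  if (!all(is.finite(d))) stop("distances must all be finite")
  stopifnot(max(abs(d - t(d))) < 1e-8)
  max_perp <- (k - 1) / 3
  if (identical(perplexity, "auto")) {
    perplexity <- min(10, max(1, floor(max_perp)))
  }
  if (!(perplexity > 0 && perplexity <= max_perp)) {
    stop("perplexity must lie in (0, ", format(max_perp),
         "] for K = ", k, " diseases; got ", perplexity)
  }

  pc <- .tsne_affinities(d^2, perplexity)
  p <- (pc + t(pc))
  p <- p / sum(p)
  p <- pmax(p, 1e-12)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    sub_seed <- as.integer((as.numeric(seed) + (r - 1) * 1000003) %%
                             2147483647)
    cand <- .tsne_descent(p, k, sub_seed, n_iter)
    if (is.null(best) || cand$kl < best$kl) best <- cand
  }
  y <- best$y
  dimnames(y) <- list(rownames(d), c("x", "y"))
  attr(y, "params") <- list(perplexity = perplexity, seed = as.integer(seed),
                            n_iter = as.integer(n_iter),
                            n_restarts = as.integer(n_restarts),
                            kl = best$kl)
  y
}

# One gradient-descent run from a seeded random start; returns the final
# coordinates and KL divergence between input and embedded affinities.
.tsne_descent <- function(p, k, seed, n_iter) {
  exag_until <- min(250L, as.integer(n_iter))
  eta <- 200
  y <- with_seed(seed, matrix(rnorm(k * 2, sd = 1e-4), k, 2))
  vel <- matrix(0, k, 2)
  gains <- matrix(1, k, 2)
  q <- NULL
  for (it in seq_len(n_iter)) {
    pe <- if (it <= exag_until) p * 12 else p
    ss <- rowSums(y^2)
    num <- 1 / (1 + outer(ss, ss, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pe - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    mom <- if (it < 250) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8),
                  0.01)
    vel <- mom * vel - eta * gains * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y))
  }
  off <- upper.tri(p) | lower.tri(p)
  list(y = y, kl = sum(p[off] * log(p[off] / q[off])))
}
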