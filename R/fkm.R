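# Fuzzy k-means (fuzzy c-means) on 2-D embedded disease coordinates,
# implemented from the algorithm's printed update equations:
#   objective      OF = sum_k sum_g u_kg^m d_kg^2,  rows of U sum to 1
#   centroids      C_g = sum_k u_kg^m z_k / sum_k u_kg^m
#   memberships    u_kg = 1 / sum_j (d_kg / d_kj)^(2/(m-1)),
#                  with u_kg = 1 (others 0) whenever d_kg = 0
# iterated EM-style from a random row-stochastic start until the membership
# matrix stabilises.

# Euclidean point-to-centroid distance matrix (K x G), clamped at zero to
# guard against tiny negative values from the quadratic expansion.
.pc_dist <- function(coords, centroids) {
  d2 <- outer(rowSums(coords^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(coords, centroids)
  sqrt(pmax(d2, 0))
}

.check_memberships <- function(u, tol = 1e-9) {
  stopifnot(is.matrix(u), all(u >= -tol), all(u <= 1 + tol),
            all(abs(rowSums(u) - 1) < tol))
  invisible(u)
}

#' Fuzzy k-means centroid update
#'
#' Each centroid is the `u^m`-weighted mean of the K points:
#' `C_g = sum_k u_kg^m z_k / sum_k u_kg^m`.
#'
#' @param coords K x 2 coordinate matrix.
#' @param memberships K x G row-stochastic membership matrix U.
#' @param m Fuzzifier, `> 1`.
#' @return G x 2 centroid matrix.
#' @export
update_centroids <- function(coords, memberships, m = 2) {
  stopifnot(m > 1, nrow(coords) == nrow(memberships))
  w <- memberships^m
  tot <- colSums(w)
  if (any(tot <= 0)) {
    stop("degenerate cluster: membership column ",
         paste(which(tot <= 0), collapse = ", "),
         " has zero total weight")
  }
  crossprod(w, coords) / tot
}

#' Fuzzy k-means membership update
#'
#' Memberships follow the inverse-distance rule
#' `u_kg = 1 / sum_j (d_kg / d_kj)^(2/(m-1))` with `d_kg` the Euclidean
#' distance from point k to centroid g. A point coinciding with a centroid
#' (`d_kg = 0`) gets membership 1 there and 0 elsewhere; if it coincides
#' with several centroids the lowest-index one wins (deterministic
#' tie-break).
#'
#' @param coords K x 2 coordinate matrix.
#' @param centroids G x 2 centroid matrix.
#' @param m Fuzzifier, `> 1`.
#' @return K x G row-stochastic membership matrix.
#' @export
update_memberships <- function(coords, centroids, m = 2) {
  stopifnot(m > 1, all(is.finite(coords)), all(is.finite(centroids)))
  d <- .pc_dist(coords, centroids)
  u <- matrix(0, nrow(d), ncol(d))
  zero <- d == 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[cbind(which(hit), max.col(zero[hit, , drop = FALSE],
                                ties.method = "first"))] <- 1
  }
  if (any(!hit)) {
    w <- d[!hit, , drop = FALSE]^(-2 / (m - 1))
    u[!hit, ] <- w / rowSums(w)
  }
  dimnames(u) <- list(rownames(coords), NULL)
  u
}

#' Fuzzy k-means objective function
#'
#' `OF = sum_k sum_g u_kg^m * d_kg^2`, the quantity the EM iteration
#' minimises under the row-sum-1 constraint.
#'
#' @inheritParams update_centroids
#' @param centroids G x 2 centroid matrix.
#' @return Non-negative scalar.
#' @export
fkm_objective <- function(coords, centroids, memberships, m = 2) {
  stopifnot(nrow(coords) == nrow(memberships),
            ncol(memberships) == nrow(centroids))
  sum(memberships^m * .pc_dist(coords, centroids)^2)
}

.fkm_em <- function(coords, u0, m, tol, max_iter) {
  u <- u0
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  centroids <- NULL
  while (it < max_iter) {
    it <- it + 1
    centroids <- update_centroids(coords, u, m)
    u_new <- update_memberships(coords, centroids, m)
    trace[it] <- fkm_objective(coords, centroids, u_new, m)
    delta <- sqrt(sum((u_new - u)^2))
    u <- u_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(memberships = u, centroids = centroids, objective_trace = trace,
       n_iter = it, converged = converged)
}

#' Fit fuzzy k-means
#'
#' Alternates the centroid and membership updates from a random
#' row-stochastic start (rows drawn from a uniform Dirichlet under the given
#' seed) until the Frobenius norm of successive membership matrices falls
#' below `tol` or `max_iter` is reached. `n_init` random restarts are run
#' and the fit with the lowest final objective kept. Hard labels follow the
#' strict 0.5 membership threshold ([assign_labels()]).
#'
#' @param coords K x 2 coordinate matrix (rownames = disease codes).
#' @param G Number of clusters, `1 <= G <= K`.
#' @param m Fuzzifier (`> 1`); 2 is the standard value used throughout.
#' @param tol Convergence tolerance on `||U(r) - U(r-1)||_F`.
#' @param max_iter Iteration cap per restart; non-convergence warns and
#'   returns `converged = FALSE`, it is not an error.
#' @param seed Integer seed for the random initialisations.
#' @param n_init Number of random restarts.
#' @param threshold Membership threshold for hard assignment.
#' @return An `fkm_result`: `memberships` (K x G), `centroids` (G x 2),
#'   `m`, `objective_trace` (non-increasing), `n_iter`, `converged`,
#'   `hard_labels` (named integer, `NA` = not assigned) and `not_assigned`.
#' @export
fkm_fit <- function(coords, G, m = 2, tol = 1e-6, max_iter = 500L,
                    seed = 1L, n_init = 10L, threshold = 0.5) {
  k <- nrow(coords)
  if (!(G >= 1 && G <= k)) stop("G must lie in [1, ", k, "]; got ", G)
  stopifnot(m > 1, tol > 0, max_iter >= 1, n_init >= 1)
  if (G == 1) {
    u <- matrix(1, k, 1, dimnames = list(rownames(coords), NULL))
    centroids <- colMeans(coords)
    centroids <- matrix(centroids, 1, 2)
    fit <- list(memberships = u, centroids = centroids,
                objective_trace = fkm_objective(coords, centroids, u, m),
                n_iter = 1L, converged = TRUE)
  } else {
    fit <- with_seed(seed, {
      best <- NULL
      for (r in seq_len(n_init)) {
        e <- matrix(rexp(k * G), k, G)
        u0 <- e / rowSums(e)
        cand <- tryCatch(.fkm_em(coords, u0, m, tol, max_iter),
                         error = function(err) NULL)
        if (!is.null(cand) &&
            (is.null(best) ||
             cand$objective_trace[cand$n_iter] <
               best$objective_trace[best$n_iter])) {
          best <- cand
        }
      }
      if (is.null(best)) stop("every fuzzy k-means restart degenerated")
      best
    })
    if (!fit$converged) {
      warning("fuzzy k-means did not converge within ", max_iter,
              " iterations (final membership change above ", tol, ")")
    }
  }
  al <- assign_labels(fit$memberships, threshold)
  structure(c(fit, list(m = m, hard_labels = al$labels,
                        not_assigned = al$not_assigned)),
            class = "fkm_result")
}

#' @export
print.fkm_result <- function(x, ...) {
  cat("<fkm_result> K = ", nrow(x$memberships), ", G = ",
      ncol(x$memberships), ", m = ", x$m, "; OF = ",
      format(x$objective_trace[x$n_iter], digits = 6), " after ", x$n_iter,
      " iterations (", if (x$converged) "converged" else "not converged",
      "); ", length(x$not_assigned), " not assigned\n", sep = "")
  invisible(x)
}

#' Threshold fuzzy memberships into hard labels
#'
#' A disease is considered well classified into cluster g when its
#' membership degree strictly exceeds the threshold (default 0.5, so at most
#' one cluster can qualify); otherwise it is reported as not assigned,
#' keeping its full membership row for inspection.
#'
#' @param memberships K x G row-stochastic membership matrix.
#' @param threshold Threshold in `[0.5, 1)`.
#' @return List with `labels` (named integer vector, `NA` where not
#'   assigned) and `not_assigned` (character vector of codes).
#' @export
assign_labels <- function(memberships, threshold = 0.5) {
  stopifnot(threshold >= 0.5, threshold < 1)
  .check_memberships(memberships)
  top <- max.col(memberships, ties.method = "first")
  labels <- ifelse(memberships[cbind(seq_len(nrow(memberships)), top)] >
                     threshold, top, NA_integer_)
  names(labels) <- rownames(memberships)
  list(labels = labels,
       not_assigned = rownames(memberships)[is.na(labels)] %||% character(0))
}
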