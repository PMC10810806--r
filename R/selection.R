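#' Select the number of clusters by elbow and silhouette
#'
#' Before the fuzzy fit, a hard k-means pass over a range of cluster counts
#' records, for each G, the within-cluster sum of squares (WSS) and the mean
#' silhouette width. The best G maximises the mean silhouette; the elbow G
#' (largest second difference of the WSS curve) is always reported and
#' breaks exact silhouette ties. Each G is fitted with `n_restarts` seeded
#' random starts plus a warm start grown from the previous G's best centers
#' (previous centers plus the point farthest from its center), which makes
#' the reported WSS curve non-increasing in G.
#'
#' @param coords K x 2 coordinate matrix.
#' @param g_min,g_max Inclusive range of cluster counts,
#'   `2 <= g_min <= g_max <= K - 1`; `g_max` defaults to `min(6, K - 1)`.
#' @param n_restarts Random restarts per G.
#' @param seed Integer seed.
#' @return List with `G_best`, `elbow_G` and `diagnostics` (data frame
#'   `G, wss, mean_silhouette`; `NA` rows mark counts that were infeasible,
#'   e.g. more clusters than distinct points).
#' @export
select_num_clusters <- function(coords, g_min = 2L, g_max = NULL,
                                n_restarts = 10L, seed = 1L) {
  k <- nrow(coords)
  g_max <- as.integer(g_max %||% min(6L, k - 1L))
  g_min <- as.integer(g_min)
  if (!(2 <= g_min && g_min <= g_max && g_max <= k - 1)) {
    stop("need 2 <= g_min <= g_max <= K - 1 (K = ", k, "); got [",
         g_min, ", ", g_max, "]")
  }
  gs <- g_min:g_max
  dmat <- dist(coords)
  wss <- sil <- rep(NA_real_, length(gs))
  fits <- vector("list", length(gs))
  with_seed(seed, {
    prev <- NULL
    for (i in seq_along(gs)) {
      cands <- list(tryCatch(kmeans(coords, centers = gs[i],
                                    nstart = n_restarts, iter.max = 100),
                             error = function(e) NULL))
      if (!is.null(prev)) {
        # grow the previous solution: add the worst-fitted point as a center
        far <- which.max(rowSums((coords - prev$centers[prev$cluster, ,
                                                        drop = FALSE])^2))
        warm <- rbind(prev$centers, coords[far, ])
        if (!anyDuplicated(warm)) {
          cands <- c(cands, list(tryCatch(kmeans(coords, centers = warm,
                                                 iter.max = 100),
                                          error = function(e) NULL)))
        }
      }
      cands <- Filter(Negate(is.null), cands)
      if (length(cands)) {
        fit <- cands[[which.min(vapply(cands, `[[`, 0, "tot.withinss"))]]
        fits[[i]] <- fit
        prev <- fit
        wss[i] <- fit$tot.withinss
        sw <- cluster::silhouette(fit$cluster, dmat)
        sil[i] <- mean(sw[, "sil_width"])
      }
    }
  })
  if (all(is.na(sil))) stop("no feasible cluster count in [", g_min, ", ",
                            g_max, "]")
  elbow_g <- if (length(gs) >= 3 && sum(!is.na(wss)) == length(gs)) {
    second <- diff(diff(wss))               # at interior G values
    gs[which.max(second) + 1L]
  } else {
    gs[1]
  }
  best_sil <- max(sil, na.rm = TRUE)
  tied <- gs[!is.na(sil) & sil == best_sil]
  g_best <- if (elbow_g %in% tied) elbow_g else min(tied)
  list(G_best = as.integer(g_best), elbow_G = as.integer(elbow_g),
       diagnostics = data.frame(G = gs, wss = wss, mean_silhouette = sil))
}
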