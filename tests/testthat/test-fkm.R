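test_that("centroid update is the u^m-weighted mean", {
  # symmetric memberships -> midpoint
  pts <- rbind(c(0, 0), c(2, 0))
  u <- matrix(c(0.5, 0.5), 2, 1)
  expect_equal(update_centroids(pts, u, m = 2), matrix(c(1, 0), 1, 2),
               ignore_attr = TRUE)

  # crisp memberships reduce to the arithmetic mean of assigned points
  pts2 <- rbind(c(0, 0), c(1, 1), c(5, 3), c(7, 5))
  u2 <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(update_centroids(pts2, u2, m = 2),
               rbind(c(0.5, 0.5), c(6, 4)), ignore_attr = TRUE)

  # hand evaluation of the printed equation, m = 2
  pts3 <- cbind(c(0, 1, 4), c(0, 0, 0))
  u3 <- matrix(c(0.9, 0.8, 0.1), 3, 1)
  want_x <- (0.81 * 0 + 0.64 * 1 + 0.01 * 4) / (0.81 + 0.64 + 0.01)
  expect_equal(update_centroids(pts3, u3, m = 2)[1, 1], want_x,
               tolerance = 1e-12)

  expect_error(update_centroids(pts2, cbind(c(1, 1, 1, 1), 0), m = 2),
               "degenerate cluster")
})

test_that("membership update follows the inverse-distance and zero rules", {
  cen <- rbind(c(0, 0), c(4, 0))
  # point on centroid 1 -> (1, 0)
  expect_equal(update_memberships(rbind(c(0, 0)), cen)[1, ], c(1, 0))
  # equidistant -> (0.5, 0.5)
  expect_equal(update_memberships(rbind(c(2, 0)), cen)[1, ], c(0.5, 0.5))
  # distances (1, 2), m = 2 -> (0.8, 0.2), checked to 1e-12
  expect_equal(update_memberships(rbind(c(1, 0)), rbind(c(0, 0), c(3, 0)))[1, ],
               c(0.8, 0.2), tolerance = 1e-12)
  # several coincident centroids: membership 1 to the lowest index
  tri <- rbind(c(1, 1), c(1, 1), c(9, 9))
  expect_equal(update_memberships(rbind(c(1, 1)), tri)[1, ], c(1, 0, 0))
  # rows always sum to 1
  set.seed(1)
  u <- update_memberships(matrix(rnorm(40), 20), matrix(rnorm(6), 3))
  expect_equal(rowSums(u), rep(1, 20), tolerance = 1e-12)
})

test_that("objective is the membership-weighted sum of squared distances", {
  pts <- rbind(c(0, 0), c(3, 0))
  expect_equal(fkm_objective(pts, pts, diag(2), m = 2), 0)
  expect_equal(fkm_objective(rbind(c(1, 0)), rbind(c(0, 0)),
                             matrix(1, 1, 1), m = 2), 1)
  # hand-summed u^2 d^2 for the (0.8, 0.2) membership fixture
  coords <- rbind(c(1, 0), c(2, 0))
  cen <- rbind(c(0, 0), c(3, 0))
  u <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  hand <- 0.8^2 * 1 + 0.2^2 * 4 + 0.2^2 * 4 + 0.8^2 * 1
  expect_equal(fkm_objective(coords, cen, u, m = 2), hand, tolerance = 1e-12)
})

test_that("the EM fit is monotone, row-stochastic and G = 1 is exact", {
  set.seed(8)
  coords <- matrix(rnorm(60), 30)
  for (g in c(2, 3, 4)) {
    fit <- fkm_fit(coords, G = g, seed = g)
    expect_true(all(diff(fit$objective_trace) <=
                      1e-8 * max(1, fit$objective_trace[1])))
    expect_equal(rowSums(fit$memberships), rep(1, 30), tolerance = 1e-9)
    expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
    expect_true(fit$converged)
  }
  one <- fkm_fit(coords, G = 1)
  expect_identical(unname(one$memberships[, 1]), rep(1, 30))
  expect_equal(one$centroids[1, ], colMeans(coords), ignore_attr = TRUE)
  expect_true(all(one$hard_labels == 1L))
  expect_error(fkm_fit(coords, G = 31), "G must lie")
  expect_warning(fkm_fit(coords, G = 3, max_iter = 1, n_init = 1),
                 "did not converge")
})

test_that("fuzzy clusters recover well-separated blobs", {
  blobs <- make_blobs()
  fit <- fkm_fit(blobs$coords, G = 3, seed = 21)
  lab <- unname(fit$hard_labels)
  expect_gte(perm_agreement(blobs$labels[!is.na(lab)], lab[!is.na(lab)]),
             0.95)

  # m -> 1 approaches hard clustering: every point near-crisp at m = 1.05
  hard <- fkm_fit(blobs$coords, G = 3, m = 1.05, seed = 21)
  expect_true(all(apply(hard$memberships, 1, max) >= 0.99))

  # thresholded fuzzy labels agree with multi-restart hard k-means
  km <- morbclust:::with_seed(99,
    kmeans(blobs$coords, centers = 3, nstart = 10))
  keep <- !is.na(lab)
  expect_gte(perm_agreement(km$cluster[keep], lab[keep]), 0.95)

  # cluster relabelling invariance: two seeds agree up to permutation
  fit2 <- fkm_fit(blobs$coords, G = 3, seed = 1234)
  lab2 <- unname(fit2$hard_labels)
  both <- !is.na(lab) & !is.na(lab2)
  expect_gte(perm_agreement(lab[both], lab2[both]), 0.95)
})

test_that("hard assignment thresholds memberships strictly at 0.5", {
  u <- rbind(a = c(0.6, 0.4), b = c(0.5, 0.5))
  al <- assign_labels(u)
  expect_identical(al$labels, c(a = 1L, b = NA_integer_))
  expect_identical(al$not_assigned, "b")
  u3 <- rbind(x = c(0.34, 0.33, 0.33))
  expect_identical(assign_labels(u3)$not_assigned, "x")
  expect_error(assign_labels(u, threshold = 0.4), "threshold")
  expect_error(assign_labels(u, threshold = 1), "threshold")
})
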