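# Independent oracles and fixture builders shared across the suite.

# Brute-force Jaccard distance: explicit double loop over disease pairs,
# counting patient-set intersections and unions. Deliberately naive and
# independent of the package's vectorised implementation.
jaccard_oracle <- function(v) {
  k <- ncol(v)
  d <- matrix(0, k, k, dimnames = list(colnames(v), colnames(v)))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      pa <- which(v[, a] == 1)
      pb <- which(v[, b] == 1)
      d[a, b] <- 1 - length(intersect(pa, pb)) / length(union(pa, pb))
    }
  }
  diag(d) <- 0
  d
}

# Random binary matrix with no all-zero column.
random_binary <- function(n, k) {
  repeat {
    v <- matrix(rbinom(n * k, 1, 0.4), n, k)
    if (all(colSums(v) > 0)) break
  }
  colnames(v) <- paste0("d", seq_len(k))
  v
}

# Well-separated 2-D Gaussian blobs with ground-truth labels.
make_blobs <- function(n_per = 20,
                       centers = rbind(c(0, 0), c(12, 0), c(0, 12)),
                       sd = 0.5, seed = 42) {
  set.seed(seed)
  g <- nrow(centers)
  coords <- do.call(rbind, lapply(seq_len(g), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  rownames(coords) <- sprintf("p%02d", seq_len(n_per * g))
  colnames(coords) <- c("x", "y")
  list(coords = coords, labels = rep(seq_len(g), each = n_per))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

.all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(.all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# Largest agreement fraction between two label vectors over relabellings.
perm_agreement <- function(a, b) {
  la <- sort(unique(a))
  lb <- sort(unique(b))
  stopifnot(length(la) == length(lb))
  max(vapply(.all_perms(la), function(p) {
    mean(p[match(b, lb)] == a)
  }, 0))
}

# Long records for a small hand-checkable cohort: 6 patients with row sums
# 1, 2, 3, 1, 2, 5 over 5 diseases, all ages in range.
records_six <- function() {
  sets <- list(P1 = "d1", P2 = c("d1", "d2"), P3 = c("d2", "d3", "d4"),
               P4 = "d5", P5 = c("d4", "d5"),
               P6 = c("d1", "d2", "d3", "d4", "d5"))
  ages <- c(30, 25, 70, 88, 100, 45)
  sexes <- c("M", "F", "F", "M", "F", "M")
  do.call(rbind, lapply(seq_along(sets), function(i) {
    data.frame(patient_id = names(sets)[i], sex = sexes[i], age = ages[i],
               disease_code = sets[[i]], stringsAsFactors = FALSE)
  }))
}

# Enumerate every n x k binary matrix as rows of bits (for small n * k).
enumerate_binary <- function(n, k) {
  total <- 2^(n * k)
  lapply(seq_len(total) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n * k)]
    matrix(bits, n, k, dimnames = list(NULL, paste0("d", seq_len(k))))
  })
}
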