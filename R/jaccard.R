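#' Jaccard co-occurrence distance between diseases
#'
#' Computes the K x K distance matrix D over the diseases (columns) of the
#' binary occurrence matrix C. Writing `P_k` for the set of patients carrying
#' disease k,
#' \deqn{d_{kl} = 1 - |P_k \cap P_l| / |P_k \cup P_l|,}
#' i.e. one minus the share of patients carrying either disease who carry
#' both. `d_kl = 0` iff the two patient sets coincide and `d_kl = 1` iff the
#' diseases never co-occur; values near 0 are strong evidence of
#' co-occurrence. The distance is computed on patient sets (binary
#' indicators), with no smoothing or prevalence correction, and is a metric.
#'
#' @param x An `occurrence_matrix` or a binary patient-by-disease matrix
#'   with column names.
#' @return Symmetric K x K numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, and disease codes as dimnames.
#' @examples
#' v <- rbind(c(1, 0), c(1, 1), c(1, 1), c(0, 1))
#' colnames(v) <- c("a", "b")
#' jaccard_distance_matrix(v)  # |intersect| = 2, |union| = 4 -> d = 0.5
#' @export
jaccard_distance_matrix <- function(x) {
  v <- if (inherits(x, "occurrence_matrix")) x$values else as.matrix(x)
  stopifnot(nrow(v) >= 1, ncol(v) >= 2, all(v %in% c(0L, 1L)))
  storage.mode(v) <- "double"
  cs <- colSums(v)
  if (any(cs == 0)) {
    stop("Jaccard distance undefined for diseases carried by no patient: ",
         paste(colnames(v)[cs == 0], collapse = ", "))
  }
  inter <- crossprod(v)
  uni <- outer(cs, cs, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  # exact symmetry regardless of floating-point summation order
  d <- (d + t(d)) / 2
  dimnames(d) <- list(colnames(v), colnames(v))
  d
}
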