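#' Specify a planted-block synthetic multimorbid cohort
#'
#' Defines a generative model for synthetic multimorbid populations with
#' known (planted) co-occurrence structure. Each patient draws a primary
#' disease block, carries each disease of that block independently with
#' probability `p_in` and every other blocked disease with `p_out`, so
#' within-block pairs co-occur more often than between-block pairs. A tail
#' of rare diseases (marginal prevalence below the exclusion threshold) is
#' drawn independently of the blocks. Patients with fewer than two diseases
#' are redrawn (rejection sampling), enforcing multimorbidity.
#'
#' Optionally each block is split into sub-blocks: the patient also draws a
#' primary sub-block within the primary block and carries its diseases with
#' the larger probability `p_in_sub`, planting nested structure that a
#' sub-clustering analysis should recover.
#'
#' Defaults are the validation conditions used throughout the test suite:
#' 5,000 patients, three blocks of eight diseases, `p_in = 0.4`,
#' `p_out = 0.02`, three rare diseases at 0.01% prevalence, uniform
#' sex-by-age strata.
#'
#' @param n_patients Number of patients N.
#' @param blocks List of disjoint character vectors of disease codes.
#' @param block_weights Probability vector over blocks (patient's primary
#'   block); defaults to uniform.
#' @param p_in Within-(primary-)block carriage probability.
#' @param p_out Out-of-block carriage probability (`p_out <= p_in`; equality
#'   gives the no-signal control in which blocks carry no information).
#' @param sub_blocks Optional list (one element per block) of lists of code
#'   vectors partitioning the block into sub-blocks.
#' @param p_in_sub Carriage probability within the primary sub-block
#'   (required with `sub_blocks`; must be `>= p_in`).
#' @param rare_diseases Named numeric vector: code -> marginal prevalence,
#'   each strictly below `rare_threshold`.
#' @param rare_threshold Exclusion threshold the rare tail must stay under.
#' @param strata_mix Probability vector over the 8 canonical strata (order
#'   of [canonical_strata()]); defaults to uniform.
#' @param seed Integer seed; identical seeds give bit-identical populations.
#' @return A `planted_model` object.
#' @export
planted_model <- function(n_patients = 5000L,
                          blocks = split(sprintf("B%dD%02d",
                                                 rep(1:3, each = 8),
                                                 rep(1:8, times = 3)),
                                         rep(1:3, each = 8)),
                          block_weights = NULL,
                          p_in = 0.4,
                          p_out = 0.02,
                          sub_blocks = NULL,
                          p_in_sub = NULL,
                          rare_diseases = c(RARE1 = 1e-4, RARE2 = 1e-4,
                                            RARE3 = 1e-4),
                          rare_threshold = 5e-4,
                          strata_mix = NULL,
                          seed = 1L) {
  blocks <- lapply(unname(blocks), as.character)
  block_codes <- unlist(blocks)
  if (anyDuplicated(block_codes)) stop("disease blocks must be disjoint")
  g_star <- length(blocks)
  block_weights <- block_weights %||% rep(1 / g_star, g_star)
  stopifnot(length(block_weights) == g_star,
            abs(sum(block_weights) - 1) < 1e-8,
            all(block_weights >= 0))
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1; got p_in = ", p_in,
         ", p_out = ", p_out)
  }
  if (!is.null(sub_blocks)) {
    stopifnot(length(sub_blocks) == g_star, !is.null(p_in_sub),
              p_in_sub >= p_in, p_in_sub <= 1)
    for (b in seq_len(g_star)) {
      part <- unlist(lapply(sub_blocks[[b]], as.character))
      if (!setequal(part, blocks[[b]]) || anyDuplicated(part)) {
        stop("sub_blocks[[", b, "]] must partition blocks[[", b, "]]")
      }
    }
  }
  if (length(rare_diseases)) {
    stopifnot(!is.null(names(rare_diseases)),
              !anyDuplicated(names(rare_diseases)),
              !any(names(rare_diseases) %in% block_codes))
    if (any(rare_diseases >= rare_threshold) || any(rare_diseases < 0)) {
      stop("rare-disease prevalences must lie in [0, ", rare_threshold, ")")
    }
  }
  strata_mix <- strata_mix %||% rep(1 / 8, 8)
  stopifnot(length(strata_mix) == 8, abs(sum(strata_mix) - 1) < 1e-8,
            all(strata_mix >= 0))
  stopifnot(n_patients >= 1)
  structure(list(n_patients = as.integer(n_patients), blocks = blocks,
                 block_weights = block_weights, p_in = p_in, p_out = p_out,
                 sub_blocks = sub_blocks, p_in_sub = p_in_sub,
                 rare_diseases = rare_diseases,
                 rare_threshold = rare_threshold,
                 strata_mix = strata_mix, seed = as.integer(seed)),
            class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat("<planted_model> N = ", x$n_patients, "; ", length(x$blocks),
      " blocks (", paste(lengths(x$blocks), collapse = ", "),
      " diseases); p_in = ", x$p_in, ", p_out = ", x$p_out,
      if (!is.null(x$sub_blocks)) paste0(", p_in_sub = ", x$p_in_sub),
      "; ", length(x$rare_diseases), " rare; seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# Draw the N x K carriage indicators for a set of patient block assignments.
.draw_carriage <- function(model, n, primary, sub_primary) {
  blocks <- model$blocks
  block_of <- rep(seq_along(blocks), lengths(blocks))
  p <- matrix(model$p_out, nrow = n, ncol = length(block_of))
  in_block <- outer(primary, block_of, "==")
  p[in_block] <- model$p_in
  if (!is.null(model$sub_blocks)) {
    codes <- unlist(blocks)
    sub_of <- rep(NA_integer_, length(codes))
    for (b in seq_along(blocks)) {
      for (s in seq_along(model$sub_blocks[[b]])) {
        sub_of[codes %in% model$sub_blocks[[b]][[s]]] <- s
      }
    }
    in_sub <- in_block & outer(sub_primary, sub_of, "==")
    p[in_sub] <- model$p_in_sub
  }
  vb <- matrix(runif(n * ncol(p)) < p, nrow = n)
  if (length(model$rare_diseases)) {
    vr <- matrix(runif(n * length(model$rare_diseases)) <
                   rep(model$rare_diseases, each = n), nrow = n)
    vb <- cbind(vb, vr)
  }
  storage.mode(vb) <- "integer"
  colnames(vb) <- c(unlist(blocks), names(model$rare_diseases))
  vb
}

.draw_blocks <- function(model, n) {
  primary <- sample.int(length(model$blocks), n, replace = TRUE,
                        prob = model$block_weights)
  sub_primary <- if (is.null(model$sub_blocks)) rep(NA_integer_, n) else {
    n_sub <- lengths(model$sub_blocks)[primary]
    as.integer(floor(runif(n) * n_sub) + 1)
  }
  list(primary = primary, sub_primary = sub_primary)
}

#' Generate a synthetic multimorbid population
#'
#' Samples a cohort from a [planted_model()]: primary blocks, disease
#' carriage, rare tail, sex/age strata. Whole patients with fewer than two
#' diseases are redrawn until the multimorbidity constraint holds (capped at
#' 1,000 rounds; an infeasible model errors). Output is bit-identical for
#' identical models (including seed).
#'
#' @param model A `planted_model`.
#' @return List with `matrix` (an `occurrence_matrix`, catalog in byte-sorted
#'   code order), `truth` (named integer vector: code -> planted block index,
#'   `0` for rare/unblocked diseases), `sub_truth` (code -> global sub-block
#'   index, `0` where inapplicable, `NULL` for non-nested models) and
#'   `model`.
#' @export
generate_population <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  n <- model$n_patients
  with_seed(model$seed, {
    draw <- .draw_blocks(model, n)
    v <- .draw_carriage(model, n, draw$primary, draw$sub_primary)
    bad <- which(rowSums(v) < 2)
    rounds <- 0
    while (length(bad)) {
      rounds <- rounds + 1
      if (rounds > 1000) {
        stop("could not satisfy the >= 2 diseases constraint within 1000 ",
             "redraw rounds; the model is infeasible (p_in = ", model$p_in,
             ", p_out = ", model$p_out, ", blocks of ",
             paste(lengths(model$blocks), collapse = "/"), " diseases)")
      }
      redraw <- .draw_blocks(model, length(bad))
      v[bad, ] <- .draw_carriage(model, length(bad), redraw$primary,
                                 redraw$sub_primary)
      bad <- bad[rowSums(v[bad, , drop = FALSE]) < 2]
    }
    strata <- canonical_strata()
    s_idx <- sample.int(8, n, replace = TRUE, prob = model$strata_mix)
    sex <- vapply(strata, `[[`, "", "sex")[s_idx]
    cls <- vapply(strata, `[[`, "", "age_class")[s_idx]
    lo <- .age_breaks[match(cls, age_classes)]
    hi <- .age_breaks[match(cls, age_classes) + 1] - 1L
    age <- lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
    patients <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                           sex = sex, age = age,
                           age_class = age_class_of(age),
                           stringsAsFactors = FALSE)
    ord <- order(colnames(v), method = "radix")
    v <- v[, ord, drop = FALSE]
    mat <- new_occurrence_matrix(v, patients, disease_catalog(colnames(v)))

    truth <- c(rep(seq_along(model$blocks), lengths(model$blocks)),
               rep(0L, length(model$rare_diseases)))
    names(truth) <- c(unlist(model$blocks), names(model$rare_diseases))
    sub_truth <- NULL
    if (!is.null(model$sub_blocks)) {
      flat <- unlist(lapply(model$sub_blocks, function(b) b), recursive = FALSE)
      sub_truth <- rep(0L, length(truth))
      names(sub_truth) <- names(truth)
      for (s in seq_along(flat)) sub_truth[flat[[s]]] <- s
    }
    list(matrix = mat, truth = truth, sub_truth = sub_truth, model = model)
  })
}

#' Align planted block labels with a catalog
#'
#' @param truth Named integer vector (code -> block index; `0` is the
#'   sentinel for rare/unblocked diseases).
#' @param catalog A [disease_catalog()] or character vector of codes, every
#'   one present in `truth`.
#' @return Integer label vector in catalog order (named), usable for
#'   adjusted-Rand comparisons against pipeline hard labels.
#' @export
planted_labels <- function(truth, catalog) {
  codes <- as.character(catalog)
  unknown <- setdiff(codes, names(truth))
  if (length(unknown)) {
    stop("codes absent from the planted truth: ",
         paste(unknown, collapse = ", "))
  }
  truth[codes]
}
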