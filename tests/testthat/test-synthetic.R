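no_rare <- stats::setNames(numeric(0), character(0))

test_that("degenerate probabilities give the exact planted block", {
  m <- planted_model(n_patients = 50, blocks = list(c("a", "b", "c")),
                     p_in = 1, p_out = 0, rare_diseases = no_rare, seed = 3)
  pop <- generate_population(m)
  expect_true(all(pop$matrix$values == 1L))
  d <- jaccard_distance_matrix(pop$matrix)
  expect_true(all(d == 0))
  expect_identical(unname(pop$truth), rep(1L, 3))
})

test_that("every generated patient is multimorbid and output is seeded", {
  m <- planted_model(n_patients = 800, p_in = 0.3, p_out = 0.02, seed = 5)
  a <- generate_population(m)
  expect_true(all(rowSums(a$matrix$values) >= 2))
  # bit-identical under the same seed, different under another
  b <- generate_population(m)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$matrix$patients, b$matrix$patients)
  m2 <- planted_model(n_patients = 800, p_in = 0.3, p_out = 0.02, seed = 6)
  expect_false(identical(generate_population(m2)$matrix$values,
                         a$matrix$values))
})

test_that("planted blocks induce lower within-block Jaccard distance", {
  pop <- generate_population(planted_model(seed = 1))
  er <- exclude_rare(pop$matrix)
  d <- jaccard_distance_matrix(er$matrix)
  lab <- planted_labels(pop$truth, colnames(er$matrix$values))
  same <- outer(lab, lab, "==") & upper.tri(d)
  diff <- outer(lab, lab, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})

test_that("rare-disease marginals converge to their stated prevalence", {
  m <- planted_model(n_patients = 50000,
                     rare_diseases = c(R1 = 4e-4, R2 = 2e-4), seed = 17)
  pop <- generate_population(m)
  prev <- disease_prevalence(pop$matrix)
  for (code in names(m$rare_diseases)) {
    p <- m$rare_diseases[[code]]
    se <- sqrt(p * (1 - p) / m$n_patients)
    expect_lt(abs(prev[[code]] - p), 3 * se)
  }
})

test_that("no-signal models are allowed and infeasible ones error", {
  expect_s3_class(planted_model(p_in = 0.1, p_out = 0.1), "planted_model")
  expect_error(planted_model(p_in = 0.1, p_out = 0.2), "p_out <= p_in")
  expect_error(planted_model(rare_diseases = c(R = 0.01)),
               "rare-disease prevalences")
  expect_error(planted_model(blocks = list(c("a", "b"), c("b", "c"))),
               "disjoint")
  starved <- planted_model(n_patients = 10, blocks = list(c("a", "b")),
                           p_in = 0.001, p_out = 0, rare_diseases = no_rare,
                           seed = 1)
  expect_error(generate_population(starved), "1000 redraw rounds")
})

test_that("planted labels align with any catalog order", {
  truth <- c(a = 1L, b = 1L, c = 2L, d = 2L, r = 0L)
  expect_identical(planted_labels(truth, c("a", "b")), c(a = 1L, b = 1L))
  cat1 <- c("a", "c", "r", "b", "d")
  lab1 <- planted_labels(truth, cat1)
  expect_identical(lab1, truth[cat1])
  # permuting the catalog permutes the labels identically
  p <- c(3, 1, 5, 2, 4)
  expect_identical(planted_labels(truth, cat1[p]), lab1[p])
  expect_error(planted_labels(truth, c("a", "zz")), "zz")
})

test_that("nested models plant recoverable sub-block structure", {
  blocks <- list(c("a1", "a2", "a3", "a4"), c("b1", "b2", "b3", "b4"))
  subs <- list(list(c("a1", "a2"), c("a3", "a4")),
               list(c("b1", "b2"), c("b3", "b4")))
  m <- planted_model(n_patients = 2000, blocks = blocks, sub_blocks = subs,
                     p_in = 0.3, p_in_sub = 0.8, p_out = 0.02,
                     rare_diseases = no_rare, seed = 23)
  pop <- generate_population(m)
  expect_identical(unname(pop$sub_truth),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  d <- jaccard_distance_matrix(pop$matrix)
  lab <- planted_labels(pop$sub_truth, colnames(pop$matrix$values))
  same <- outer(lab, lab, "==") & upper.tri(d)
  diff <- outer(lab, lab, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
  expect_error(planted_model(blocks = blocks,
                             sub_blocks = list(subs[[1]], list("b1")),
                             p_in = 0.3, p_in_sub = 0.8),
               "partition")
})
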