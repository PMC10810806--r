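test_that("build_matrix constructs the binary indicator matrix", {
  rec <- data.frame(patient_id = c("A", "A", "B", "B"),
                    sex = c("F", "F", "M", "M"), age = c(40, 40, 70, 70),
                    disease_code = c("d1", "d2", "d2", "d3"))
  m <- build_matrix(rec, disease_catalog(c("d1", "d2", "d3")))
  expect_identical(unname(m$values), rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)))
  expect_identical(colnames(m$values), c("d1", "d2", "d3"))

  # one patient with every catalog disease -> a row of ones
  full <- data.frame(patient_id = "Z", sex = "F", age = 50,
                     disease_code = c("d1", "d2", "d3"))
  expect_identical(unname(build_matrix(full)$values[1, ]), rep(1L, 3))

  # 5-patient, 4-disease fixture checked cell by cell against a hand table
  sets <- list(P1 = c("a", "b"), P2 = c("b", "c"), P3 = "d",
               P4 = c("a", "c", "d"), P5 = c("a", "b", "c", "d"))
  rec5 <- do.call(rbind, lapply(names(sets), function(p) {
    data.frame(patient_id = p, sex = "M", age = 60, disease_code = sets[[p]])
  }))
  hand <- rbind(c(1, 1, 0, 0),
                c(0, 1, 1, 0),
                c(0, 0, 0, 1),
                c(1, 0, 1, 1),
                c(1, 1, 1, 1))
  m5 <- build_matrix(rec5)
  expect_identical(unname(m5$values), matrix(as.integer(hand), 5, 4))
  expect_identical(colnames(m5$values), c("a", "b", "c", "d"))

  # duplicate pairs collapse; conflicting attributes are an error
  expect_identical(build_matrix(rbind(rec, rec))$values, m$values)
  bad <- rec
  bad$age[3] <- 71
  expect_error(build_matrix(bad), "duplicate patient_id.*B")
  expect_error(build_matrix(rec, disease_catalog(c("d1", "d2"))),
               "not in catalog.*d3")
})

test_that("multimorbidity filter keeps row sums >= 2 within the age window", {
  m <- build_matrix(records_six())
  f <- filter_multimorbid(m)
  # row sums 1,2,3,1,2,5 -> 4 retained; boundary ages 25 and 100 included
  expect_identical(f$patients$patient_id, c("P2", "P3", "P5", "P6"))
  expect_true(all(rowSums(f$values) >= 2))
  expect_identical(ncol(f$values), ncol(m$values))
  # idempotent
  expect_identical(filter_multimorbid(f), f)
  # age window is enforced
  old <- build_matrix(data.frame(patient_id = "Q", sex = "F", age = 101,
                                 disease_code = c("d1", "d2")))
  expect_error(filter_multimorbid(old), "no patient")
})

test_that("stratification follows the closed age classes and partitions", {
  expect_identical(age_class_of(c(25, 44, 45, 64, 65, 84, 85, 100)),
                   c("25-44", "25-44", "45-64", "45-64", "65-84", "65-84",
                     "85-100", "85-100"))
  expect_true(is.na(age_class_of(24)) && is.na(age_class_of(101)))

  m <- build_matrix(records_six())
  s <- stratify(m, stratum("M", "65-84"))
  expect_identical(s$patients$patient_id, character(0))
  s2 <- stratify(m, stratum("F", "65-84"))
  expect_identical(s2$patients$patient_id, "P3")
  expect_identical(stratify(m, stratum("all", "all"))$values, m$values)

  # the 8 canonical strata are disjoint and exhaustive
  pop <- generate_population(planted_model(n_patients = 400, seed = 9))
  parts <- lapply(canonical_strata(), function(st)
    stratify(pop$matrix, st)$patients$patient_id)
  ids <- unlist(parts, use.names = FALSE)
  expect_identical(sort(ids), sort(pop$matrix$patients$patient_id))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("rare-disease exclusion is strict and idempotent", {
  # column sums 500, 3, 1 over N = 10000 -> prevalences 5%, 0.03%, 0.01%
  v <- matrix(0L, 10000, 3, dimnames = list(NULL, c("common", "low", "tiny")))
  v[1:500, 1] <- 1L
  v[1:3, 2] <- 1L
  v[1, 3] <- 1L
  pts <- data.frame(patient_id = sprintf("P%05d", 1:10000), sex = "F",
                    age = 50L, age_class = "45-64")
  m <- morbclust:::new_occurrence_matrix(v, pts, disease_catalog(colnames(v)))
  er <- exclude_rare(m, 5e-4)
  expect_identical(er$excluded, c("low", "tiny"))
  expect_identical(colnames(er$matrix$values), "common")
  expect_identical(er$report$prevalence, c(0.05, 3e-4, 1e-4))

  # exactly at the threshold is retained ("lower than" is strict)
  v2 <- v
  v2[1:5, 3] <- 1L  # 5/10000 = 0.05% exactly
  m2 <- morbclust:::new_occurrence_matrix(v2, pts,
                                          disease_catalog(colnames(v2)))
  expect_identical(exclude_rare(m2, 5e-4)$excluded, "low")

  # idempotent; all-excluded errors
  again <- exclude_rare(er$matrix, 5e-4)
  expect_identical(again$matrix$values, er$matrix$values)
  expect_length(again$excluded, 0)
  expect_error(exclude_rare(m, threshold = 0.9), "all 3 diseases")
})

test_that("disease prevalence is column sum over population size", {
  v <- cbind(ones = rep(1L, 12), zeros = rep(0L, 12),
             three = c(rep(1L, 3), rep(0L, 9)))
  pts <- data.frame(patient_id = paste0("P", 1:12), sex = "M", age = 30L,
                    age_class = "25-44")
  m <- morbclust:::new_occurrence_matrix(v, pts, disease_catalog(colnames(v)))
  expect_equal(disease_prevalence(m),
               c(ones = 1, three = 0.25, zeros = 0)[colnames(v)])
})

test_that("records round-trip through the matrix and through CSV", {
  rec <- records_six()
  m <- build_matrix(rec)
  back <- as_patient_records(m)
  m2 <- build_matrix(back)
  expect_identical(m2$values, m$values)
  expect_identical(m2$patients, m$patients)

  long_path <- withr::local_tempfile(fileext = ".csv")
  write_patient_csv(rec, long_path)
  expect_identical(build_matrix(read_patient_csv(long_path))$values, m$values)

  mat_path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(m, mat_path)
  m3 <- read_matrix_csv(mat_path)
  expect_identical(m3$values, m$values)
  expect_identical(m3$patients$age, m$patients$age)
})
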