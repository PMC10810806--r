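#' Canonical age classes of the study design
#'
#' Adult multimorbid patients are analysed in four closed integer age classes:
#' 25--44, 45--64, 65--84 and 85--100 years. Together with sex (M, F) they
#' define the eight canonical strata.
#'
#' @format Character vector of class labels.
#' @export
age_classes <- c("25-44", "45-64", "65-84", "85-100")

.age_breaks <- c(25L, 45L, 65L, 85L, 101L)

#' Age class of an integer age
#'
#' @param age Integer vector of ages in years.
#' @return Character vector of age-class labels; `NA` outside 25--100.
#' @examples
#' age_class_of(c(25, 44, 45, 64, 65, 100))
#' @export
age_class_of <- function(age) {
  as.character(cut(as.integer(age), breaks = .age_breaks,
                   labels = age_classes, right = FALSE))
}

#' Disease catalog
#'
#' An ordered set of unique disease codes. The catalog order fixes the
#' row/column order of every downstream matrix, so it must be reproducible:
#' when a catalog is inferred from data the codes are sorted byte-wise
#' (locale-independent radix sort); an explicitly supplied catalog keeps the
#' order given.
#'
#' @param codes Character vector of unique disease codes.
#' @param labels Optional character vector of human-readable names, same
#'   length as `codes`.
#' @return A `disease_catalog` object (a character vector of codes).
#' @export
disease_catalog <- function(codes, labels = NULL) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) {
    stop("duplicate disease codes in catalog: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(codes))
    names(labels) <- codes
  }
  structure(codes, labels = labels, class = c("disease_catalog", "character"))
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat("<disease_catalog> ", length(x), " codes: ",
      paste(utils::head(unclass(x), 8), collapse = ", "),
      if (length(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

new_occurrence_matrix <- function(values, patients, catalog) {
  storage.mode(values) <- "integer"
  stopifnot(nrow(values) == nrow(patients),
            ncol(values) == length(catalog),
            all(values %in% c(0L, 1L)))
  dimnames(values) <- list(patients$patient_id, as.character(catalog))
  structure(list(values = values, patients = patients, catalog = catalog),
            class = "occurrence_matrix")
}

#' @export
dim.occurrence_matrix <- function(x) dim(x$values)

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("<occurrence_matrix> ", nrow(x$values), " patients x ",
      ncol(x$values), " diseases; mean diseases/patient ",
      format(mean(rowSums(x$values)), digits = 4), "\n", sep = "")
  invisible(x)
}

# Row/column subset that keeps values, patient attributes and catalog aligned.
om_subset <- function(x, rows = NULL, cols = NULL) {
  v <- x$values
  p <- x$patients
  cat <- x$catalog
  if (!is.null(rows)) {
    v <- v[rows, , drop = FALSE]
    p <- p[rows, , drop = FALSE]
  }
  if (!is.null(cols)) {
    v <- v[, cols, drop = FALSE]
    keep <- colnames(v)
    cat <- disease_catalog(keep, labels = attr(cat, "labels")[keep])
  }
  rownames(p) <- NULL
  new_occurrence_matrix(v, p, cat)
}

.check_records <- function(records) {
  needed <- c("patient_id", "sex", "age", "disease_code")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("records must have columns ", paste(needed, collapse = ", "),
         "; missing: ", paste(missing, collapse = ", "))
  }
  bad_sex <- setdiff(unique(records$sex), c("M", "F"))
  if (length(bad_sex)) stop("sex must be 'M' or 'F'; found: ",
                            paste(bad_sex, collapse = ", "))
  records
}

#' Build the binary patient-by-disease occurrence matrix
#'
#' Constructs the N x K indicator matrix C with `C[i, k] = 1` when patient i
#' carries disease k. Input is a long table with one row per patient-disease
#' pair (duplicated pairs are collapsed); each patient must have consistent
#' sex and age across rows.
#'
#' @param records Data frame with columns `patient_id`, `sex` (`"M"`/`"F"`),
#'   `age` (integer years) and `disease_code`.
#' @param catalog Optional [disease_catalog()]. When absent, the catalog is
#'   inferred from the data (codes sorted byte-wise). When present, any code
#'   not in the catalog is an error.
#' @return An `occurrence_matrix`: binary values, per-patient attributes
#'   (`patient_id`, `sex`, `age`, `age_class`) and the catalog.
#' @examples
#' rec <- data.frame(patient_id = c("A", "A", "B", "B"),
#'                   sex = "F", age = 70,
#'                   disease_code = c("d1", "d2", "d2", "d3"))
#' build_matrix(rec)$values
#' @export
build_matrix <- function(records, catalog = NULL) {
  records <- .check_records(as.data.frame(records))
  if (nrow(records) == 0) stop("records is empty")
  records$patient_id <- as.character(records$patient_id)
  records$disease_code <- as.character(records$disease_code)
  records$age <- as.integer(records$age)

  attrs <- unique(records[c("patient_id", "sex", "age")])
  dup <- unique(attrs$patient_id[duplicated(attrs$patient_id)])
  if (length(dup)) {
    stop("duplicate patient_id with conflicting attributes: ",
         paste(dup, collapse = ", "))
  }

  if (is.null(catalog)) {
    catalog <- disease_catalog(sort(unique(records$disease_code),
                                    method = "radix"))
  } else {
    if (!inherits(catalog, "disease_catalog")) catalog <- disease_catalog(catalog)
    unknown <- setdiff(unique(records$disease_code), as.character(catalog))
    if (length(unknown)) {
      stop("disease codes not in catalog: ", paste(unknown, collapse = ", "))
    }
  }

  pid <- attrs$patient_id
  v <- matrix(0L, nrow = length(pid), ncol = length(catalog))
  v[cbind(match(records$patient_id, pid),
          match(records$disease_code, as.character(catalog)))] <- 1L
  patients <- data.frame(patient_id = pid, sex = attrs$sex, age = attrs$age,
                         age_class = age_class_of(attrs$age),
                         stringsAsFactors = FALSE)
  rownames(patients) <- NULL
  new_occurrence_matrix(v, patients, catalog)
}

#' Convert an occurrence matrix back to long patient records
#'
#' Inverse of [build_matrix()] (up to row order): one row per patient-disease
#' pair.
#'
#' @param x An `occurrence_matrix`.
#' @return Data frame with columns `patient_id`, `sex`, `age`, `disease_code`.
#' @export
as_patient_records <- function(x) {
  idx <- which(x$values == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(patient_id = x$patients$patient_id[idx[, 1]],
             sex = x$patients$sex[idx[, 1]],
             age = x$patients$age[idx[, 1]],
             disease_code = as.character(x$catalog)[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Restrict a cohort to multimorbid patients in the study age window
#'
#' Keeps patients carrying at least `min_diseases` chronic conditions (the
#' multimorbidity definition: two or more) whose age lies in
#' `[age_min, age_max]`. Columns are unchanged.
#'
#' @param x An `occurrence_matrix`.
#' @param min_diseases Minimum number of diseases per retained patient.
#' @param age_min,age_max Inclusive age bounds in years.
#' @return The filtered `occurrence_matrix`.
#' @export
filter_multimorbid <- function(x, min_diseases = 2L, age_min = 25L,
                               age_max = 100L) {
  stopifnot(inherits(x, "occurrence_matrix"), min_diseases >= 1)
  keep <- rowSums(x$values) >= min_diseases &
    x$patients$age >= age_min & x$patients$age <= age_max
  if (!any(keep)) {
    stop("no patient satisfies the multimorbidity/age filter (min_diseases = ",
         min_diseases, ", age in [", age_min, ", ", age_max, "]); ",
         "downstream distances are undefined on an empty cohort")
  }
  om_subset(x, rows = which(keep))
}

#' Define a population stratum
#'
#' @param sex `"M"`, `"F"` or `"all"`.
#' @param age_class One of `age_classes` or `"all"`.
#' @return A `stratum` object.
#' @export
stratum <- function(sex = "all", age_class = "all") {
  sex <- match.arg(sex, c("all", "M", "F"))
  age_class <- match.arg(age_class, c("all", age_classes))
  structure(list(sex = sex, age_class = age_class), class = "stratum")
}

#' @export
format.stratum <- function(x, ...) paste(x$sex, x$age_class, sep = "/")

#' @export
print.stratum <- function(x, ...) {
  cat("<stratum> ", format(x), "\n", sep = "")
  invisible(x)
}

#' The eight canonical sex-by-age strata
#'
#' @return Named list of the 8 [stratum()] objects (2 sexes x 4 age classes).
#' @export
canonical_strata <- function() {
  grid <- expand.grid(age_class = age_classes, sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)),
                function(i) stratum(grid$sex[i], grid$age_class[i]))
  names(out) <- vapply(out, format, "")
  out
}

#' Restrict a cohort to one sex-by-age stratum
#'
#' The `"all"` wildcard matches every patient; the 8 canonical strata
#' partition the cohort (pairwise disjoint, exhaustive). An empty result is
#' allowed here; downstream operations error on emptiness.
#'
#' @param x An `occurrence_matrix`.
#' @param s A [stratum()].
#' @return The restricted `occurrence_matrix`.
#' @export
stratify <- function(x, s) {
  stopifnot(inherits(x, "occurrence_matrix"), inherits(s, "stratum"))
  keep <- rep(TRUE, nrow(x$values))
  if (s$sex != "all") keep <- keep & x$patients$sex == s$sex
  if (s$age_class != "all") {
    keep <- keep & !is.na(x$patients$age_class) &
      x$patients$age_class == s$age_class
  }
  om_subset(x, rows = which(keep))
}

#' Exclude rare diseases from a population
#'
#' Drops diseases whose marginal prevalence (column sum / number of patients
#' in the current population) is strictly below `threshold`, following the
#' European rare-disease convention of 0.05%. Applied per (sub)population,
#' i.e. after stratification; rows are not re-filtered for multimorbidity
#' afterwards, so denominators stay stable.
#'
#' @param x An `occurrence_matrix`.
#' @param threshold Prevalence threshold as a proportion (default `5e-4`).
#' @return List with `matrix` (columns retained), `excluded` (character
#'   vector of dropped codes) and `report` (data frame
#'   `disease_code, prevalence, excluded`).
#' @export
exclude_rare <- function(x, threshold = 5e-4) {
  stopifnot(inherits(x, "occurrence_matrix"), nrow(x$values) >= 1)
  prev <- colSums(x$values) / nrow(x$values)
  drop <- prev < threshold
  if (all(drop)) {
    stop("all ", length(prev), " diseases fall below the prevalence ",
         "threshold ", threshold, "; nothing left to analyse")
  }
  report <- data.frame(disease_code = names(prev),
                       prevalence = unname(prev),
                       excluded = unname(drop),
                       stringsAsFactors = FALSE)
  list(matrix = om_subset(x, cols = which(!drop)),
       excluded = names(prev)[drop],
       report = report)
}

#' Marginal disease prevalence
#'
#' Column sum divided by the number of patients of the analysed population.
#'
#' @param x An `occurrence_matrix`.
#' @return Named numeric vector of proportions in `[0, 1]`.
#' @export
disease_prevalence <- function(x) {
  stopifnot(inherits(x, "occurrence_matrix"), nrow(x$values) >= 1)
  colSums(x$values) / nrow(x$values)
}
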