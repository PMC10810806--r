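#' Read a long patient-disease CSV
#'
#' Expected header: `patient_id,sex,age,disease_code`, one row per
#' patient-disease pair, UTF-8. Duplicate pairs are tolerated (they collapse
#' in [build_matrix()]).
#'
#' @param path Path to the CSV file.
#' @return Data frame of records suitable for [build_matrix()].
#' @export
read_patient_csv <- function(path) {
  rec <- read.csv(path, colClasses = c(patient_id = "character",
                                       sex = "character",
                                       age = "integer",
                                       disease_code = "character"),
                  fileEncoding = "UTF-8")
  .check_records(rec)
}

#' Write a long patient-disease CSV
#'
#' @param records Data frame with columns `patient_id,sex,age,disease_code`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(records, path) {
  write.csv(.check_records(records)[c("patient_id", "sex", "age",
                                      "disease_code")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an occurrence matrix as wide CSV plus attribute companion
#'
#' The matrix CSV has `patient_id` first, then one 0/1 column per disease
#' code; the companion CSV carries `patient_id,sex,age`.
#'
#' @param x An `occurrence_matrix`.
#' @param path Matrix CSV path.
#' @param attrs_path Companion CSV path (default: `path` with `_attrs`
#'   inserted before the extension).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path,
                             attrs_path = sub("(\\.[^.]+)?$", "_attrs\\1",
                                              path)) {
  stopifnot(inherits(x, "occurrence_matrix"))
  df <- data.frame(patient_id = x$patients$patient_id, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  write.csv(x$patients[c("patient_id", "sex", "age")], attrs_path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an occurrence matrix written by [write_matrix_csv()]
#'
#' @param path Matrix CSV path.
#' @param attrs_path Companion attribute CSV path.
#' @return An `occurrence_matrix`.
#' @export
read_matrix_csv <- function(path,
                            attrs_path = sub("(\\.[^.]+)?$", "_attrs\\1",
                                             path)) {
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(patient_id = "character"))
  at <- read.csv(attrs_path, colClasses = c(patient_id = "character",
                                            sex = "character",
                                            age = "integer"))
  stopifnot(identical(df$patient_id, at$patient_id))
  v <- as.matrix(df[, -1, drop = FALSE])
  patients <- data.frame(patient_id = at$patient_id, sex = at$sex,
                         age = at$age, age_class = age_class_of(at$age),
                         stringsAsFactors = FALSE)
  new_occurrence_matrix(v, patients, disease_catalog(colnames(v)))
}

# Full-precision numeric formatting for CSV artifacts (round-trips doubles).
.fmt_full <- function(x) sprintf("%.17g", x)

#' Write a square distance matrix as CSV
#'
#' Disease codes appear as header row and first column; values at full
#' double precision.
#'
#' @param d Square numeric matrix with disease-code dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  df <- data.frame(disease_code = rownames(d),
                   apply(d, 2, .fmt_full),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
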