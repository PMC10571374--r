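# Cohort schema, validation, CSV I/O, and diagnosis stratification.

# Column schema for a patient cohort. cr_popf is the outcome label and is
# optional at prediction time; vfa, sarcopenia and cholesterol were not
# recorded in every hospital's dataset and are optional throughout.
cohort_columns <- function() {
  list(
    required = c("id", "age", "sex", "height", "weight", "bmi", "albumin",
                 "lymphocytes", "pni", "parenchymal_thickness", "mpd_size",
                 "mpd_index", "diabetes", "biliary_drainage", "conut",
                 "diagnosis"),
    optional = c("vfa", "sarcopenia", "cholesterol", "cr_popf"),
    logical = c("diabetes", "biliary_drainage", "sarcopenia", "cr_popf"),
    character = c("id", "sex", "diagnosis")
  )
}

#' Validate a patient cohort
#'
#' Checks the cohort schema: required columns, unique ids, factor levels,
#' strict positivity of continuous physiological values, and internal
#' consistency of the derived markers (`bmi = weight / height^2` and
#' `mpd_index = mpd_size / parenchymal_thickness` within `tol`).
#'
#' @param cohort a data frame, one row per patient
#' @param tol absolute tolerance for derived-marker consistency
#' @return the cohort, invisibly, after coercion to a tibble
#' @export
validate_cohort <- function(cohort, tol = 1e-6) {
  sc <- cohort_columns()
  missing_cols <- setdiff(sc$required, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(cohort), c(sc$required, sc$optional))
  if (length(unknown))
    stop("unknown cohort columns: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(cohort$id)) {
    dup <- unique(cohort$id[duplicated(cohort$id)])
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(cohort$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(cohort$diagnosis %in% c("PDAC", "non-PDAC")))
    stop("diagnosis must be 'PDAC' or 'non-PDAC'")
  pos_cols <- c("age", "height", "weight", "bmi", "vfa", "albumin",
                "lymphocytes", "pni", "parenchymal_thickness", "mpd_size",
                "mpd_index", "cholesterol")
  for (cl in intersect(pos_cols, names(cohort))) {
    x <- cohort[[cl]]
    if (any(!is.na(x) & (!is.finite(x) | x <= 0)))
      stop("non-positive value in column '", cl, "'")
  }
  if (any(!is.na(cohort$conut) & cohort$conut < 0))
    stop("conut must be non-negative")
  bad <- abs(cohort$bmi - cohort$weight / cohort$height^2) > tol
  if (any(bad, na.rm = TRUE))
    stop("bmi inconsistent with weight/height^2 for id(s): ",
         paste(cohort$id[which(bad)], collapse = ", "))
  bad <- abs(cohort$mpd_index -
               cohort$mpd_size / cohort$parenchymal_thickness) > tol
  if (any(bad, na.rm = TRUE))
    stop("mpd_index inconsistent with mpd_size/parenchymal_thickness ",
         "for id(s): ", paste(cohort$id[which(bad)], collapse = ", "))
  invisible(tibble::as_tibble(cohort))
}

#' Read a patient cohort from CSV
#'
#' The file is UTF-8, comma-separated, with a header row naming the schema
#' columns; boolean columns are coded 0/1. The cohort is validated on read.
#'
#' @param path file path
#' @return a tibble, one row per patient
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  sc <- cohort_columns()
  for (cl in intersect(sc$logical, names(raw))) {
    x <- raw[[cl]]
    if (!all(x %in% c(0, 1, NA)))
      stop("column '", cl, "' must be coded 0/1 (row ",
           which(!x %in% c(0, 1, NA))[1], ")")
    raw[[cl]] <- as.logical(x)
  }
  if (anyDuplicated(raw$id)) {
    dup_row <- which(duplicated(raw$id))[1]
    stop("duplicate record id '", raw$id[dup_row], "' at row ", dup_row)
  }
  cohort <- tibble::as_tibble(raw)
  if (nrow(cohort) > 0) validate_cohort(cohort)
  cohort
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: boolean columns are written as 0/1 and a
#' write-then-read round trip reproduces the cohort exactly.
#'
#' @param cohort a cohort data frame
#' @param path file path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (cl in intersect(cohort_columns()$logical, names(out)))
    out[[cl]] <- as.integer(out[[cl]])
  for (cl in names(out))
    if (is.double(out[[cl]])) out[[cl]] <- fmt_double(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Shortest decimal representation that parses back to the same double, so
# a CSV round trip is lossless.
fmt_double <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 15:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Split a cohort by preoperative diagnosis
#'
#' Partitions the cohort into the pancreatic ductal adenocarcinoma stratum
#' and the non-PDAC stratum. The two submodels of the final prediction model
#' are fitted and evaluated within these strata.
#'
#' @param cohort a cohort data frame with a `diagnosis` column
#' @return named list with elements `PDAC` and `non-PDAC`
#' @export
stratify_by_diagnosis <- function(cohort) {
  if (anyNA(cohort$diagnosis))
    stop("every record needs a diagnosis")
  list("PDAC" = cohort[cohort$diagnosis == "PDAC", , drop = FALSE],
       "non-PDAC" = cohort[cohort$diagnosis == "non-PDAC", , drop = FALSE])
}
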