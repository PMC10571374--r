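# Marker panel, derived preoperative markers, and cut-off discretization.

#' The 14-marker candidate panel
#'
#' Returns the panel of candidate CR-POPF predictors with their kinds and
#' discretization cut-offs. Continuous markers are dichotomized at the listed
#' cut-off (value at or above the cut-off maps to bin 1); binary markers are
#' coded 1 when the condition is present (male sex, diabetes, biliary
#' drainage, sarcopenia, PDAC diagnosis).
#'
#' Cut-offs: age 65 y, BMI 25 kg/m2, VFA 100 cm2, PNI 45, albumin 3.5 g/dL,
#' parenchymal thickness 13 mm, MPD size 3 mm, MPD index 0.3, CONUT 3
#' (the usual ">= 3" malnutrition dichotomy).
#'
#' @param include_diagnosis keep `diagnosis` in the panel. The diagnosis is a
#'   stratification variable in the final model, so stratified analyses drop
#'   it (the default); unstratified all-case analyses keep it.
#' @return a tibble with columns `name`, `kind` (`"continuous"` or
#'   `"binary"`), `cutoff` (`NA` for binary markers) and `description`.
#' @export
marker_panel <- function(include_diagnosis = FALSE) {
  panel <- tibble::tibble(
    name = c("age", "sex", "bmi", "vfa", "pni", "albumin",
             "parenchymal_thickness", "mpd_size", "mpd_index",
             "diabetes", "biliary_drainage", "conut", "sarcopenia",
             "diagnosis"),
    kind = c("continuous", "binary", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "binary", "binary", "continuous", "binary",
             "binary"),
    cutoff = c(65, NA, 25, 100, 45, 3.5, 13, 3, 0.3, NA, NA, 3, NA, NA),
    description = c(
      "age at surgery (years)",
      "male sex",
      "body mass index (kg/m2)",
      "visceral fat area on CT (cm2)",
      "prognostic nutritional index",
      "serum albumin (g/dL)",
      "pancreatic parenchymal thickness (mm)",
      "main pancreatic duct diameter (mm)",
      "MPD size / parenchymal thickness",
      "diabetes mellitus",
      "preoperative biliary drainage",
      "CONUT score (dichotomized at >= 3)",
      "CT-defined sarcopenia",
      "preoperative diagnosis of PDAC"
    )
  )
  if (!include_diagnosis) panel <- panel[panel$name != "diagnosis", ]
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "kind", "cutoff") %in% names(panel)))
  if (anyDuplicated(panel$name))
    stop("duplicate marker names in panel: ",
         paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "))
  if (!all(panel$kind %in% c("continuous", "binary")))
    stop("marker kind must be 'continuous' or 'binary'")
  bad <- panel$kind == "continuous" & !is.finite(panel$cutoff)
  if (any(bad))
    stop("continuous markers need a finite cutoff: ",
         paste(panel$name[bad], collapse = ", "))
  bad <- panel$kind == "binary" & !is.na(panel$cutoff)
  if (any(bad))
    stop("binary markers must not carry a cutoff: ",
         paste(panel$name[bad], collapse = ", "))
  invisible(panel)
}

check_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0))
    stop(what, " must be strictly positive and finite", call. = FALSE)
  invisible(x)
}

#' Main pancreatic duct index
#'
#' Ratio of MPD diameter to pancreatic parenchymal thickness, both in mm.
#' A low index marks a non-dilated duct in thick (typically soft) parenchyma,
#' the gland phenotype prone to postoperative fistula.
#'
#' @param mpd_size duct diameter, mm
#' @param parenchymal_thickness parenchymal thickness, mm
#' @return dimensionless ratio
#' @export
compute_mpd_index <- function(mpd_size, parenchymal_thickness) {
  check_positive(mpd_size, "mpd_size")
  check_positive(parenchymal_thickness, "parenchymal_thickness")
  mpd_size / parenchymal_thickness
}

#' Body mass index
#'
#' @param height metres
#' @param weight kilograms
#' @return kg/m2
#' @export
compute_bmi <- function(height, weight) {
  check_positive(height, "height")
  check_positive(weight, "weight")
  weight / height^2
}

#' Prognostic nutritional index (Onodera)
#'
#' PNI = 10 x albumin (g/dL) + 0.005 x total lymphocyte count (/mm3).
#'
#' @param albumin serum albumin, g/dL
#' @param lymphocytes total lymphocyte count per mm3
#' @return dimensionless score
#' @export
compute_pni <- function(albumin, lymphocytes) {
  check_positive(albumin, "albumin")
  check_positive(lymphocytes, "lymphocytes")
  10 * albumin + 0.005 * lymphocytes
}

#' CONUT score
#'
#' Controlling nutritional status score: sum of three banded sub-scores.
#' Albumin (g/dL): >=3.5 scores 0, 3.0-3.49 scores 2, 2.5-2.99 scores 4,
#' <2.5 scores 6. Lymphocytes (/mm3): >=1600 scores 0, 1200-1599 scores 1,
#' 800-1199 scores 2, <800 scores 3. Cholesterol (mg/dL): >=180 scores 0,
#' 140-179 scores 1, 100-139 scores 2, <100 scores 3.
#'
#' @param albumin serum albumin, g/dL
#' @param lymphocytes total lymphocyte count per mm3
#' @param cholesterol total cholesterol, mg/dL
#' @return integer score, 0-12
#' @export
compute_conut <- function(albumin, lymphocytes, cholesterol) {
  check_positive(albumin, "albumin")
  check_positive(lymphocytes, "lymphocytes")
  check_positive(cholesterol, "cholesterol")
  alb <- ifelse(albumin >= 3.5, 0L, ifelse(albumin >= 3.0, 2L,
         ifelse(albumin >= 2.5, 4L, 6L)))
  lym <- ifelse(lymphocytes >= 1600, 0L, ifelse(lymphocytes >= 1200, 1L,
         ifelse(lymphocytes >= 800, 2L, 3L)))
  cho <- ifelse(cholesterol >= 180, 0L, ifelse(cholesterol >= 140, 1L,
         ifelse(cholesterol >= 100, 2L, 3L)))
  alb + lym + cho
}

# Binary marker columns map to {0,1}: male sex -> 1, PDAC diagnosis -> 1,
# condition present -> 1.
binary_marker_bit <- function(x, name) {
  if (name == "sex") {
    if (!all(x %in% c("male", "female")))
      stop("sex must be 'male' or 'female'")
    return(as.integer(x == "male"))
  }
  if (name == "diagnosis") {
    if (!all(x %in% c("PDAC", "non-PDAC")))
      stop("diagnosis must be 'PDAC' or 'non-PDAC'")
    return(as.integer(x == "PDAC"))
  }
  if (is.logical(x)) return(as.integer(x))
  if (all(x %in% c(0, 1))) return(as.integer(x))
  stop("binary marker '", name, "' must be logical or 0/1")
}

#' Discretize cohort markers at their panel cut-offs
#'
#' Maps each marker to a bin in \{0, 1\}: for a continuous marker, 1 iff the
#' value is at or above the cut-off (the boundary goes to the upper bin); for
#' a binary marker, 1 iff the condition is present (male, PDAC, or TRUE).
#'
#' @param cohort a cohort data frame (see [read_cohort_csv()])
#' @param panel a marker panel, default [marker_panel()]
#' @param markers marker names to discretize, default the whole panel
#' @return integer matrix of 0/1, one row per record, columns named and
#'   ordered as `markers`; rownames are record ids.
#' @export
discretize_cohort <- function(cohort, panel = marker_panel(),
                              markers = panel$name) {
  validate_panel(panel)
  missing_def <- setdiff(markers, panel$name)
  if (length(missing_def))
    stop("markers not in panel: ", paste(missing_def, collapse = ", "))
  out <- matrix(NA_integer_, nrow = nrow(cohort), ncol = length(markers),
                dimnames = list(cohort$id, markers))
  for (m in markers) {
    if (!m %in% names(cohort))
      stop("cohort lacks marker column '", m, "'")
    x <- cohort[[m]]
    if (anyNA(x))
      stop("missing values in marker '", m, "'")
    def <- panel[panel$name == m, ]
    out[, m] <- if (def$kind == "continuous") {
      as.integer(x >= def$cutoff)
    } else {
      binary_marker_bit(x, m)
    }
  }
  out
}
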