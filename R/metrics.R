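# Confusion matrices and the reported performance metrics.

#' Cross-tabulate predictions against outcome labels
#'
#' @param predictions logical vector, `TRUE` = CR-POPF predicted
#' @param labels logical vector, `TRUE` = CR-POPF observed
#' @return an object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `fn`, `tn` (positive class = CR-POPF)
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  if (length(predictions) == 0) stop("empty prediction vector")
  predictions <- as.logical(predictions); labels <- as.logical(labels)
  if (anyNA(predictions) || anyNA(labels))
    stop("predictions and labels must be TRUE/FALSE")
  confusion_matrix(tp = sum(predictions & labels),
                   fp = sum(predictions & !labels),
                   fn = sum(!predictions & labels),
                   tn = sum(!predictions & !labels))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative integer cell counts
#' @return a `confusion_matrix` object
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("confusion cells must be non-negative integers")
  cells <- as.list(stats::setNames(as.integer(cells), names(cells)))
  structure(cells, class = "confusion_matrix")
}

#' Sum confusion matrices cellwise
#'
#' Pools per-stratum matrices into the whole-cohort matrix.
#'
#' @param cms non-empty list of `confusion_matrix` objects
#' @return a `confusion_matrix`
#' @export
pool_confusions <- function(cms) {
  if (length(cms) == 0) stop("no confusion matrices to pool")
  stopifnot(all(vapply(cms, inherits, logical(1), "confusion_matrix")))
  confusion_matrix(tp = sum(vapply(cms, `[[`, integer(1), "tp")),
                   fp = sum(vapply(cms, `[[`, integer(1), "fp")),
                   fn = sum(vapply(cms, `[[`, integer(1), "fn")),
                   tn = sum(vapply(cms, `[[`, integer(1), "tn")))
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Performance metrics from a confusion matrix
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive predictive value
#' tp/(tp+fp), negative predictive value tn/(tn+fn), and the F1 measure, the
#' harmonic mean of PPV and sensitivity. A metric whose denominator is zero
#' is `NA` (undefined), never 0.
#'
#' @param cm a `confusion_matrix`
#' @return an object of class `performance_metrics`: a named list of reals in
#'   \[0, 1\] (or `NA`)
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn)
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp)
  ppv <- safe_ratio(cm$tp, cm$tp + cm$fp)
  npv <- safe_ratio(cm$tn, cm$tn + cm$fn)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv,
                 npv = npv, f1 = f1_measure(ppv, sens)),
            class = "performance_metrics")
}

#' F1 measure from precision and recall
#'
#' @param ppv positive predictive value (precision)
#' @param sensitivity recall
#' @return harmonic mean `2 * ppv * sensitivity / (ppv + sensitivity)`;
#'   `NA` if either input is undefined, 0 if both are 0
#' @export
f1_measure <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity)) return(NA_real_)
  if (ppv + sensitivity == 0) return(0)
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' Round a proportion to a whole percent, half up
#'
#' Report formatting used in the classification tables; raw proportions are
#' kept internally.
#'
#' @param metric a proportion in \[0, 1\] (NAs pass through)
#' @return integer percent
#' @export
round_percent <- function(metric) {
  if (any(!is.na(metric) & (metric < 0 | metric > 1)))
    stop("metric must lie in [0, 1]")
  as.integer(floor(100 * metric + 0.5))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("pred +", "pred -"),
                              c("POPF +", "POPF -")))
  print(m)
  invisible(x)
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f  F1 %.3f\n",
    x$sensitivity, x$specificity, x$ppv, x$npv, x$f1))
  invisible(x)
}
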