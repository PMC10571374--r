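# The final diagnosis-stratified prediction model.
#
# Routing: PDAC patients are scored by a discrete Bayes submodel on the MPD
# index alone (cut-off 0.3); all other diagnoses by a submodel on MPD index
# and BMI (cut-offs 0.3 and 25). The marker sets and cut-offs are fixed --
# they are the published artifact; rediscovering them from a cohort is what
# loo_select() is for. The risk DIRECTION, however, is always learned from
# the training data, never hardcoded: each submodel is an honest classifier
# fit, and the model as a whole is a six-row decision table.

pdac_markers <- "mpd_index"
nonpdac_markers <- c("mpd_index", "bmi")

#' Build the final stratified CR-POPF prediction model
#'
#' @param training labeled training cohort with both strata and, within each
#'   stratum, both outcome classes
#' @param alpha smoothing pseudo-count passed to both submodel fits
#' @param panel marker panel supplying the cut-offs
#' @return an object of class `popf_model` with `pdac` and `nonpdac`
#'   submodels
#' @export
build_final_model <- function(training, alpha = 1,
                              panel = marker_panel()) {
  parts <- stratify_by_diagnosis(training)
  for (st in names(parts))
    if (nrow(parts[[st]]) == 0)
      stop("training cohort has no ", st, " records")
  fit_stratum <- function(part, markers) {
    X <- discretize_cohort(part, panel, markers)
    fit_discrete_bayes(X, part$cr_popf, alpha = alpha)
  }
  structure(
    list(pdac = fit_stratum(parts[["PDAC"]], pdac_markers),
         nonpdac = fit_stratum(parts[["non-PDAC"]], nonpdac_markers),
         alpha = alpha, panel = panel),
    class = "popf_model")
}

route_submodel <- function(model, diagnosis) {
  if (diagnosis == "PDAC") model$pdac else model$nonpdac
}

#' Predict CR-POPF for patients
#'
#' Routes each record to its diagnosis stratum's submodel, discretizes the
#' submodel's markers at their cut-offs, and returns the decision with the
#' posterior CR-POPF probability.
#'
#' @param model a fitted `popf_model`
#' @param cohort records to score (labels not required)
#' @return tibble with columns `id`, `diagnosis`, `predicted` (logical) and
#'   `posterior` (posterior probability of CR-POPF)
#' @export
predict_popf <- function(model, cohort) {
  stopifnot(inherits(model, "popf_model"))
  if (anyNA(cohort$diagnosis)) stop("every record needs a diagnosis")
  out <- tibble::tibble(id = cohort$id, diagnosis = cohort$diagnosis,
                        predicted = NA, posterior = NA_real_)
  for (st in c("PDAC", "non-PDAC")) {
    rows <- which(cohort$diagnosis == st)
    if (!length(rows)) next
    clf <- route_submodel(model, st)
    X <- discretize_cohort(cohort[rows, , drop = FALSE], model$panel,
                           clf$marker_names)
    post <- posterior_popf(clf, X)
    out$posterior[rows] <- post[, "pos"]
    out$predicted[rows] <- post[, "pos"] >= post[, "neg"]
  }
  out
}

#' Evaluate the stratified model on a labeled cohort
#'
#' Per-stratum confusion matrices and metrics, plus the pooled (cellwise
#' summed) matrix and metrics for the whole cohort — the layout of a
#' validation report: one row per stratum and one for all cases.
#'
#' @param model a fitted `popf_model`
#' @param cohort labeled cohort
#' @return list with `confusion` (named list of `confusion_matrix`),
#'   `metrics` (named list of `performance_metrics`), and `report`, a tibble
#'   with raw and whole-percent metrics per stratum and pooled
#' @export
evaluate_model <- function(model, cohort) {
  if (is.null(cohort$cr_popf) || anyNA(cohort$cr_popf))
    stop("evaluation needs a fully labeled cohort (cr_popf)")
  pred <- predict_popf(model, cohort)
  parts <- split(seq_len(nrow(cohort)), cohort$diagnosis)
  present <- intersect(c("PDAC", "non-PDAC"), names(parts))
  if (length(present) < 2)
    warning("stratum ", setdiff(c("PDAC", "non-PDAC"), present),
            " is empty and omitted")
  cms <- lapply(parts[present], function(rows)
    confusion(pred$predicted[rows], cohort$cr_popf[rows]))
  cms$pooled <- pool_confusions(cms)
  mets <- lapply(cms, metrics_from_confusion)
  report <- do.call(rbind, lapply(names(cms), function(nm) {
    m <- mets[[nm]]; cm <- cms[[nm]]
    tibble::tibble(
      stratum = nm, n = cm$tp + cm$fp + cm$fn + cm$tn,
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      sensitivity = m$sensitivity, specificity = m$specificity,
      ppv = m$ppv, npv = m$npv, f1 = m$f1,
      sensitivity_pct = round_percent(m$sensitivity),
      specificity_pct = round_percent(m$specificity),
      ppv_pct = round_percent(m$ppv), npv_pct = round_percent(m$npv))
  }))
  list(confusion = cms, metrics = mets, report = report)
}

#' The model as a decision table
#'
#' The stratified model is a finite lookup: two PDAC rows (MPD index bin)
#' and four non-PDAC rows (MPD index bin x BMI bin), each with the learned
#' decision and posterior.
#'
#' @param model a fitted `popf_model`
#' @return tibble with one row per (stratum, cell)
#' @export
decision_table <- function(model) {
  stopifnot(inherits(model, "popf_model"))
  one <- function(clf, stratum) {
    k <- clf$k
    cells <- as.matrix(expand.grid(rep(list(0:1), k)))[, seq_len(k),
                                                       drop = FALSE]
    colnames(cells) <- clf$marker_names
    post <- posterior_popf(clf, cells)
    tibble::tibble(
      stratum = stratum,
      cell = apply(cells, 1, paste, collapse = ""),
      markers = paste(clf$marker_names, collapse = "+"),
      posterior = unname(post[, "pos"]),
      predicted = unname(post[, "pos"] >= post[, "neg"]))
  }
  rbind(one(model$pdac, "PDAC"), one(model$nonpdac, "non-PDAC"))
}

#' @export
print.popf_model <- function(x, ...) {
  cat("Stratified CR-POPF prediction model\n")
  cat("  PDAC submodel: MPD index (cut-off 0.3)\n")
  cat("  non-PDAC submodel: MPD index (0.3) + BMI (25)\n")
  dt <- decision_table(x)
  dt$posterior <- sprintf("%.3f", dt$posterior)
  print(as.data.frame(dt), row.names = FALSE)
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' The JSON carries marker names, cut-offs, per-cell class counts, priors
#' and the smoothing constant — enough to reconstruct the classifier (and
#' audit the decision table) exactly.
#'
#' @param model a fitted `popf_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_json <- function(model, path) {
  ser_clf <- function(clf) list(
    marker_names = clf$marker_names,
    cutoffs = model$panel$cutoff[match(clf$marker_names,
                                       model$panel$name)],
    counts_neg = clf$counts[, "neg"], counts_pos = clf$counts[, "pos"],
    priors = as.list(clf$priors), alpha = clf$alpha,
    n_train = clf$n_train)
  jsonlite::write_json(
    list(model = "stratified_popf",
         pdac = ser_clf(model$pdac), nonpdac = ser_clf(model$nonpdac),
         alpha = model$alpha),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reconstruct a fitted model from its JSON serialization
#'
#' @param path file written by [write_model_json()]
#' @param panel marker panel (cut-offs are checked against the file)
#' @return a `popf_model`
#' @export
read_model_json <- function(path, panel = marker_panel()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_clf <- function(s) {
    counts <- cbind(neg = as.integer(s$counts_neg),
                    pos = as.integer(s$counts_pos))
    k <- length(s$marker_names)
    stored <- panel$cutoff[match(s$marker_names, panel$name)]
    if (!isTRUE(all.equal(stored, as.numeric(s$cutoffs))))
      stop("cut-offs in model file do not match the panel")
    n_class <- colSums(counts)[c("neg", "pos")]
    priors <- unlist(s$priors)[c("neg", "pos")]
    emp <- n_class / sum(n_class)
    # empirical priors are restored bit-exactly from the counts rather
    # than from their decimal serialization
    if (isTRUE(all.equal(unname(priors), unname(emp), tolerance = 1e-12)))
      priors <- emp
    structure(list(marker_names = s$marker_names, k = k, counts = counts,
                   priors = priors, alpha = s$alpha, n_train = s$n_train,
                   n_class = n_class),
              class = "discrete_bayes")
  }
  structure(list(pdac = de_clf(raw$pdac), nonpdac = de_clf(raw$nonpdac),
                 alpha = raw$alpha, panel = panel),
            class = "popf_model")
}
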