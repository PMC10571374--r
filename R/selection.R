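# Leave-one-out wrapper selection of the optimal marker combination.
#
# The procedure: hold out one training sample; on the remaining N-1, fit the
# discrete Bayes classifier for EVERY candidate marker combination of the
# requested size(s) and score it by its re-substitution estimate (classify
# the same N-1 samples); select one combination per fold by the criterion;
# repeat for all N folds; the most frequently selected combination wins.
# The held-out sample itself is never used -- selection sees only sub-training
# data, and the whole procedure is deterministic given the cohort.
#
# The per-fold work is done on precomputed per-combination cell indices and
# count arrays (decrement one sample, re-derive the decision table, read the
# confusion off the counts), so a full 180-fold run over all 1-3 marker
# subsets of 14 candidates takes seconds.

#' Enumerate marker combinations of a given size
#'
#' @param markers character vector of candidate marker names
#' @param k combination size
#' @return list of character vectors, each sorted; the list is in
#'   lexicographic order, which is also the deterministic tie-break order
#' @export
enumerate_combinations <- function(markers, k) {
  if (k < 1 || k > length(markers))
    stop("combination size k = ", k, " out of range 1..", length(markers))
  ms <- sort(unique(markers))
  if (length(ms) != length(markers)) stop("duplicate candidate markers")
  utils::combn(ms, k, simplify = FALSE)
}

combo_key <- function(combo) paste(sort(combo), collapse = "+")

#' Re-substitution estimate for one marker combination
#'
#' Fits the classifier on the given profiles restricted to `combination` and
#' scores it on the same samples.
#'
#' @param profiles 0/1 matrix with named columns (see [discretize_cohort()])
#' @param labels logical outcome vector
#' @param combination character vector of marker names
#' @param alpha smoothing pseudo-count
#' @return a `performance_metrics` object
#' @export
resubstitution_estimate <- function(profiles, labels, combination,
                                    alpha = 1) {
  sub <- profiles[, combination, drop = FALSE]
  clf <- fit_discrete_bayes(sub, labels, alpha = alpha)
  metrics_from_confusion(confusion(predict(clf, sub), labels))
}

#' Select the best combination from per-combination metrics
#'
#' Under `"max_sens_spec_floor"`, the combination with maximal sensitivity
#' among those with specificity at or above the floor; if none qualifies the
#' fold falls back to maximal F1 (flagged). Under `"max_f1"`, maximal F1.
#' Ties break toward fewer markers, then lexicographically.
#'
#' @param metrics data frame with columns `combination` (list of character
#'   vectors), `sensitivity`, `specificity`, `f1`
#' @param criterion `"max_sens_spec_floor"` or `"max_f1"`
#' @param specificity_floor floor for the constrained criterion
#' @return list with `combination`, `criterion_value`, `fallback`
#' @export
select_best <- function(metrics, criterion = "max_sens_spec_floor",
                        specificity_floor = 0.5) {
  if (nrow(metrics) == 0) stop("no combinations evaluated")
  sizes <- lengths(metrics$combination)
  keys <- vapply(metrics$combination, combo_key, character(1))
  ord <- order(sizes, keys)
  metrics <- metrics[ord, , drop = FALSE]
  pick <- function(values) {
    i <- which.max(values)  # first maximum = fewest markers, then lex
    list(combination = metrics$combination[[i]],
         criterion_value = values[i])
  }
  if (criterion == "max_f1") {
    out <- pick(metrics$f1)
    out$fallback <- FALSE
  } else if (criterion == "max_sens_spec_floor") {
    eligible <- !is.na(metrics$specificity) &
      metrics$specificity >= specificity_floor
    if (any(eligible)) {
      sens <- metrics$sensitivity
      sens[!eligible] <- -Inf
      out <- pick(sens)
      out$fallback <- FALSE
    } else {
      out <- pick(metrics$f1)
      out$fallback <- TRUE
    }
  } else stop("unknown criterion '", criterion, "'")
  out
}

# Vectorized LOO engine over precomputed combination cell indices.
# X: n x m 0/1 matrix over candidate markers; y: logical outcome;
# combos: list of integer column-index vectors in tie-break order.
loo_core <- function(X, y, combos, alpha, criterion, specificity_floor) {
  n <- nrow(X); J <- length(combos)
  k_of <- lengths(combos)
  ncell <- 8L  # pad every combination to 2^3 cells; empty cells weigh 0
  if (any(k_of > 3)) ncell <- 2L^max(k_of)
  C <- matrix(1L, n, J)
  for (j in seq_len(J)) {
    idx <- combos[[j]]
    C[, j] <- 1L + as.integer(X[, idx, drop = FALSE] %*%
                                2^(seq_along(idx) - 1))
  }
  ybit <- as.integer(y)
  off <- (seq_len(J) - 1L) * (2L * ncell)
  lin <- as.vector(t(C) + ybit[rep(seq_len(n), each = J)] * ncell + off)
  A <- array(tabulate(lin, nbins = 2L * ncell * J), c(ncell, 2L, J))
  npos <- sum(ybit); nneg <- n - npos
  two_k <- 2^k_of

  sel_j <- integer(n); sel_val <- numeric(n); sel_fb <- logical(n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    npos_f <- npos - ybit[i]; nneg_f <- nneg - (1L - ybit[i])
    if (npos_f == 0L || nneg_f == 0L) { skipped[i] <- TRUE; next }
    Af <- A
    li <- C[i, ] + ybit[i] * ncell + off
    Af[li] <- Af[li] - 1L
    negc <- matrix(Af[, 1L, ], ncell, J)
    posc <- matrix(Af[, 2L, ], ncell, J)
    # cross-multiplied decision scores, exact for small counts (matches
    # predict.discrete_bayes including its tie behaviour)
    dec <- sweep(posc + alpha, 2, npos_f * (nneg_f + alpha * two_k), "*") >=
      sweep(negc + alpha, 2, nneg_f * (npos_f + alpha * two_k), "*")
    if (alpha == 0) {
      zero <- posc == 0 & negc == 0
      if (any(zero)) dec[zero] <- npos_f >= nneg_f
    }
    TP <- colSums(posc * dec); FP <- colSums(negc * dec)
    FN <- npos_f - TP; TN <- nneg_f - FP
    sens <- TP / npos_f; spec <- TN / nneg_f
    f1 <- ifelse(2 * TP + FP + FN == 0, 0, 2 * TP / (2 * TP + FP + FN))
    if (criterion == "max_f1") {
      j <- which.max(f1); sel_val[i] <- f1[j]
    } else {
      eligible <- spec >= specificity_floor
      if (any(eligible)) {
        s <- sens; s[!eligible] <- -Inf
        j <- which.max(s); sel_val[i] <- sens[j]
      } else {
        j <- which.max(f1); sel_val[i] <- f1[j]; sel_fb[i] <- TRUE
      }
    }
    sel_j[i] <- j
  }
  list(sel_j = sel_j, sel_val = sel_val, fallback = sel_fb,
       skipped = skipped)
}

#' Leave-one-out selection of the optimal marker combination
#'
#' Runs the full wrapper procedure on a labeled cohort. By default each
#' combination size is searched in its own pass (`cumulative = FALSE`),
#' mirroring how single-, two- and three-marker panels are reported side by
#' side; with `cumulative = TRUE` all sizes compete in one pass and the
#' fewer-markers tie-break applies across sizes.
#'
#' Folds in which the held-out sample leaves a single-class sub-training set
#' are skipped with a warning and excluded from the tally denominator.
#'
#' @param cohort labeled cohort (needs `cr_popf`)
#' @param candidates candidate marker names; default the panel minus
#'   `diagnosis` (a stratification variable, not a predictor)
#' @param sizes combination sizes to search, each in 1..3 normally
#' @param criterion per-fold selection criterion, see [select_best()]
#' @param specificity_floor specificity constraint, default 0.5
#' @param alpha smoothing pseudo-count for every classifier fit
#' @param cumulative search all sizes in a single competition
#' @param panel marker panel supplying cut-offs
#' @return if `cumulative`, one `selection_result`; otherwise a named list of
#'   `selection_result`, one per size. Each carries the per-fold selection
#'   log (`folds`), the frequency `tally`, and the `winner` combination.
#' @export
loo_select <- function(cohort,
                       candidates = setdiff(marker_panel()$name, "diagnosis"),
                       sizes = 1:2,
                       criterion = c("max_sens_spec_floor", "max_f1"),
                       specificity_floor = 0.5, alpha = 1,
                       cumulative = FALSE,
                       panel = marker_panel(include_diagnosis = TRUE)) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0) stop("empty candidate marker list")
  if (is.null(cohort$cr_popf) || anyNA(cohort$cr_popf))
    stop("selection needs a fully labeled cohort (cr_popf)")
  if (sum(cohort$cr_popf) < 2 || sum(!cohort$cr_popf) < 2)
    stop("need at least 2 samples per outcome class")
  X <- discretize_cohort(cohort, panel, candidates)
  y <- as.logical(cohort$cr_popf)
  run <- function(szs) {
    combos <- list()
    for (k in sort(szs))
      combos <- c(combos, enumerate_combinations(candidates, k))
    idx <- lapply(combos, function(cmb) match(cmb, candidates))
    core <- loo_core(X, y, idx, alpha, criterion, specificity_floor)
    selection_result(cohort$id, combos, core, criterion,
                     specificity_floor, alpha, szs)
  }
  if (cumulative) return(run(sizes))
  out <- lapply(sizes, run)
  names(out) <- as.character(sizes)
  out
}

selection_result <- function(ids, combos, core, criterion,
                             specificity_floor, alpha, sizes) {
  keep <- !core$skipped
  if (any(core$skipped))
    warning(sum(core$skipped), " fold(s) skipped: held-out sample left a ",
            "single-class sub-training set")
  keys <- vapply(combos, combo_key, character(1))
  folds <- tibble::tibble(
    fold = which(keep),
    held_out_id = ids[keep],
    combination = keys[core$sel_j[keep]],
    criterion_value = core$sel_val[keep],
    fallback = core$fallback[keep])
  tal <- table(folds$combination)
  tally <- tibble::tibble(
    combination = names(tal),
    size = lengths(strsplit(names(tal), "+", fixed = TRUE)),
    freq = as.integer(tal))
  tally <- tally[order(-tally$freq, tally$size, tally$combination), ]
  winner_key <- tally$combination[1]
  structure(
    list(folds = folds, tally = tally,
         winner = strsplit(winner_key, "+", fixed = TRUE)[[1]],
         n_folds = sum(keep), skipped_ids = ids[core$skipped],
         criterion = criterion, specificity_floor = specificity_floor,
         alpha = alpha, sizes = sizes),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out marker selection (%d folds, sizes %s, criterion %s)\n",
    x$n_folds, paste(x$sizes, collapse = ","), x$criterion))
  cat("winner:", combo_key(x$winner), "\n")
  top <- utils::head(x$tally, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-40s %4d/%d folds\n", top$combination[i],
                top$freq[i], x$n_folds))
  invisible(x)
}

#' Held-out leave-one-out performance of one combination
#'
#' Diagnostic companion to [loo_select()]: re-substitution estimates drive
#' the selection (and are optimistic); this reports the honest leave-one-out
#' estimate for a fixed combination, classifying each held-out sample with a
#' classifier fitted on the other N-1.
#'
#' @inheritParams loo_select
#' @param combination marker names of the fixed combination
#' @return a `performance_metrics` object
#' @export
loo_holdout_estimate <- function(cohort, combination, alpha = 1,
                                 panel = marker_panel(include_diagnosis = TRUE)) {
  X <- discretize_cohort(cohort, panel, combination)
  y <- as.logical(cohort$cr_popf)
  n <- nrow(X)
  pred <- logical(n)
  for (i in seq_len(n)) {
    if (sum(y[-i]) == 0 || sum(!y[-i]) == 0)
      stop("degenerate fold: a class vanishes when holding out sample ", i)
    clf <- fit_discrete_bayes(X[-i, , drop = FALSE], y[-i], alpha = alpha)
    pred[i] <- predict(clf, X[i, , drop = FALSE])
  }
  metrics_from_confusion(confusion(pred, y))
}
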