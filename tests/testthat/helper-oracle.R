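# Shared fixtures and the brute-force Bayes oracle used to cross-check the
# classifier implementation.

# Eight-sample, one-marker training set used throughout: POPF+ cases sit
# mostly in the low bin, controls mostly in the high bin.
eight_sample_fixture <- function() {
  list(
    profiles = matrix(c(0, 0, 0, 1, 0, 1, 1, 1), ncol = 1,
                      dimnames = list(NULL, "m")),
    labels = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

# Brute-force discrete Bayes rule: tabulate the joint (cell, class) counts
# by direct row matching and compare prior-weighted smoothed likelihoods.
# Shares no code with the package's cell-indexing path.
oracle_predict <- function(X, y, Xnew, alpha) {
  k <- ncol(X)
  n_pos <- sum(y); n_neg <- sum(!y)
  key <- function(M) apply(M, 1, paste, collapse = "")
  train_keys <- key(X)
  vapply(key(Xnew), function(cell) {
    c_pos <- sum(train_keys == cell & y)
    c_neg <- sum(train_keys == cell & !y)
    # prior(c) * P(cell|c) compared by cross-multiplication (exact for
    # the rational probabilities involved)
    s_pos <- n_pos * (c_pos + alpha) * (n_neg + alpha * 2^k)
    s_neg <- n_neg * (c_neg + alpha) * (n_pos + alpha * 2^k)
    if (s_pos == 0 && s_neg == 0) n_pos >= n_neg else s_pos >= s_neg
  }, logical(1), USE.NAMES = FALSE)
}

# Minimal labeled cohort over custom binary markers, for selection tests
# that need hand-built structure rather than the generator.
binary_marker_cohort <- function(markers, labels) {
  stopifnot(is.matrix(markers))
  tibble::tibble(
    id = sprintf("S%03d", seq_len(nrow(markers))),
    !!!as.data.frame(markers),
    cr_popf = labels)
}

binary_panel <- function(names) {
  tibble::tibble(name = names, kind = "binary", cutoff = NA_real_,
                 description = names)
}
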