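#' Stratified fold assignment
#'
#' Random fold labels balanced within each class: every fold receives the
#' same number of samples from each class, up to a remainder of one.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed making the assignment reproducible.
#' @return Integer vector of fold ids in `1..k`, aligned with `y`.
#' @export
make_folds <- function(y, k = 10, seed = 1) {
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  y <- as.factor(y)
  if (min(table(y)) < 1) stop("empty class", call. = FALSE)
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(sample(k), length(idx))
    }
  })
  folds
}

#' Default SBFS criterion: cross-validated LDA accuracy
#'
#' Mean accuracy of an LDA classifier under stratified k-fold CV with a
#' fixed fold assignment. Falls back to majority-class prediction when LDA
#' cannot be fit (e.g. a training fold with a constant feature set).
#'
#' @param X Numeric feature matrix.
#' @param y Class labels.
#' @param folds Integer fold assignment aligned with the rows.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
lda_cv_criterion <- function(X, y, folds) {
  k <- max(folds)
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    pred <- tryCatch({
      fit <- suppressWarnings(MASS::lda(X[tr, , drop = FALSE],
                                        grouping = y[tr]))
      as.character(predict(fit, X[!tr, , drop = FALSE])$class)
    }, error = function(e) {
      rep(names(which.max(table(y[tr]))), sum(!tr))
    })
    mean(pred == as.character(y[!tr]))
  }, 0)
  mean(acc)
}

#' Sequential backward (floating) feature selection
#'
#' Wrapper selection starting from the full feature set: at each step the
#' feature whose removal most improves the criterion is dropped; with
#' `floating = TRUE`, previously removed features are conditionally re-added
#' whenever that improves on the best criterion value seen at the resulting
#' subset size. The default criterion is the mean accuracy of an LDA
#' classifier under internal stratified 10-fold cross-validation; selection
#' must be run on training data only. Stops when no single removal strictly
#' increases the criterion.
#'
#' @param features Feature tibble with a `label` column (training rows only).
#' @param criterion Function `(X, y, folds) -> J in [0, 1]`; default
#'   [lda_cv_criterion()].
#' @param floating Re-add removed features conditionally (default `TRUE`).
#' @param k Internal CV folds for the default criterion (default 10).
#' @param seed Seed for the internal fold assignment.
#' @param max_steps Safety cap on accepted removal steps (default `Inf`).
#' @return Object of class `sbfs_result`: `selected` feature names and a
#'   `trace` tibble of `(size, J)` over accepted states.
#' @export
sbfs <- function(features, criterion = lda_cv_criterion, floating = TRUE,
                 k = 10, seed = 1, max_steps = Inf) {
  cols <- feature_cols(features)
  if (length(cols) < 2) stop("need at least 2 features", call. = FALSE)
  y <- as.factor(features$label)
  if (nlevels(droplevels(y)) < 2) stop("labels contain a single class",
                                       call. = FALSE)
  X <- as.matrix(features[cols])
  folds <- make_folds(y, k = min(k, min(table(y))), seed = seed)
  Jfun <- function(sub) criterion(X[, sub, drop = FALSE], y, folds)

  current <- cols
  removed <- character(0)
  J_cur <- Jfun(current)
  best_at_size <- stats::setNames(J_cur, length(current))
  trace <- list(list(size = length(current), J = J_cur))
  steps <- 0

  while (length(current) > 1 && steps < max_steps) {
    cand <- vapply(current, function(f) Jfun(setdiff(current, f)), 0)
    best <- which.max(cand)
    if (cand[best] <= J_cur) break
    removed <- c(removed, current[best])
    current <- setdiff(current, current[best])
    J_cur <- cand[best]
    sz <- as.character(length(current))
    best_at_size[sz] <- max(J_cur, best_at_size[sz], na.rm = TRUE)
    trace <- c(trace, list(list(size = length(current), J = J_cur)))
    steps <- steps + 1

    if (floating) {
      repeat {
        if (!length(removed)) break
        back <- vapply(removed, function(f) Jfun(c(current, f)), 0)
        b <- which.max(back)
        sz_up <- as.character(length(current) + 1)
        prev <- best_at_size[sz_up]
        if (!is.na(prev) && back[b] <= prev) break
        current <- c(current, removed[b])
        removed <- setdiff(removed, removed[b])
        J_cur <- back[b]
        best_at_size[sz_up] <- J_cur
        trace <- c(trace, list(list(size = length(current), J = J_cur)))
      }
    }
  }
  structure(
    list(selected = current[order(match(current, cols))],
         trace = dplyr::bind_rows(trace)),
    class = "sbfs_result"
  )
}

#' @export
print.sbfs_result <- function(x, ...) {
  cat(sprintf("<sbfs_result> %d features selected, final J = %.3f\n",
              length(x$selected), x$trace$J[nrow(x$trace)]))
  invisible(x)
}

#' Selection trace as a tibble
#'
#' @param x An `sbfs_result`.
#' @param ... Unused.
#' @return Tibble of `(size, J)` over accepted states.
#' @export
tidy.sbfs_result <- function(x, ...) x$trace
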