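#' Stratified k-fold cross-validation of a feature-selection + classifier
#' pipeline
#'
#' Splits the samples into `k` stratified folds; within each training fold
#' the z-score transform is fitted and (optionally) SBFS feature selection is
#' run, then the classifier is trained and the held-out fold predicted.
#' Every sample is tested exactly once. All fitting happens strictly inside
#' the training fold, so the held-out labels can never leak into scaling or
#' selection.
#'
#' @param features Feature tibble from [assemble_features()] (columns
#'   `subject_id`, `label`, features).
#' @param classifier Classifier family name, see [train_classifier()].
#' @param k Number of folds (default 10).
#' @param select Run [sbfs()] inside each training fold (default `FALSE`).
#' @param seed Integer seed controlling fold assignment, selection folds and
#'   classifier randomness.
#' @param fdr_mode FDR convention, see [confusion_metrics()].
#' @param sbfs_args Extra arguments passed to [sbfs()].
#' @param folds Optional explicit fold assignment (integer vector in `1..k`
#'   aligned with the rows); default stratified random via [make_folds()].
#'   Supplying folds directly supports leakage audits where labels are
#'   perturbed without changing the partition.
#' @return Object of class `eegmci_cv`: per-fold metrics, pooled confusion
#'   counts, and the per-fold fitted state (scaler statistics and selected
#'   features) for audit.
#' @export
kfold_cv <- function(features, classifier = "LSVM", k = 10, select = FALSE,
                     seed = 1, fdr_mode = "reported", sbfs_args = list(),
                     folds = NULL) {
  y <- features$label
  if (is.null(folds)) folds <- make_folds(y, k = k, seed = seed)
  res <- run_cv_iterations(features, split_ids = folds, classifier = classifier,
                           select = select, seed = seed, sbfs_args = sbfs_args)
  per_fold <- dplyr::bind_rows(lapply(seq_along(res$confusions), function(f) {
    dplyr::bind_cols(tibble::tibble(fold = f),
                     confusion_metrics(res$confusions[[f]], fdr_mode))
  }))
  total <- Reduce(function(a, b) {
    structure(list(TP = a$TP + b$TP, FN = a$FN + b$FN,
                   FP = a$FP + b$FP, TN = a$TN + b$TN),
              class = "confusion_counts")
  }, res$confusions)
  structure(list(per_fold = per_fold, counts = total,
                 fold_state = res$state, classifier = classifier,
                 fdr_mode = fdr_mode, scheme = "kfold"),
            class = "eegmci_cv")
}

#' Leave-one-participant-out cross-validation
#'
#' One iteration per subject: that subject's rows are held out, the z-score
#' transform (and optional SBFS selection) is fitted on the remaining
#' subjects, the classifier is trained and the held-out subject predicted.
#' Confusion counts are accumulated over all iterations, so no subject ever
#' appears in both training and test data of an iteration. Intended for
#' feature tables extracted from full unsegmented recordings (one row per
#' participant), but also valid with several rows per subject.
#'
#' @inheritParams kfold_cv
#' @param one_row_per_subject Require exactly one row per subject id
#'   (default `TRUE`, the participant-independent protocol).
#' @return An `eegmci_cv` object with accumulated counts.
#' @export
lopo_cv <- function(features, classifier = "LSVM", select = FALSE, seed = 1,
                    fdr_mode = "reported", sbfs_args = list(),
                    one_row_per_subject = TRUE) {
  ids <- features$subject_id
  if (one_row_per_subject && anyDuplicated(ids)) {
    stop("duplicate subject_ids: supply one unsegmented recording per participant",
         call. = FALSE)
  }
  split_ids <- match(ids, unique(ids))
  res <- run_cv_iterations(features, split_ids = split_ids,
                           classifier = classifier, select = select,
                           seed = seed, sbfs_args = sbfs_args)
  total <- Reduce(function(a, b) {
    structure(list(TP = a$TP + b$TP, FN = a$FN + b$FN,
                   FP = a$FP + b$FP, TN = a$TN + b$TN),
              class = "confusion_counts")
  }, res$confusions)
  per_fold <- dplyr::bind_cols(tibble::tibble(fold = NA_integer_),
                               confusion_metrics(total, fdr_mode))
  structure(list(per_fold = per_fold, counts = total,
                 fold_state = res$state, classifier = classifier,
                 fdr_mode = fdr_mode, scheme = "lopo"),
            class = "eegmci_cv")
}

# Shared engine: one iteration per unique split id; z-scoring and optional
# SBFS fitted on the training rows only.
run_cv_iterations <- function(features, split_ids, classifier, select, seed,
                              sbfs_args) {
  confusions <- list()
  state <- list()
  for (f in sort(unique(split_ids))) {
    tr <- features[split_ids != f, , drop = FALSE]
    te <- features[split_ids == f, , drop = FALSE]
    if (!nrow(te)) stop("empty fold", call. = FALSE)
    zs <- zscore_fit(tr)
    tr_z <- zscore_apply(zs, tr)
    te_z <- zscore_apply(zs, te)
    cols <- feature_cols(features)
    if (select) {
      sel <- do.call(sbfs, c(list(tr_z, seed = seed + f), sbfs_args))
      cols <- sel$selected
    }
    model <- train_classifier(classifier, as.matrix(tr_z[cols]),
                              tr_z$label, seed = seed + f)
    pred <- predict_classifier(model, as.matrix(te_z[cols]))
    confusions[[length(confusions) + 1L]] <- confusion_counts(te$label, pred)
    state[[length(state) + 1L]] <- list(zscore = zs, selected = cols)
  }
  list(confusions = confusions, state = state)
}

#' @export
print.eegmci_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<eegmci_cv> %s, %s: AC %.1f  SE %.1f  SP %.1f  F1 %.1f  FDR %.1f (%%)\n",
              x$scheme, x$classifier, g$AC, g$SE, g$SP, g$F1, g$FDR))
  invisible(x)
}

#' Per-fold cross-validation metrics
#'
#' @param x An `eegmci_cv` object.
#' @param ... Unused.
#' @return Tibble of per-fold metrics (percent).
#' @export
tidy.eegmci_cv <- function(x, ...) x$per_fold

#' One-row cross-validation summary
#'
#' For k-fold results, the mean and standard deviation of each metric over
#' folds; for leave-one-participant-out results, the metrics of the
#' accumulated confusion counts.
#'
#' @param x An `eegmci_cv` object.
#' @param ... Unused.
#' @return One-row tibble: `AC`, `SE`, `SP`, `F1`, `FDR` (and `_sd` columns
#'   for k-fold).
#' @export
glance.eegmci_cv <- function(x, ...) {
  if (x$scheme == "lopo") {
    return(confusion_metrics(x$counts, x$fdr_mode))
  }
  m <- x$per_fold[c("AC", "SE", "SP", "F1", "FDR")]
  out <- dplyr::summarise(m, dplyr::across(dplyr::everything(),
                                           ~ mean(.x, na.rm = TRUE)))
  sds <- dplyr::summarise(m, dplyr::across(dplyr::everything(),
                                           ~ stats::sd(.x, na.rm = TRUE)))
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(out, sds)
}

#' Box plot of per-fold metrics
#'
#' @param object An `eegmci_cv` object from [kfold_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eegmci_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_fold,
                            cols = c("AC", "SE", "SP", "F1", "FDR"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}
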