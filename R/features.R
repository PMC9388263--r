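#' Assemble a feature matrix from EEG segments
#'
#' Runs the requested extractors on every segment and binds the results into
#' a tidy feature table: one row per segment, metadata columns `subject_id`
#' and `label`, then the feature columns in fixed order (connectivity,
#' spectral, nonlinear). The full three-set table is 171 + 108 + 152 = 431
#' features wide.
#'
#' @param segments List of [eeg_recording] segments.
#' @param sets Character subset of
#'   `c("connectivity", "spectral", "nonlinear")`.
#' @param sl_params [sl_params()] block for the connectivity set.
#' @param sl_stride Reference-time stride for the SL estimator.
#' @param lyap_m Lyapunov embedding dimension for the nonlinear set.
#' @return Tibble with `subject_id`, `label`, and one column per feature.
#' @export
assemble_features <- function(segments,
                              sets = c("connectivity", "spectral", "nonlinear"),
                              sl_params = eegmci::sl_params(),
                              sl_stride = 1L, lyap_m = 5) {
  sets <- match.arg(sets, several.ok = TRUE)
  if (!length(segments)) stop("no segments supplied", call. = FALSE)
  # fixed concatenation order regardless of how `sets` was spelled
  sets <- intersect(c("connectivity", "spectral", "nonlinear"), sets)
  rows <- purrr::map(segments, function(seg) {
    feats <- numeric(0)
    if ("connectivity" %in% sets) {
      feats <- c(feats, connectivity_features(seg, sl_params, sl_stride))
    }
    if ("spectral" %in% sets) feats <- c(feats, spectral_features(seg))
    if ("nonlinear" %in% sets) {
      feats <- c(feats, nonlinear_features(seg, lyap_m = lyap_m))
    }
    tibble::as_tibble_row(c(
      list(subject_id = seg$subject_id, label = seg$label),
      as.list(feats)
    ))
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out)) stop("missing values in assembled feature matrix",
                       call. = FALSE)
  out
}

#' Names of the feature columns of a feature table
#'
#' Returns every column name except the metadata columns
#' (`subject_id`, `label`).
#'
#' @param features A feature tibble as returned by [assemble_features()].
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(features) {
  setdiff(names(features), c("subject_id", "label"))
}

#' Fit and apply a z-score transform
#'
#' `zscore_fit()` computes per-feature mean and sample (n-1) standard
#' deviation from training rows only; `zscore_apply()` standardises any
#' feature table with those statistics. Features constant in training map
#' to zero everywhere.
#'
#' @param train Feature tibble (rows = training samples) as from
#'   [assemble_features()]; metadata columns are passed through untouched.
#' @return For `zscore_fit()`, a list of class `zscore_stats` with `mean`
#'   and `sd` vectors; for `zscore_apply()`, the transformed tibble.
#' @export
zscore_fit <- function(train) {
  cols <- feature_cols(train)
  m <- vapply(train[cols], mean, 0)
  s <- vapply(train[cols], stats::sd, 0)
  structure(list(mean = m, sd = s), class = "zscore_stats")
}

#' @rdname zscore_fit
#' @param stats A `zscore_stats` object from `zscore_fit()`.
#' @param data Feature tibble to transform.
#' @export
zscore_apply <- function(stats, data) {
  stopifnot(inherits(stats, "zscore_stats"))
  cols <- names(stats$mean)
  for (cl in cols) {
    s <- stats$sd[[cl]]
    data[[cl]] <- if (is.na(s) || s == 0) {
      rep(0, nrow(data))
    } else {
      (data[[cl]] - stats$mean[[cl]]) / s
    }
  }
  data
}

#' Write / read feature tables
#'
#' Thin CSV wrappers for the feature-table interchange format: a header of
#' feature names plus `subject_id` and `label` columns.
#'
#' @param features Feature tibble.
#' @param path CSV path.
#' @return `read_features()` returns the tibble; `write_features()` returns
#'   `path` invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}
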