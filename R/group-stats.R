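#' Per-feature two-sample t-tests between diagnostic groups
#'
#' Welch two-sample t-test of each feature between the two label groups.
#'
#' @param features Feature tibble with a `label` column (two classes).
#' @param subset Optional character vector of feature names to test
#'   (default: all feature columns).
#' @return Tibble with columns `feature`, `t`, `p`, one row per feature.
#' @export
ttest_features <- function(features, subset = NULL) {
  cols <- feature_cols(features)
  if (!is.null(subset)) {
    missing <- setdiff(subset, cols)
    if (length(missing)) stop("unknown features: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    cols <- subset
  }
  y <- as.factor(features$label)
  if (nlevels(droplevels(y)) != 2) stop("need exactly two label groups",
                                        call. = FALSE)
  g1 <- y == levels(y)[1]
  if (sum(g1) < 2 || sum(!g1) < 2) stop("each group needs >= 2 samples",
                                        call. = FALSE)
  res <- purrr::map(cols, function(cl) {
    a <- features[[cl]][g1]; b <- features[[cl]][!g1]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) return(tibble::tibble(feature = cl, t = 0, p = 1))
      stop("zero within-group variance with differing means for '", cl, "'",
           call. = FALSE)
    }
    tt <- stats::t.test(a, b)
    tibble::tibble(feature = cl, t = unname(tt$statistic), p = tt$p.value)
  })
  dplyr::bind_rows(res)
}

#' Top-ranked features by t-test p-value
#'
#' Returns the `top_k` rows of a t-test table in ascending p-value order,
#' with ties broken alphabetically by feature name. Used to report the most
#' discriminative functional-connectivity coefficients.
#'
#' @param ttable Tibble from [ttest_features()].
#' @param top_k Number of rows to keep (default 10).
#' @return Tibble of at most `top_k` rows, sorted by `p`.
#' @export
rank_connectivity <- function(ttable, top_k = 10) {
  if (!nrow(ttable)) stop("empty t-test table", call. = FALSE)
  if (top_k > nrow(ttable)) {
    warning("top_k exceeds table size; returning the full table",
            call. = FALSE)
    top_k <- nrow(ttable)
  }
  ttable <- dplyr::arrange(ttable, .data$p, .data$feature)
  ttable[seq_len(top_k), , drop = FALSE]
}
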